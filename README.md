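# psmadyn

Quantitative analysis of short-term androgen-blockade effects on PSMA
expression and tumour cellularity from serial [68Ga]Ga-PSMA-11 PET/MR, for
imaging scientists and biostatisticians working on treatment-response
quantification in hormone-sensitive prostate cancer.

Static SUV readings can stay deceptively flat while androgen blockade
transiently *up*-regulates PSMA receptor density and simultaneously thins
out tumour cells. Separating those effects needs dynamic PET kinetics (the
binding potential), diffusion MRI (cellularity), and longitudinal models
that can represent a non-monotonic trajectory. `psmadyn` implements that
whole chain, plus the synthetic data needed to test it end to end.

## What it computes

**Kinetics.** The non-displaceable binding potential BP_ND of the PSMA
tracer is estimated by the simplified reference tissue model (SRTM) from
lesion and reference time–activity curves (TACs):

    C_T(t) = R1·C_R(t) + (k2 − R1·k2a)·(C_R ⊗ e^(−k2a·t))(t),
    k2a = k2 / (1 + BP_ND)

fitted by weighted Levenberg–Marquardt on (R1, log k2, log(1 + BP_ND)) with
frame-duration/count weights and multi-start (`fit_srtm()`).

**Image quantification.** Frame-integrated decay correction to injection
time, adaptive 40%-relative-threshold lesion segmentation
(`segment_lesion_40pct()`), VOI-mean TAC extraction, SUV conversion and
1-ml-sphere SUVpeak (`suv_peak()`).

**ADC.** Mono-exponential diffusion fit S(b) = S0·e^(−b·ADC) by weighted
log-linear least squares (`fit_adc_monoexp()`), lesion-mean ADC.

**Longitudinal statistics.** Percent fold changes from baseline, median/IQR
group summaries, REML linear mixed-effects trajectory models with cubic
time and an ADC-extended variant (`fit_lme()`), mixed-model Bland–Altman
bias/limits of agreement and the generalized concordance correlation
coefficient (`agreement_lme()`, `concordance_correlation()`).

**Synthetic data.** Tri-exponential plasma input, one-tissue reference and
SRTM lesion TAC simulators with frame-statistics noise, 4D dynamic PET and
multi-b DWI phantoms with ground-truth masks, and a longitudinal cohort
generator with per-patient random effects (`generate_cohort()`).

The per-patient serum-PSA table of the 8-patient study cohort is packaged
(`load_psa_fixture()`), so the biochemical-response analysis reproduces
from the installed package alone.

## Worked example

Biochemical response of the packaged cohort — fold changes, group
medians/IQRs, and the mixed-effects decline rate:

```r
library(psmadyn)
library(dplyr)

psa <- load_psa_fixture()
excl <- unique(psa$patient_id[psa$pet_negative])
traj <- compute_fold_changes(select(psa, -pet_negative),
                             exclude_patients = excl)
summarize_trajectories(traj)
#> # A tibble: 3 × 6
#>   metric   day median    q1    q3     n
#>   <chr>  <dbl>  <dbl> <dbl> <dbl> <int>
#> 1 PSA        7  -23.5 -41.3 -10.8     5
#> 2 PSA       21  -55.6 -63.9 -25.7     5
#> 3 PSA       28  -88.3 -89.7 -29.1     7
```

By day 28 the PET-positive patients' PSA has fallen by a median 88.3%
(IQR −89.7% to −29.1%): a strong group-level biochemical response. The
mixed model puts the average decline near −2.2 percentage points per
treatment day (all eight patients, missing draws dropped):

```r
fit_lme(compute_fold_changes(select(psa, -pet_negative)),
        pct_change ~ day + (1 | patient_id))
#> Linear mixed-effects fit (lmer, REML); n_obs = 28, n_groups = 8
#>   term        estimate std.error    df statistic     p.value conf.low conf.high
#> 1 (Intercept)    -2.83     8.26     26    -0.342 0.735         -19.8      14.1
#> 2 day            -2.17     0.300    26    -7.25  0.000000107    -2.79     -1.56
```

Kinetics on synthetic ground truth — simulate a lesion with known
parameters, add 5% frame noise, and refit:

```r
cp  <- make_input_function()
ref <- simulate_reference_tac(cp)                       # 55-frame schedule
les <- simulate_lesion_tac_srtm(ref, list(R1 = 1.2, k2 = 0.3, bpnd = 2)) |>
  add_tac_noise(0.05, seed = 42)
fit_srtm(les, ref)
#> SRTM fit (55 frames)
#>   R1    = 1.2869 (SE 0.0569)
#>   k2    = 0.2615 /min (SE 0.0227)
#>   BP_ND = 2.0247 (SE 0.0560)
#>   weighted RSS = 4.65e+04; restarts used = 3
```

BP_ND comes back within ~1% of the generating value of 2.0 at this noise
level; `autoplot(fit)` overlays the fitted curve on the data. A full
simulate → quantify → fit → analyze run with per-stage CSV/JSON artifacts
and provenance is one call: `run_pipeline(study_config(out_dir = "run1"))`,
or from a shell, `Rscript scripts/pipeline.R --out-dir run1 --seed 1`.

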