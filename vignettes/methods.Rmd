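---
title: "Models and methods: dynamic PSMA PET/MR quantification and longitudinal response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmadyn)
library(dplyr)
```

# Scope

`psmadyn` quantifies the short-term effect of androgen blockade on prostate
cancer lesions from serial [68Ga]Ga-PSMA-11 PET/MR: the non-displaceable
binding potential (BP~ND~) of the PSMA tracer estimated from dynamic PET by
the simplified reference tissue model (SRTM), lesion apparent diffusion
coefficient (ADC) from multi-b diffusion MRI, SUVpeak from static PET, and a
statistical layer that turns per-visit values into fold changes, group
summaries, mixed-effects trajectories, and method-agreement statistics.
Because clinical dynamic PET series of this kind are rarely shareable, the
package carries a synthetic-data layer that generates kinetically and
statistically faithful inputs for every stage; all tests run against it.

Out of scope, deliberately: PET reconstruction, MR pulse sequences,
inter-scan registration, partial-volume correction beyond the VOI strategy,
and any clinical decision logic.

# Kinetic model

## Plasma input and reference region

The simulators are driven by a tri-exponential (Feng-type) bolus model

$$C_p(t) = (A_1 t - A_2 - A_3)\,e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} +
A_3 e^{-\lambda_3 t},$$

zero at injection and non-negative whenever $\lambda_1$ is the fastest rate.
No arterial sampling exists in the imaging protocol this package models;
the input function is a *simulation driver only*, and its defaults
(`feng_default_params()`) are shaped to a sharp sub-minute peak with a slow
tail, not fitted to patient data.

The reference region — gluteus maximus, effectively devoid of PSMA
receptors — is simulated as a one-tissue compartment,
$dC_R/dt = K_1' C_p - k_2' C_R$. The defaults $K_1' = 0.1$ ml/ml/min,
$k_2' = 0.25$/min are plausible for resting muscle and are labelled as
simulation choices: the study this package reproduces reports no kinetic
rate constants, so none of these values should be read as measured.

## SRTM forward model and fitting

Lesion kinetics follow the SRTM operational equation

$$C_T(t) = R_1 C_R(t) + \left(k_2 - R_1 k_{2a}\right)
\left(C_R \otimes e^{-k_{2a} t}\right)(t),
\qquad k_{2a} = \frac{k_2}{1 + BP_{ND}},$$

with $R_1$ the delivery ratio, $k_2$ the tissue efflux rate and BP~ND~ the
binding potential. Continuous curves are evaluated on a 0.01-min internal
grid; the exponential convolution is a trapezoidal recursion implemented as
a linear recursive filter (exact for the discretized integrand, O(n)); frame
values are *averages over each frame interval*, not point samples, matching
how PET frames integrate counts. The default frame schedule is the 55-frame
acquisition (15 × 20 s, 15 × 40 s, 25 × 60 s, 40 min total).

`fit_srtm()` minimizes the weighted residual sum of squares by
Levenberg–Marquardt. Parameters are fitted as $(R_1, \log k_2,
\log(1+BP_{ND}))$, which enforces $k_2 > 0$ and $BP_{ND} > -1$ without
constrained optimization. Three fixed starting points
(`srtm_default_starts()`) guard against local minima; the best converged
solution is kept and the restart count reported. Standard errors come from
the Jacobian at the optimum, delta-transformed to the natural scale.
Weights follow the frame-statistics inverse-variance rule

$$w_i \propto \frac{\Delta t_i}{\max(C_i,\,0.05\,C_{\max})\,
e^{\lambda t_i}},$$

normalized to mean 1; the 5% clamp keeps near-empty early frames from
dominating. This is one concrete reading of duration-and-counts weighting —
vendor conventions differ and are not documented, so parameter *recovery*,
not vendor-output equality, is the correctness criterion throughout.

Two numerical facts matter when interpreting tests. When the reference TAC
carries its continuous fine-grid curve (simulated data), fits are exact to
machine precision on noiseless input. When only frame values are available
(the measured-data path), the reference is rebuilt by linear interpolation
through frame mid-points anchored at (0, 0); the resulting frame
discretization biases noiseless recovery by roughly 0.5% in $R_1$ and
0.4% in $k_2$ (≈0.06% in BP~ND~), which we judged preferable to
mean-preserving reconstructions that oscillate on sharply peaked curves.
The SRTM objective is also anisotropic: $k_2$ is its weakly identified
direction, so exhaustive-grid cross-checks in the test suite compare optima
through an independent simplex refinement rather than raw grid-cell
locations.

# Image quantification

*Decay correction* multiplies each frame by the exact frame-integrated
factor $e^{\lambda t_{start}}\lambda\Delta t/(1 - e^{-\lambda\Delta t})$
($\lambda = \ln 2 / 67.71$ min for gallium-68), refuses double application,
and inverts exactly.

*Segmentation* uses an adaptive relative threshold: within a spherical
search region around a seed voxel, threshold at 40% of the region maximum
and keep the 6-connected supra-threshold component containing the maximum.
6-connectivity is conservative by intent (no diagonal leakage into
bladder-like structures); voxels exactly at threshold are included; the
mask records method, threshold and search region as provenance. Whether the
original analysis applied a background-adaptive correction is not
documented; the plain relative threshold is implemented and tagged.

*SUVpeak* is the maximum mean SUV over 1-ml spheres (radius ≈ 6.204 mm)
centred at each voxel of the lesion mask, with sphere membership by
voxel-centre inclusion; SUV is concentration divided by dose per body
weight at 1 g/ml density. Candidate centres are restricted to the mask,
keeping the peak a sub-volume of the lesion VOI.

*TAC extraction* is the unweighted per-frame mean over the mask. Voxel
indices are 1-based (R convention) with world coordinates in mm from the
grid origin; frames must be contiguous — gaps are errors, never silently
interpolated.

# ADC estimation

The mono-exponential diffusion model $S(b) = S_0 e^{-b\,\mathrm{ADC}}$ is
fitted by weighted log-linear least squares with weights $\propto S^2$,
which approximates the full nonlinear fit at high SNR while being
deterministic and start-free; with exactly two b-values it reproduces the
closed form $\ln(S_0/S_b)/b$ identically. Voxels with any non-positive
signal are excluded and counted. Default b-values are {0, 800} s/mm² — the
source protocol does not state them, so they are configurable and labelled
non-measured. Simulated DWI noise is Gaussian rather than Rician: at the
lesion SNR regime simulated here (SNR ≥ 50 in the calibration tests) the
magnitude bias is far below the 3% recovery tolerance.

# Longitudinal statistics

Fold change is $100(x_{follow} - x_{base})/x_{base}$: the convention is
fixed by the sign of every reported decline (a description of the
computation as baseline-minus-follow-up would flip all signs). Baseline
rows are zero by construction; series without a usable baseline are dropped
with a count. Patients without PET-detectable lesions are excluded from
imaging summaries *explicitly, by listed ID* — never inferred.

Group descriptives are medians with IQRs under midpoint plotting positions
$(k - 0.5)/n$ with linear interpolation (`quantile type 5`). This
convention was chosen because it reproduces the printed day-28 upper
quartile of the study's PSA table from first principles; the printed lower
quartile (−89.6) is not exactly reproducible under any standard convention
we tried (closest: −89.72), most plausibly because the tabulated PSA values
are rounded — the discrepancy is reported, not forced.

Trajectory models are linear mixed-effects fits (lme4, REML) with
per-patient random intercepts: ΔPSA% with linear time; ΔBP~ND~% with
linear + quadratic + cubic time (the cubic term is what lets a biphasic,
rebound-shaped PSMA trajectory be detected); an extended ΔBP~ND~% model
adds ΔADC% as a covariate. Day-0 rows (identically zero) stay in the
models with an intercept — on a four-day visit grid they are what
identifies the cubic polynomial's intercept. Inference uses t statistics
on residual degrees of freedom ($n - p$), the default of the original
analysis tooling; Satterthwaite corrections are deliberately not applied,
and this is documented as a convention, not an equivalence claim. The
PSA model reconstruction is necessarily partial — the original
specification (raw PSA vs fold change, random slopes, baseline rows) is
not published — so the package documents its default and exposes the
formula. Degenerate data (zero random variance, perfect fits) fall back to
ordinary least squares, the exact limit of the mixed model there, with the
`engine` field recording the path. Singular fixed-effect designs error,
naming the collinear terms: in a zero-noise synthetic cohort ΔADC% is an
exact linear function of time, so the extended model is *meant* to refuse
that input.

Agreement between static (ΔSUV%) and dynamic (ΔBP~ND~%) response metrics
uses a mixed-model Bland–Altman: differences $d$ are modelled as
$d \sim 1 + (1|\text{lesion})$, bias is the intercept and the 95% limits
are $\text{bias} \pm 1.96\sqrt{\sigma^2_{lesion} + \sigma^2_{res}}$.
Concordance uses the variance-components generalized CCC from the
long-format model $\text{value} \sim \text{method} +
(1|\text{lesion-visit})$, with the method variance term
$(\hat\beta_{method})^2/2$; when the grouping degenerates (zero subject
variance, e.g. anticorrelated methods), Lin's sample CCC is reported
instead and the estimator is named in the output. The repeated-measures
unit is the lesion-visit pair; the original analysis does not state its
choice, so this one is documented.

# The synthetic cohort

`generate_cohort()` emulates the study design: patients scanned at
treatment days {0, 7, 21, 28} under first-generation antiandrogen. Its
fixed-effect defaults *are* the study conditions: the cubic ΔBP~ND~%
trajectory (−5.63, +1.11, −0.03 %/day^k^), the linear ΔADC% slope
(+1.66 %/day), the linear ΔSUV% slope (−0.83 %/day), and a PSA decline
rate of 0.0766/day derived from the day-28 median fold change of −88.3%.
Patient-level heterogeneity enters as Gaussian random intercepts on the
percent scale (SDs 15/8/10 points for BP~ND~/ADC/SUV) with residual SDs
20/6/8 — chosen once as realistic for the wide interquartile ranges seen
in this setting — and PSA noise is multiplicative lognormal
(σ~log~ = 0.1) so concentrations stay positive. Baselines are lognormal
draws (BP~ND~ ≈ 3, ADC ≈ 0.9 × 10⁻³ mm²/s, SUVpeak ≈ 8, PSA ≈ 15 ng/ml).
Absolute values are reconstructed from the percent trajectories, so the
fold-change layer inverts the construction exactly.

What the generator does *not* emulate: scanner physics (resolution,
scatter, randoms), motion, registration error between visits, Rician DWI
noise, correlated lesion-level random effects, or dropout mechanisms
beyond explicit missing rows. Passing tests therefore demonstrate that the
estimators recover the truth of *this* generative family at the stated
noise levels — not that they are robust to every artefact of clinical
data.

# Problem sizes and reproducibility

Monte-Carlo checks use sizes chosen to make sampling error a small
fraction of each tolerance: 200 replicates for SRTM noise bias (5% frame
noise, 55-frame schedule), 200 DWI voxel-set replicates at SNR 50, and 200
cohort replicates at 50 patients for CI calibration, where per-coefficient
binomial noise (±1.5 points) motivates judging the 93–97% band on the
rate pooled over the four trajectory coefficients. All simulators are
bit-reproducible under a fixed seed, every pipeline output embeds the seed
and a config hash, and re-running `run_pipeline()` with an identical
configuration reproduces identical numeric outputs.

# Known limitations

- The SRTM fit is the classic three-parameter model; no vascular term,
  no SRTM2, no voxelwise parametric maps.
- The measured-data reference interpolation carries the ~0.5% $R_1$
  discretization bias described above.
- Inference on small cohorts (eight patients) relies on residual-df t
  intervals; these are anti-conservative relative to Satterthwaite for
  variance-component-heavy designs, which is part of why the calibration
  claims are made at n = 50, not n = 8.
- The printed agreement statistics of the source study (bias 25.7%, LoA
  −107.2% to +158.6%, CCC 0.069) depend on per-lesion imaging values
  published only as figures; the package reproduces the *estimators* on
  constructed and simulated ground truth instead.
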