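#' Configuration for the longitudinal cohort simulator
#'
#' Defines the study conditions emulated by [generate_cohort()]: visit grid,
#' fixed-effect trajectory shapes, per-patient random-intercept SDs and
#' residual SDs. Defaults reproduce the study design this package targets:
#' an 8-patient cohort scanned at treatment days 0, 7, 21 and 28 under
#' first-generation antiandrogen, with a biphasic (cubic-in-time) mean
#' trajectory of the PSMA binding-potential fold change, a linearly rising
#' ADC fold change, a linearly declining SUVpeak fold change, and
#' exponentially declining PSA.
#'
#' @param n_patients Number of patients (>= 1).
#' @param lesions_per_patient Lesions simulated per patient.
#' @param visit_days Treatment days; must include day 0 (baseline).
#' @param bpnd_poly Cubic fixed-effect coefficients (linear, quadratic,
#'   cubic; %/day^k) of the mean ΔBP_ND% trajectory.
#' @param adc_slope Linear fixed-effect slope of ΔADC%, %/day.
#' @param suv_slope Linear fixed-effect slope of ΔSUV%, %/day.
#' @param psa_rate PSA exponential decline rate, per day.
#' @param random_effect_sds Named vector, per-patient random-intercept SDs
#'   (percentage points) for `bpnd`, `adc`, `suv`.
#' @param residual_sds Named vector, residual SDs (percentage points) for
#'   `bpnd`, `adc`, `suv`.
#' @param psa_sdlog Lognormal SD of multiplicative PSA noise (keeps PSA
#'   positive).
#' @param baselines Named list of baseline lognormal draws:
#'   `meanlog`/`sdlog` per metric (`bpnd` unitless, `adc` mm^2/s,
#'   `suv` unitless, `psa` ng/ml).
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 8,
                          lesions_per_patient = 1,
                          visit_days = c(0, 7, 21, 28),
                          bpnd_poly = c(-5.63, 1.11, -0.03),
                          adc_slope = 1.66,
                          suv_slope = -0.83,
                          psa_rate = 0.0766,
                          random_effect_sds = c(bpnd = 15, adc = 8, suv = 10),
                          residual_sds = c(bpnd = 20, adc = 6, suv = 8),
                          psa_sdlog = 0.10,
                          baselines = list(
                            bpnd = c(meanlog = log(3), sdlog = 0.4),
                            adc = c(meanlog = log(0.9e-3), sdlog = 0.15),
                            suv = c(meanlog = log(8), sdlog = 0.4),
                            psa = c(meanlog = log(15), sdlog = 1)),
                          seed = 1L) {
  if (n_patients < 1) abort("`n_patients` must be >= 1.")
  if (!0 %in% visit_days) abort("`visit_days` must include day 0 (baseline).")
  if (any(c(random_effect_sds, residual_sds, psa_sdlog) < 0)) {
    abort("All SDs must be >= 0.")
  }
  structure(list(n_patients = n_patients,
                 lesions_per_patient = lesions_per_patient,
                 visit_days = sort(unique(visit_days)),
                 bpnd_poly = bpnd_poly, adc_slope = adc_slope,
                 suv_slope = suv_slope, psa_rate = psa_rate,
                 random_effect_sds = random_effect_sds,
                 residual_sds = residual_sds, psa_sdlog = psa_sdlog,
                 baselines = baselines, seed = as.integer(seed)),
            class = "cohort_config")
}

poly_eval <- function(coefs, x) {
  out <- 0
  for (k in seq_along(coefs)) out <- out + coefs[k] * x^k
  out
}

#' Simulate a longitudinal biomarker cohort
#'
#' Generates a long-format visit table of per-lesion BP_ND, ADC and SUVpeak
#' and per-patient PSA at each treatment day. For each imaging metric the
#' percent change from baseline at day d > 0 is
#' fixed-effect trajectory (cubic polynomial for BP_ND, linear for ADC and
#' SUVpeak) + patient random intercept + residual Gaussian noise; baseline
#' rows have zero fold change by construction. Absolute values are
#' reconstructed from lognormal baseline draws. PSA declines exponentially
#' with multiplicative lognormal noise at follow-up visits.
#'
#' @param config A [cohort_config()].
#' @return Tibble with columns `patient_id`, `lesion_id` (NA for PSA),
#'   `day`, `metric` (`"BPND"`, `"ADC"`, `"SUVpeak"`, `"PSA"`), `value`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config.")
  set.seed(config$seed)
  days <- config$visit_days
  fup <- days[days > 0]
  re <- config$random_effect_sds
  rs <- config$residual_sds
  rows <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    b_re <- c(bpnd = rnorm(1, 0, re[["bpnd"]]),
              adc = rnorm(1, 0, re[["adc"]]),
              suv = rnorm(1, 0, re[["suv"]]))
    psa0 <- stats::rlnorm(1, config$baselines$psa[["meanlog"]],
                          config$baselines$psa[["sdlog"]])
    psa <- c(psa0, psa0 * exp(-config$psa_rate * fup) *
               stats::rlnorm(length(fup), 0, config$psa_sdlog))
    rows[[length(rows) + 1]] <- tibble(
      patient_id = pid, lesion_id = NA_character_,
      day = c(0, fup), metric = "PSA", value = psa)
    for (l in seq_len(config$lesions_per_patient)) {
      lid <- sprintf("%sL%d", pid, l)
      base <- c(
        bpnd = stats::rlnorm(1, config$baselines$bpnd[["meanlog"]],
                             config$baselines$bpnd[["sdlog"]]),
        adc = stats::rlnorm(1, config$baselines$adc[["meanlog"]],
                            config$baselines$adc[["sdlog"]]),
        suv = stats::rlnorm(1, config$baselines$suv[["meanlog"]],
                            config$baselines$suv[["sdlog"]]))
      pct <- list(
        bpnd = poly_eval(config$bpnd_poly, fup) + b_re[["bpnd"]] +
          rnorm(length(fup), 0, rs[["bpnd"]]),
        adc = config$adc_slope * fup + b_re[["adc"]] +
          rnorm(length(fup), 0, rs[["adc"]]),
        suv = config$suv_slope * fup + b_re[["suv"]] +
          rnorm(length(fup), 0, rs[["suv"]]))
      for (m in c("bpnd", "adc", "suv")) {
        metric <- c(bpnd = "BPND", adc = "ADC", suv = "SUVpeak")[[m]]
        vals <- c(base[[m]], base[[m]] * (1 + pct[[m]] / 100))
        rows[[length(rows) + 1]] <- tibble(
          patient_id = pid, lesion_id = lid,
          day = c(0, fup), metric = metric, value = vals)
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$patient_id, .data$lesion_id,
                 .data$metric, .data$day)
}
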