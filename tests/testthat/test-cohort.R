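zero_noise_config <- function(n = 4, bpnd_poly = c(-5.63, 1.11, -0.03),
                              adc_slope = 1.66, seed = 1) {
  cohort_config(n_patients = n, bpnd_poly = bpnd_poly, adc_slope = adc_slope,
                random_effect_sds = c(bpnd = 0, adc = 0, suv = 0),
                residual_sds = c(bpnd = 0, adc = 0, suv = 0),
                psa_sdlog = 0, seed = seed)
}

test_that("zero-noise, zero-coefficient cohorts have identically zero change", {
  coh <- generate_cohort(zero_noise_config(bpnd_poly = c(0, 0, 0)))
  traj <- compute_fold_changes(coh)
  bp <- dplyr::filter(traj, metric == "BPND")
  expect_equal(bp$pct_change, rep(0, nrow(bp)))
})

test_that("deterministic trajectories reproduce the stated shapes", {
  coh <- generate_cohort(zero_noise_config())
  traj <- compute_fold_changes(coh)
  # linear ADC slope 1.66 %/day: day 28 -> 46.48%
  adc28 <- dplyr::filter(traj, metric == "ADC", day == 28)
  expect_equal(adc28$pct_change, rep(1.66 * 28, nrow(adc28)), tolerance = 1e-9)
  # cubic polynomial at each follow-up day
  bp <- dplyr::filter(traj, metric == "BPND", day > 0)
  poly_val <- function(d) -5.63 * d + 1.11 * d^2 - 0.03 * d^3
  expect_equal(bp$pct_change, poly_val(bp$day), tolerance = 1e-9)
  # baseline rows are zero by construction
  expect_equal(dplyr::filter(traj, day == 0)$pct_change,
               rep(0, sum(traj$day == 0)))
  # PSA declines exponentially at the configured rate
  psa <- dplyr::filter(traj, metric == "PSA", day == 28)
  expect_equal(unique(round(psa$pct_change, 6)),
               round(100 * (exp(-0.0766 * 28) - 1), 6))
})

test_that("cohort generation is reproducible and validates its config", {
  c1 <- generate_cohort(cohort_config(seed = 99))
  c2 <- generate_cohort(cohort_config(seed = 99))
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(seed = 100))
  expect_false(identical(c1$value, c3$value))
  expect_error(cohort_config(visit_days = c(7, 21, 28)), "day 0")
  expect_error(cohort_config(n_patients = 0), ">= 1")
  expect_error(cohort_config(residual_sds = c(bpnd = -1, adc = 6, suv = 8)),
               ">= 0")
})

test_that("sample mean trajectory tracks the generating polynomial (Monte Carlo)", {
  coh <- generate_cohort(cohort_config(n_patients = 500, seed = 12))
  traj <- compute_fold_changes(coh)
  bp <- dplyr::filter(traj, metric == "BPND", day > 0)
  poly_val <- function(d) -5.63 * d + 1.11 * d^2 - 0.03 * d^3
  by_day <- bp |>
    dplyr::group_by(day) |>
    dplyr::summarise(m = mean(pct_change),
                     se = sd(pct_change) / sqrt(dplyr::n()))
  expect_true(all(abs(by_day$m - poly_val(by_day$day)) <= 2 * by_day$se))
})

test_that("zero-noise cohorts return the generating coefficients through the model layer", {
  coh <- generate_cohort(zero_noise_config(n = 6))
  traj <- compute_fold_changes(coh)
  # day-0 rows are exactly zero and identify the (zero) intercept
  bp <- dplyr::filter(traj, metric == "BPND")
  fit <- fit_lme(bp, pct_change ~ day + I(day^2) + I(day^3) + (1 | patient_id))
  expect_equal(tidy(fit)$estimate, c(0, -5.63, 1.11, -0.03), tolerance = 1e-8)
})
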