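#' Simulate a reference-region TAC (one-tissue kinetics)
#'
#' The reference region (gluteus maximus, devoid of PSMA receptors) is
#' modelled as a single tissue compartment,
#' \eqn{dC_R/dt = K_1' C_p(t) - k_2' C_R(t)}, driven by the plasma input
#' function. The continuous solution is evaluated on a fine internal grid and
#' averaged over each frame interval, matching how PET frames integrate
#' counts.
#'
#' @param input_function Function of time (minutes) returning plasma
#'   concentration, e.g. from [make_input_function()].
#' @param reference_params Named vector/list with `K1p` (ml/ml/min) and
#'   `k2p` (per minute, > 0). Defaults are literature-plausible for muscle,
#'   not measured values.
#' @param schedule Frame schedule tibble; default [schedule_paper55()].
#' @param dt_fine_min Internal grid step, minutes.
#' @return A `psma_tac` tibble; the continuous fine-grid solution is kept in
#'   attribute `"fine"` (list with `t`, `y`) for downstream forward models.
#' @export
simulate_reference_tac <- function(input_function,
                                   reference_params = c(K1p = 0.1, k2p = 0.25),
                                   schedule = schedule_paper55(),
                                   dt_fine_min = 0.01) {
  validate_schedule(schedule)
  p <- as.list(reference_params)
  if (p$k2p <= 0) abort("Reference efflux rate k2p must be > 0.")
  if (p$K1p < 0) abort("Reference uptake rate K1p must be >= 0.")
  t_fine <- fine_grid(schedule, dt_fine_min)
  cp <- input_function(t_fine)
  y <- p$K1p * exp_conv(cp, dt_fine_min, p$k2p)
  tac <- tac_from_schedule(schedule, frame_average(t_fine, y, schedule))
  tac$weight <- compute_fit_weights(tac)
  attr(tac, "fine") <- list(t = t_fine, y = y)
  tac
}

## SRTM operational equation on a fine uniform grid:
## C_T = R1 C_R + (k2 - R1 k2a) (C_R * exp(-k2a t)), k2a = k2 / (1 + BP_ND)
srtm_fine <- function(ref_y, dt, R1, k2, bpnd) {
  if (1 + bpnd <= 0) abort("BP_ND must be > -1.")
  if (k2 <= 0) abort("k2 must be > 0.")
  k2a <- k2 / (1 + bpnd)
  R1 * ref_y + (k2 - R1 * k2a) * exp_conv(ref_y, dt, k2a)
}

## pull (t, y) fine curve out of a simulated TAC, or interpolate frame values
ref_fine_curve <- function(reference, dt_fine_min, t_max_min) {
  fine <- attr(reference, "fine")
  t_fine <- seq(0, t_max_min, by = dt_fine_min)
  if (!is.null(fine)) {
    y <- approx(fine$t, fine$y, xout = t_fine, rule = 2)$y
  } else {
    ## measured TAC: linear interpolation through frame mid-points,
    ## anchored at (0, 0) -- there is no activity before injection
    y <- approx(c(0, reference$t_mid_min), c(0, reference$conc_Bq_ml),
                xout = t_fine, rule = 2)$y
  }
  list(t = t_fine, y = y)
}

#' Forward-simulate a lesion TAC under the SRTM
#'
#' Generates the tissue curve implied by the simplified reference tissue
#' model,
#' \deqn{C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a})\, (C_R \otimes
#'   e^{-k_{2a} t})(t), \qquad k_{2a} = k_2 / (1 + BP_{ND}),}
#' evaluated on a fine grid and frame-averaged onto the schedule.
#'
#' @param reference A reference TAC from [simulate_reference_tac()] (its
#'   continuous fine-grid attribute is used when present).
#' @param truth Named list/vector with `R1`, `k2` (per minute, > 0) and
#'   `bpnd` (> -1).
#' @param schedule Frame schedule; defaults to the reference TAC's schedule.
#' @param dt_fine_min Internal grid step, minutes.
#' @return A `psma_tac` tibble with attribute `"fine"`.
#' @export
simulate_lesion_tac_srtm <- function(reference, truth,
                                     schedule = attr(reference, "schedule"),
                                     dt_fine_min = 0.01) {
  if (is.null(schedule)) abort("No frame schedule available; pass `schedule`.")
  validate_schedule(schedule)
  p <- as.list(truth)
  fine <- ref_fine_curve(reference, dt_fine_min,
                         max(schedule$start_s + schedule$dur_s) / 60)
  y <- srtm_fine(fine$y, dt_fine_min, p$R1, p$k2, p$bpnd)
  tac <- tac_from_schedule(schedule, frame_average(fine$t, y, schedule))
  tac$weight <- compute_fit_weights(tac)
  attr(tac, "fine") <- list(t = fine$t, y = y)
  tac
}

#' Add frame-statistics noise to a TAC
#'
#' Adds zero-mean Gaussian noise with the standard PET frame-count variance
#' law: \eqn{\mathrm{Var}(C_i) \propto C_i e^{\lambda t_i} / \Delta t_i}
#' (decay-corrected data lose counts at late times; short frames collect
#' fewer counts). The proportionality constant is anchored so that
#' `noise_scale` is approximately the coefficient of variation at the TAC
#' peak for a frame of average duration. Inverse-variance fitting weights are
#' repopulated to match.
#'
#' @param tac A TAC tibble.
#' @param noise_scale Unitless noise level (>= 0); ~relative SD at the peak.
#' @param half_life Radionuclide half-life, minutes.
#' @param seed Optional integer seed for reproducibility.
#' @return A noisy `psma_tac` tibble.
#' @export
add_tac_noise <- function(tac, noise_scale, half_life = GA68_HALF_LIFE_MIN,
                          seed = NULL) {
  if (noise_scale < 0) abort("`noise_scale` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  out <- tac
  if (noise_scale > 0) {
    lambda <- log(2) / half_life
    cmax <- max(tac$conc_Bq_ml)
    v <- noise_scale^2 * cmax * pmax(tac$conc_Bq_ml, 0) *
      exp(lambda * tac$t_mid_min) * mean(tac$dt_min) / tac$dt_min
    out$conc_Bq_ml <- tac$conc_Bq_ml + rnorm(nrow(tac), 0, sqrt(v))
    out$weight <- compute_fit_weights(out, half_life)
  }
  attr(out, "fine") <- NULL
  out
}
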