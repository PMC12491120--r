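#' Decay-correct PET data to injection time
#'
#' Applies, per frame, the exact frame-integrated correction factor
#' \deqn{f_i = e^{\lambda t_{start,i}} \frac{\lambda \Delta t_i}
#'   {1 - e^{-\lambda \Delta t_i}}, \qquad \lambda = \ln 2 / T_{1/2},}
#' which converts the frame-average of decaying activity back to the
#' concentration that would have been measured at the time of tracer
#' administration. Works on TAC tibbles and on `dynamic_image` objects;
#' refuses to correct twice.
#'
#' @param x A `psma_tac` tibble or a `dynamic_image`.
#' @param half_life Radionuclide half-life, minutes; defaults to the value
#'   carried by `x` or to gallium-68.
#' @param invert If `TRUE`, removes a previously applied correction
#'   (divides by the same factors).
#' @return The corrected object with its `decay_corrected` flag updated.
#' @export
decay_correct <- function(x, half_life = NULL, invert = FALSE) {
  UseMethod("decay_correct")
}

decay_factors <- function(start_min, dur_min, half_life) {
  if (half_life <= 0) abort("Half-life must be > 0.")
  lambda <- log(2) / half_life
  exp(lambda * start_min) * (lambda * dur_min) / (1 - exp(-lambda * dur_min))
}

#' @export
decay_correct.psma_tac <- function(x, half_life = NULL, invert = FALSE) {
  half_life <- half_life %||% attr(x, "half_life_min") %||% GA68_HALF_LIFE_MIN
  corrected <- isTRUE(attr(x, "decay_corrected"))
  if (!invert && corrected) abort("TAC is already decay corrected.")
  if (invert && !corrected) abort("TAC is not decay corrected; nothing to invert.")
  f <- decay_factors(x$t_mid_min - x$dt_min / 2, x$dt_min, half_life)
  x$conc_Bq_ml <- if (invert) x$conc_Bq_ml / f else x$conc_Bq_ml * f
  attr(x, "decay_corrected") <- !invert
  x
}

#' @export
decay_correct.dynamic_image <- function(x, half_life = NULL, invert = FALSE) {
  half_life <- half_life %||% x$injection$half_life_min
  if (!invert && isTRUE(x$decay_corrected)) {
    abort("Image is already decay corrected.")
  }
  if (invert && !isTRUE(x$decay_corrected)) {
    abort("Image is not decay corrected; nothing to invert.")
  }
  f <- decay_factors(x$schedule$start_s / 60, x$schedule$dur_s / 60, half_life)
  for (i in seq_along(f)) {
    x$data[, , , i] <- if (invert) x$data[, , , i] / f[i] else x$data[, , , i] * f[i]
  }
  x$decay_corrected <- !invert
  x
}
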