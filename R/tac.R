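#' Construct a time--activity curve (TAC)
#'
#' A TAC is a tibble with one row per PET frame: mid-time and duration in
#' minutes, mean activity concentration in Bq/ml, and an inverse-variance
#' fitting weight. The frame schedule and decay-correction status travel as
#' attributes.
#'
#' @param t_mid_min Frame mid-times, minutes post-injection.
#' @param dt_min Frame durations, minutes.
#' @param conc_Bq_ml Mean activity concentration per frame, Bq/ml.
#' @param weight Fitting weights (>= 0); default 1.
#' @param schedule Optional frame schedule tibble (seconds) kept as attribute.
#' @param decay_corrected Logical; whether values are corrected to injection
#'   time. Simulated TACs are generated decay-corrected.
#' @param half_life_min Radionuclide half-life, minutes.
#' @return A `psma_tac` tibble.
#' @export
new_tac <- function(t_mid_min, dt_min, conc_Bq_ml, weight = 1,
                    schedule = NULL, decay_corrected = TRUE,
                    half_life_min = GA68_HALF_LIFE_MIN) {
  n <- length(t_mid_min)
  if (length(dt_min) != n || length(conc_Bq_ml) != n) {
    abort("t_mid_min, dt_min and conc_Bq_ml must have equal length.")
  }
  if (any(dt_min <= 0)) abort("Frame durations must be > 0.")
  weight <- rep_len(weight, n)
  if (any(weight < 0)) abort("Weights must be >= 0.")
  out <- tibble(t_mid_min = as.numeric(t_mid_min), dt_min = as.numeric(dt_min),
                conc_Bq_ml = as.numeric(conc_Bq_ml), weight = as.numeric(weight))
  attr(out, "schedule") <- schedule
  attr(out, "decay_corrected") <- decay_corrected
  attr(out, "half_life_min") <- half_life_min
  class(out) <- c("psma_tac", class(out))
  out
}

tac_from_schedule <- function(schedule, conc, ...) {
  new_tac(frame_mid_min(schedule), frame_dur_min(schedule), conc,
          schedule = schedule, ...)
}

#' Read / write a TAC as CSV
#'
#' The on-disk contract is a four-column CSV: `t_mid_min`, `dt_min`,
#' `conc_Bq_ml`, `weight`.
#'
#' @param tac A TAC tibble.
#' @param path File path.
#' @return `write_tac_csv()` returns `path` invisibly; `read_tac_csv()`
#'   returns a `psma_tac` tibble.
#' @export
write_tac_csv <- function(tac, path) {
  utils::write.csv(tac[, c("t_mid_min", "dt_min", "conc_Bq_ml", "weight")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  d <- utils::read.csv(path)
  new_tac(d$t_mid_min, d$dt_min, d$conc_Bq_ml, d$weight)
}

## --- fine-grid numerical kernels ------------------------------------------

## exponential convolution (y * exp(-rate t))(t) on a uniform grid,
## trapezoidal update written as a linear recursive filter (O(n), in C)
exp_conv <- function(y, dt, rate) {
  n <- length(y)
  if (n == 0) return(numeric(0))
  if (rate == 0) {
    return(cumsum(c(0, dt * (y[-1] + y[-n]) / 2)))
  }
  a <- exp(-rate * dt)
  x <- c(0, dt / 2 * (y[-1] + a * y[-n]))
  as.numeric(stats::filter(x, a, method = "recursive"))
}

## cumulative trapezoid of y over t (uniform or not)
cumtrapz <- function(t, y) {
  n <- length(t)
  cumsum(c(0, diff(t) * (y[-1] + y[-n]) / 2))
}

## average a fine-grid curve over each frame of a schedule (seconds)
frame_average <- function(t_fine_min, y_fine, schedule) {
  validate_schedule(schedule)
  start_min <- schedule$start_s / 60
  end_min <- (schedule$start_s + schedule$dur_s) / 60
  if (max(end_min) > max(t_fine_min) + 1e-9) {
    abort("Fine grid does not cover the full frame schedule.")
  }
  Fc <- cumtrapz(t_fine_min, y_fine)
  F_at <- function(x) approx(t_fine_min, Fc, xout = x, rule = 2)$y
  (F_at(end_min) - F_at(start_min)) / (end_min - start_min)
}

fine_grid <- function(schedule, dt_fine_min) {
  total_min <- max(schedule$start_s + schedule$dur_s) / 60
  seq(0, total_min, by = dt_fine_min)
}
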