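#' Tri-exponential (Feng-type) plasma input function
#'
#' Builds a continuous-time plasma tracer concentration model
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}
#'   + A_3 e^{-\lambda_3 t}}
#' which is zero at t = 0, rises sharply, and decays tri-exponentially.
#' This drives the synthetic kinetics only; the imaging protocol this package
#' models performs no arterial sampling, so the input function is purely a
#' simulation ground-truth device and its defaults are plausible for a
#' bolus-injected small-molecule PET tracer, not measured values.
#'
#' @param params Named list or vector with elements `A1` (Bq/ml/min),
#'   `A2`, `A3` (Bq/ml) and decay rates `l1`, `l2`, `l3` (per minute),
#'   with `l1` the fastest.
#' @return A function of time `t` (minutes, >= 0) returning plasma
#'   concentration in Bq/ml.
#' @examples
#' cp <- make_input_function()
#' cp(c(0, 1, 5, 30))
#' @export
make_input_function <- function(params = feng_default_params()) {
  p <- as.list(params)
  need <- c("A1", "A2", "A3", "l1", "l2", "l3")
  if (!all(need %in% names(p))) {
    abort(paste0("`params` must contain: ", paste(need, collapse = ", ")))
  }
  p <- lapply(p[need], as.numeric)
  f <- function(t) {
    if (any(t < 0)) abort("Input-function times must be >= 0.")
    with(p, (A1 * t - A2 - A3) * exp(-l1 * t) + A2 * exp(-l2 * t) + A3 * exp(-l3 * t))
  }
  ## reject parameter sets that dip negative anywhere on a dense check grid
  chk <- f(seq(0, 120, by = 0.01))
  if (any(chk < -1e-9)) {
    abort("Input-function parameters produce negative concentrations.")
  }
  f
}

#' Default input-function coefficients
#'
#' Shape parameters of the tri-exponential bolus model used by the
#' simulators. Amplitudes are in Bq/ml (A1 in Bq/ml/min), rates per minute.
#' These are simulation defaults, chosen to give a sharp ~0.5-min peak and a
#' slowly clearing tail; they are not derived from patient data.
#'
#' @return Named numeric vector of the six coefficients.
#' @export
feng_default_params <- function() {
  c(A1 = 30000, A2 = 800, A3 = 500, l1 = 4, l2 = 0.5, l3 = 0.008)
}
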