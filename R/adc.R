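#' Fit the mono-exponential diffusion model
#'
#' Estimates S0 and the apparent diffusion coefficient per voxel from signals
#' at two or more b-values, using weighted log-linear least squares: regress
#' \eqn{\ln S} on b with weights proportional to \eqn{S^2}, which
#' approximates the full nonlinear fit at high SNR while staying
#' deterministic (no starting values). ADC = -slope, S0 = exp(intercept).
#' Voxels with any non-positive signal cannot enter the log fit; they are
#' excluded and counted. With exactly two b-values the fit passes through
#' both points, so it equals the closed form \eqn{\ln(S_0/S_b)/b} regardless
#' of the weights.
#'
#' @param signals Numeric vector (one voxel/VOI, one value per b) or matrix
#'   (voxels in rows, b-values in columns).
#' @param b_values Diffusion weightings, s/mm^2; >= 2 distinct values.
#' @return An `adc_fit` list: `S0`, `adc` (mm^2/s; NA for excluded voxels),
#'   `n_voxels_used`, `n_voxels_excluded`.
#' @examples
#' fit_adc_monoexp(c(1000, 1000 * exp(-0.8)), c(0, 800))$adc # 1e-3
#' @export
fit_adc_monoexp <- function(signals, b_values) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  b <- as.numeric(b_values)
  if (length(unique(b)) < 2) abort("Need at least 2 distinct b-values.")
  if (ncol(signals) != length(b)) {
    abort("`signals` must have one column per b-value.")
  }
  ok <- apply(signals, 1, function(s) all(is.finite(s) & s > 0))
  if (!any(ok)) abort("All voxels excluded: no voxel has positive signal at every b.")
  S <- signals[ok, , drop = FALSE]
  L <- log(S)
  W <- S^2
  ## weighted straight-line fit of ln S on b, closed form per voxel
  sw <- rowSums(W)
  mb <- rowSums(W * rep(b, each = nrow(W))) / sw
  ml <- rowSums(W * L) / sw
  bc <- sweep(matrix(b, nrow(W), length(b), byrow = TRUE), 1, mb)
  slope <- rowSums(W * bc * L) / rowSums(W * bc^2)
  inter <- ml - slope * mb
  adc <- rep(NA_real_, nrow(signals))
  s0 <- rep(NA_real_, nrow(signals))
  adc[ok] <- -slope
  s0[ok] <- exp(inter)
  structure(list(S0 = s0, adc = adc,
                 n_voxels_used = sum(ok), n_voxels_excluded = sum(!ok)),
            class = "adc_fit")
}

#' Fit an ADC map from a 4D DWI series
#'
#' Applies [fit_adc_monoexp()] voxelwise to a (x, y, z, b) array.
#'
#' @param dwi 4D array, e.g. from [generate_dwi_series()].
#' @param b_values b-values; defaults to the array's `b_values` attribute.
#' @return List with `adc_map`, `S0_map` (3D arrays, NA where excluded) and
#'   exclusion counts.
#' @export
fit_adc_map <- function(dwi, b_values = attr(dwi, "b_values")) {
  if (is.null(b_values)) abort("`b_values` missing and not attached to `dwi`.")
  d <- dim(dwi)
  sig <- matrix(dwi, nrow = prod(d[1:3]), ncol = d[4])
  fit <- fit_adc_monoexp(sig, b_values)
  list(adc_map = array(fit$adc, d[1:3]), S0_map = array(fit$S0, d[1:3]),
       n_voxels_used = fit$n_voxels_used,
       n_voxels_excluded = fit$n_voxels_excluded)
}

#' Lesion-mean ADC over a VOI
#'
#' Arithmetic mean of the fitted ADC over mask voxels, skipping voxels
#' excluded from the fit (NA in the map).
#'
#' @param adc_map 3D ADC array, mm^2/s.
#' @param mask Logical 3D mask.
#' @return Mean ADC in mm^2/s.
#' @export
lesion_mean_adc <- function(adc_map, mask) {
  if (!identical(dim(adc_map), dim(mask))) abort("Mask does not fit the ADC map.")
  vals <- adc_map[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) abort("Mask is empty after excluding unfitted voxels.")
  mean(vals)
}
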