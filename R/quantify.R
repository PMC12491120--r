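#' Extract a mean TAC over a VOI
#'
#' Per frame, the unweighted mean of the masked voxels of a dynamic image.
#' Frame timing is copied from the image schedule and inverse-variance
#' fitting weights are populated with [compute_fit_weights()].
#'
#' @param dynamic A `dynamic_image`.
#' @param mask Logical 3D array aligned to the image grid.
#' @return A `psma_tac` tibble.
#' @export
extract_tac <- function(dynamic, mask) {
  if (!inherits(dynamic, "dynamic_image")) abort("`dynamic` must be a dynamic_image.")
  d <- dim(dynamic$data)
  if (!identical(dim(mask), d[1:3])) abort("Mask does not fit the image grid.")
  if (!any(mask)) abort("Empty mask.")
  conc <- vapply(seq_len(d[4]),
                 function(f) mean(dynamic$data[, , , f][mask]), numeric(1))
  tac <- tac_from_schedule(dynamic$schedule, conc,
                           decay_corrected = dynamic$decay_corrected,
                           half_life_min = dynamic$injection$half_life_min)
  tac$weight <- compute_fit_weights(tac, dynamic$injection$half_life_min)
  tac
}

#' Convert activity concentration to SUV
#'
#' SUV = concentration / (injected dose / body weight), assuming a tissue
#' density of 1 g/ml, so Bq/ml divided by Bq/g is unitless.
#'
#' @param concentration Activity concentration, Bq/ml (vector or array).
#' @param dose_Bq Injected dose, Bq (> 0).
#' @param weight_g Body weight, g (> 0).
#' @return SUV, same shape as `concentration`.
#' @examples
#' suv_convert(4000, dose_Bq = 160e6, weight_g = 80e3) # 2
#' @export
suv_convert <- function(concentration, dose_Bq, weight_g) {
  if (dose_Bq <= 0) abort("Injected dose must be > 0.")
  if (weight_g <= 0) abort("Body weight must be > 0.")
  concentration / (dose_Bq / weight_g)
}

#' SUVpeak: maximum 1-ml sphere-mean SUV within a lesion VOI
#'
#' For every voxel of the mask, a sphere of volume `sphere_ml` (1 ml by
#' default, radius ~6.204 mm) is centred on the voxel centre; the mean SUV of
#' all image voxels whose centres fall inside the sphere (and inside the
#' grid) is computed, and the maximum such mean is returned. Candidate
#' centres are restricted to mask voxels, keeping the peak a sub-volume of
#' the lesion VOI.
#'
#' @param image 3D array of a static PET frame, Bq/ml.
#' @param mask Logical 3D lesion mask.
#' @param dose_Bq,weight_g Injection metadata for the SUV conversion.
#' @param voxel_size_mm Voxel size, mm.
#' @param sphere_ml Sphere volume in ml.
#' @return SUVpeak (unitless scalar).
#' @export
suv_peak <- function(image, mask, dose_Bq, weight_g,
                     voxel_size_mm = c(2, 2, 2), sphere_ml = 1) {
  d <- dim(image)
  if (!identical(dim(mask), d)) abort("Mask does not fit the image grid.")
  if (!any(mask)) abort("Empty mask.")
  voxel_size_mm <- rep_len(voxel_size_mm, 3)
  radius_mm <- (3 * sphere_ml * 1000 / (4 * pi))^(1 / 3)
  ## voxel-offset neighbourhood whose centres lie within the sphere radius
  nmax <- ceiling(radius_mm / voxel_size_mm)
  offs <- expand.grid(dx = -nmax[1]:nmax[1], dy = -nmax[2]:nmax[2],
                      dz = -nmax[3]:nmax[3])
  r2 <- (offs$dx * voxel_size_mm[1])^2 + (offs$dy * voxel_size_mm[2])^2 +
    (offs$dz * voxel_size_mm[3])^2
  offs <- offs[r2 <= radius_mm^2, , drop = FALSE]
  suv <- suv_convert(image, dose_Bq, weight_g)
  centres <- which(mask, arr.ind = TRUE)
  best <- -Inf
  for (i in seq_len(nrow(centres))) {
    x <- centres[i, 1] + offs$dx
    y <- centres[i, 2] + offs$dy
    z <- centres[i, 3] + offs$dz
    keep <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
    m <- mean(suv[cbind(x[keep], y[keep], z[keep])])
    if (m > best) best <- m
  }
  best
}
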