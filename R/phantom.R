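#' Construct a dynamic PET image container
#'
#' @param data 4D array (x, y, z, frame) of activity concentration, Bq/ml.
#' @param voxel_size_mm Numeric length-3 voxel size in mm.
#' @param schedule Frame schedule tibble (seconds).
#' @param decay_corrected Logical flag.
#' @param injection List with `dose_Bq`, `weight_g`, `half_life_min`.
#' @return A `dynamic_image` object.
#' @export
dynamic_image <- function(data, voxel_size_mm, schedule,
                          decay_corrected = TRUE,
                          injection = default_injection()) {
  if (length(dim(data)) != 4) abort("`data` must be a 4D array (x, y, z, frame).")
  validate_schedule(schedule)
  if (dim(data)[4] != nrow(schedule)) {
    abort("Number of image frames does not match the schedule.")
  }
  if (any(voxel_size_mm <= 0)) abort("Voxel sizes must be > 0.")
  if (injection$half_life_min <= 0) abort("Half-life must be > 0.")
  structure(list(data = data, voxel_size_mm = rep_len(voxel_size_mm, 3),
                 schedule = schedule, decay_corrected = decay_corrected,
                 injection = injection),
            class = "dynamic_image")
}

#' Default injection metadata
#'
#' 2 MBq of tracer per kg body weight for an 80-kg patient (160 MBq),
#' gallium-68 half-life.
#' @return List with `dose_Bq`, `weight_g`, `half_life_min`.
#' @export
default_injection <- function() {
  list(dose_Bq = 160e6, weight_g = 80e3, half_life_min = GA68_HALF_LIFE_MIN)
}

## centre coordinates (mm) of every voxel along one axis; voxel i spans
## [(i-1)*vs, i*vs), centre at (i - 0.5)*vs, with the grid origin at 0
axis_centres_mm <- function(n, vs) (seq_len(n) - 0.5) * vs

## boolean sphere mask on a grid, by voxel-centre inclusion
sphere_mask <- function(dim3, voxel_size_mm, centre_mm, radius_mm) {
  cx <- axis_centres_mm(dim3[1], voxel_size_mm[1])
  cy <- axis_centres_mm(dim3[2], voxel_size_mm[2])
  cz <- axis_centres_mm(dim3[3], voxel_size_mm[3])
  dx2 <- (cx - centre_mm[1])^2
  dy2 <- (cy - centre_mm[2])^2
  dz2 <- (cz - centre_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius_mm^2
}

#' Generate a 4D dynamic PET phantom
#'
#' Builds a rectangular grid in which a spherical lesion carries the lesion
#' TAC, a disjoint slab (the reference region) carries the reference TAC, and
#' everything else sits at a flat background level. Ground-truth masks for
#' both regions are returned, enabling end-to-end
#' segmentation -> TAC extraction -> kinetic fitting tests.
#'
#' @param lesion_tac,reference_tac TAC tibbles on a shared schedule.
#' @param background_level Background concentration, Bq/ml.
#' @param dim3 Grid dimensions (voxels), length 3.
#' @param voxel_size_mm Voxel size, mm.
#' @param lesion_centre_mm,lesion_radius_mm Lesion sphere geometry, mm.
#' @param reference_z Index range (length 2) of axial slices forming the
#'   reference slab; the slab spans the full x-y extent of those slices,
#'   minus any voxels that would overlap the lesion (overlap is an error).
#' @param noise_scale Frame-statistics noise level per voxel (0 = noiseless).
#' @param seed Optional seed.
#' @param injection Injection metadata list.
#' @return List with `image` (a `dynamic_image`), `lesion_mask`,
#'   `reference_mask` (logical 3D arrays).
#' @export
generate_dynamic_phantom <- function(lesion_tac, reference_tac,
                                     background_level = 50,
                                     dim3 = c(40, 40, 24),
                                     voxel_size_mm = c(2, 2, 2),
                                     lesion_centre_mm = c(40, 40, 30),
                                     lesion_radius_mm = 8,
                                     reference_z = c(1, 6),
                                     noise_scale = 0, seed = NULL,
                                     injection = default_injection()) {
  sched <- attr(lesion_tac, "schedule") %||% frame_schedule(lesion_tac$dt_min * 60)
  if (nrow(lesion_tac) != nrow(reference_tac)) {
    abort("Lesion and reference TACs must share one schedule.")
  }
  extent <- dim3 * voxel_size_mm
  if (any(lesion_centre_mm - lesion_radius_mm < 0) ||
      any(lesion_centre_mm + lesion_radius_mm > extent)) {
    abort("Lesion sphere does not fit inside the image grid.")
  }
  lesion_mask <- sphere_mask(dim3, voxel_size_mm, lesion_centre_mm, lesion_radius_mm)
  reference_mask <- array(FALSE, dim3)
  reference_mask[, , reference_z[1]:reference_z[2]] <- TRUE
  if (any(reference_mask & lesion_mask)) {
    abort("Lesion and reference regions overlap; move the lesion or the slab.")
  }
  if (!is.null(seed)) set.seed(seed)
  n_frame <- nrow(lesion_tac)
  img <- array(0, c(dim3, n_frame))
  lambda <- log(2) / injection$half_life_min
  cmax <- max(lesion_tac$conc_Bq_ml, reference_tac$conc_Bq_ml, background_level)
  dtbar <- mean(lesion_tac$dt_min)
  for (f in seq_len(n_frame)) {
    vol <- array(background_level, dim3)
    vol[lesion_mask] <- lesion_tac$conc_Bq_ml[f]
    vol[reference_mask] <- reference_tac$conc_Bq_ml[f]
    if (noise_scale > 0) {
      v <- noise_scale^2 * cmax * pmax(vol, 0) *
        exp(lambda * lesion_tac$t_mid_min[f]) * dtbar / lesion_tac$dt_min[f]
      vol <- vol + array(rnorm(prod(dim3), 0, sqrt(as.vector(v))), dim3)
    }
    img[, , , f] <- vol
  }
  list(image = dynamic_image(img, voxel_size_mm, sched, injection = injection),
       lesion_mask = lesion_mask, reference_mask = reference_mask)
}

#' Generate a multi-b diffusion-weighted image series
#'
#' Mono-exponential diffusion signal decay per voxel,
#' \eqn{S(b) = S_0 e^{-b \cdot ADC}}, with optional additive Gaussian noise.
#' Gaussian (not Rician) noise is used: at the lesion SNR regime simulated
#' here the magnitude-signal bias is negligible and region means are
#' analysed.
#'
#' @param S0_map 3D array of b = 0 signal.
#' @param adc_map 3D array of ADC in mm^2/s (> 0 where S0 > 0).
#' @param b_values Diffusion weightings, s/mm^2 (>= 0, >= 2 values typical;
#'   default c(0, 800)).
#' @param noise_sd Additive Gaussian noise SD in signal units.
#' @param seed Optional seed.
#' @return 4D array (x, y, z, b) with attribute `b_values`.
#' @export
generate_dwi_series <- function(S0_map, adc_map, b_values = c(0, 800),
                                noise_sd = 0, seed = NULL) {
  if (any(b_values < 0)) abort("b-values must be >= 0.")
  if (!identical(dim(S0_map), dim(adc_map))) {
    abort("S0_map and adc_map must have identical dimensions.")
  }
  if (any(adc_map[S0_map > 0] < 0)) abort("ADC must be >= 0 where S0 > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  out <- array(0, c(dim(S0_map), length(b_values)))
  for (i in seq_along(b_values)) {
    s <- S0_map * exp(-b_values[i] * adc_map)
    if (noise_sd > 0) s <- s + array(rnorm(length(s), 0, noise_sd), dim(s))
    out[, , , i] <- s
  }
  attr(out, "b_values") <- b_values
  out
}
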