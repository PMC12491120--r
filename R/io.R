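#' Write / read a dynamic PET volume as NIfTI + JSON sidecar
#'
#' The on-disk contract for 4D dynamic PET is a NIfTI file (x, y, z, frame)
#' plus a JSON sidecar carrying the frame schedule and injection metadata:
#' `frame_starts_s`, `frame_durations_s`, `injected_dose_MBq`, `weight_kg`,
#' `half_life_min`, `decay_corrected` and optionally `seed`.
#'
#' @param image A `dynamic_image`.
#' @param path Output path ending in `.nii` or `.nii.gz`; the sidecar is
#'   written next to it with extension `.json`.
#' @param seed Optional seed to record in the sidecar.
#' @return `write_dynamic_nifti()` returns `path` invisibly;
#'   `read_dynamic_nifti()` returns a `dynamic_image`.
#' @export
write_dynamic_nifti <- function(image, path, seed = NULL) {
  if (!inherits(image, "dynamic_image")) abort("`image` must be a dynamic_image.")
  nii <- RNifti::asNifti(image$data, pixdim = c(image$voxel_size_mm, 1))
  RNifti::writeNifti(nii, path)
  sidecar <- list(frame_starts_s = image$schedule$start_s,
                  frame_durations_s = image$schedule$dur_s,
                  injected_dose_MBq = image$injection$dose_Bq / 1e6,
                  weight_kg = image$injection$weight_g / 1e3,
                  half_life_min = image$injection$half_life_min,
                  decay_corrected = image$decay_corrected)
  if (!is.null(seed)) sidecar$seed <- seed
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dynamic_nifti
#' @export
read_dynamic_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  sc <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  dynamic_image(array(as.numeric(nii), dim(nii)),
                voxel_size_mm = RNifti::pixdim(nii)[1:3],
                schedule = frame_schedule(sc$frame_durations_s),
                decay_corrected = isTRUE(sc$decay_corrected),
                injection = list(dose_Bq = sc$injected_dose_MBq * 1e6,
                                 weight_g = sc$weight_kg * 1e3,
                                 half_life_min = sc$half_life_min))
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write / read a VOI mask as NIfTI (uint8 payload)
#'
#' @param mask Logical 3D array.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param voxel_size_mm Voxel size recorded in the header.
#' @return `write_mask_nifti()` returns `path` invisibly;
#'   `read_mask_nifti()` a logical array.
#' @export
write_mask_nifti <- function(mask, path, voxel_size_mm = c(2, 2, 2)) {
  arr <- array(as.integer(mask), dim(mask))
  nii <- RNifti::asNifti(arr, pixdim = rep_len(voxel_size_mm, 3),
                         datatype = "uint8")
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  array(as.numeric(nii) > 0, dim(nii))
}
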