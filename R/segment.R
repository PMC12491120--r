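#' Adaptive 40% relative-threshold lesion segmentation
#'
#' Delineates a lesion on a static PET frame: within a spherical search
#' region around a seed point, the threshold is set to a fixed fraction
#' (default 40%) of the maximum voxel value in that region, and the returned
#' mask is the 6-connected component of supra-threshold voxels (still within
#' the search region) that contains the maximum voxel. The relative threshold
#' adapts the contour to each lesion's own uptake, reducing
#' partial-volume-driven volume changes across visits; 6-connectivity is
#' deliberately conservative, avoiding diagonal leakage into adjacent hot
#' structures.
#'
#' @param image 3D array of a static PET frame (or SUV image).
#' @param seed_vox Integer voxel index (x, y, z), 1-based, inside the grid.
#' @param search_radius_mm Radius of the spherical search region, mm.
#' @param voxel_size_mm Voxel size, mm (length 1 or 3).
#' @param threshold_frac Relative threshold as a fraction of the search
#'   region maximum (default 0.40). Voxels at exactly the threshold are
#'   included.
#' @return Logical 3D mask with attributes `method` ("adaptive40"),
#'   `threshold` (absolute value used) and `search` (seed + radius).
#' @export
segment_lesion_40pct <- function(image, seed_vox, search_radius_mm,
                                 voxel_size_mm = c(2, 2, 2),
                                 threshold_frac = 0.40) {
  d <- dim(image)
  if (length(d) != 3) abort("`image` must be a 3D array.")
  seed_vox <- as.integer(seed_vox)
  if (any(seed_vox < 1) || any(seed_vox > d)) abort("Seed voxel is outside the grid.")
  voxel_size_mm <- rep_len(voxel_size_mm, 3)
  centre_mm <- (seed_vox - 0.5) * voxel_size_mm
  search <- sphere_mask(d, voxel_size_mm, centre_mm, search_radius_mm)
  if (!any(search)) abort("Search sphere contains no voxels.")
  vals <- image[search]
  vmax <- max(vals)
  if (vmax <= 0) abort("No signal: search region maximum is not positive.")
  thr <- threshold_frac * vmax
  supra <- search & (image >= thr)
  ## flood fill (6-connectivity) from the search-region maximum
  max_idx <- which(search & image == vmax)[1]
  max_vox <- arrayInd(max_idx, d)
  mask <- flood_fill_6(supra, as.integer(max_vox))
  attr(mask, "method") <- "adaptive40"
  attr(mask, "threshold") <- thr
  attr(mask, "search") <- list(seed_vox = seed_vox,
                               radius_mm = search_radius_mm,
                               threshold_frac = threshold_frac)
  mask
}

## 6-connected component of `ok` containing `start` (integer xyz);
## iterative label propagation on the logical array (vectorized per sweep)
flood_fill_6 <- function(ok, start) {
  d <- dim(ok)
  comp <- array(FALSE, d)
  if (!ok[start[1], start[2], start[3]]) return(comp)
  comp[start[1], start[2], start[3]] <- TRUE
  shift <- function(a, ax, by) {
    out <- array(FALSE, d)
    idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    n <- d[ax]
    if (n == 1) return(out)
    if (by == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  repeat {
    grown <- comp
    for (ax in 1:3) for (by in c(1, -1)) {
      grown <- grown | shift(comp, ax, by)
    }
    grown <- grown & ok
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}
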