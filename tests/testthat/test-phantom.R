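make_test_tacs <- function() {
  ref <- simulate_reference_tac(default_cp, schedule = short_schedule)
  les <- simulate_lesion_tac_srtm(ref, default_truth)
  list(ref = ref, les = les)
}

test_that("noiseless phantom carries the generating TACs exactly", {
  tacs <- make_test_tacs()
  ph <- generate_dynamic_phantom(tacs$les, tacs$ref, background_level = 50,
                                 dim3 = c(24, 24, 16),
                                 lesion_centre_mm = c(24, 24, 20),
                                 lesion_radius_mm = 6, reference_z = c(1, 4))
  ext <- extract_tac(ph$image, ph$lesion_mask)
  expect_equal(ext$conc_Bq_ml, tacs$les$conc_Bq_ml)
  ext_r <- extract_tac(ph$image, ph$reference_mask)
  expect_equal(ext_r$conc_Bq_ml, tacs$ref$conc_Bq_ml)
})

test_that("zero background leaves non-region voxels at zero in all frames", {
  tacs <- make_test_tacs()
  ph <- generate_dynamic_phantom(tacs$les, tacs$ref, background_level = 0,
                                 dim3 = c(24, 24, 16),
                                 lesion_centre_mm = c(24, 24, 20),
                                 lesion_radius_mm = 6, reference_z = c(1, 4))
  outside <- !(ph$lesion_mask | ph$reference_mask)
  for (f in seq_len(dim(ph$image$data)[4])) {
    expect_true(all(ph$image$data[, , , f][outside] == 0))
  }
})

test_that("geometry violations are rejected", {
  tacs <- make_test_tacs()
  expect_error(
    generate_dynamic_phantom(tacs$les, tacs$ref, dim3 = c(24, 24, 16),
                             lesion_centre_mm = c(2, 24, 20),
                             lesion_radius_mm = 6),
    "does not fit")
  expect_error(
    generate_dynamic_phantom(tacs$les, tacs$ref, dim3 = c(24, 24, 16),
                             lesion_centre_mm = c(24, 24, 6),
                             lesion_radius_mm = 6, reference_z = c(1, 4)),
    "overlap")
})

test_that("noisy phantom mean TAC is unbiased (within 3 SE per frame)", {
  tacs <- make_test_tacs()
  nrep <- 100
  ext <- matrix(NA_real_, nrep, 10)
  for (r in seq_len(nrep)) {
    ph <- generate_dynamic_phantom(tacs$les, tacs$ref, background_level = 50,
                                   dim3 = c(16, 16, 12),
                                   lesion_centre_mm = c(16, 16, 14),
                                   lesion_radius_mm = 5, reference_z = c(1, 3),
                                   noise_scale = 0.5, seed = 1000 + r)
    ext[r, ] <- extract_tac(ph$image, ph$lesion_mask)$conc_Bq_ml
  }
  m <- colMeans(ext)
  se <- apply(ext, 2, sd) / sqrt(nrep)
  expect_true(all(abs(m - tacs$les$conc_Bq_ml) <= 3 * se + 1e-9))
})

test_that("dynamic NIfTI + sidecar round-trips the image and metadata", {
  tacs <- make_test_tacs()
  ph <- generate_dynamic_phantom(tacs$les, tacs$ref, dim3 = c(16, 16, 12),
                                 lesion_centre_mm = c(16, 16, 14),
                                 lesion_radius_mm = 5, reference_z = c(1, 3))
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_dynamic_nifti(ph$image, tmp, seed = 7)
  back <- read_dynamic_nifti(tmp)
  expect_equal(back$data, ph$image$data, tolerance = 1e-6)
  expect_equal(back$schedule$dur_s, ph$image$schedule$dur_s)
  expect_equal(back$injection$dose_Bq, ph$image$injection$dose_Bq)
  # mask round trip
  tmp2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask_nifti(ph$lesion_mask, tmp2)
  expect_identical(read_mask_nifti(tmp2), ph$lesion_mask)
})
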