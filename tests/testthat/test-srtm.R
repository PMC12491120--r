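test_that("srtm_predict reduces to the reference at R1 = 1, BP_ND = 0 and to zero on zero input", {
  pred <- srtm_predict(list(R1 = 1, k2 = 0.3, bpnd = 0), default_ref)
  expect_lt(max(abs(pred$conc_Bq_ml - default_ref$conc_Bq_ml)) /
              max(default_ref$conc_Bq_ml), 1e-3)
  zero_ref <- new_tac(default_ref$t_mid_min, default_ref$dt_min,
                      rep(0, nrow(default_ref)),
                      schedule = attr(default_ref, "schedule"))
  pz <- srtm_predict(default_truth, zero_ref)
  expect_equal(pz$conc_Bq_ml, rep(0, nrow(zero_ref)))
  expect_error(srtm_predict(default_truth, default_ref[1:2, ]), "3 frames")
})

test_that("srtm_predict and the forward simulator share one operational equation", {
  les <- simulate_lesion_tac_srtm(default_ref, default_truth)
  pred <- srtm_predict(default_truth, default_ref)
  expect_lt(max(abs(pred$conc_Bq_ml - les$conc_Bq_ml)) / max(les$conc_Bq_ml),
            1e-3)
})

test_that("fitting weights follow the duration/count formula exactly", {
  les <- simulate_lesion_tac_srtm(default_ref, default_truth)
  lambda <- log(2) / GA68_HALF_LIFE_MIN
  raw <- les$dt_min / (pmax(les$conc_Bq_ml, 0.05 * max(les$conc_Bq_ml)) *
                         exp(lambda * les$t_mid_min))
  expect_equal(compute_fit_weights(les), raw / mean(raw), tolerance = 1e-12)
  # constant TAC, equal frames, lambda = 0 (infinite half-life) -> all 1
  const <- new_tac(c(0.5, 1.5, 2.5), rep(1, 3), rep(100, 3))
  expect_equal(compute_fit_weights(const, half_life = Inf), rep(1, 3))
  # doubling one duration doubles its unnormalized weight
  w1 <- compute_fit_weights(const, half_life = Inf)
  tac2 <- new_tac(c(0.5, 1.5, 3), c(1, 1, 2), rep(100, 3))
  w2 <- compute_fit_weights(tac2, half_life = Inf)
  expect_equal(w2[3] / w2[1], 2 * w1[3] / w1[1])
  expect_warning(compute_fit_weights(new_tac(1, 1, 0)), "All-zero")
})

test_that("noiseless forward/fit round trip recovers the parameters", {
  les <- simulate_lesion_tac_srtm(default_ref, default_truth)
  fit <- fit_srtm(les, default_ref)
  expect_true(fit$converged)
  expect_lt(abs(fit$R1 / default_truth$R1 - 1), 1e-3)
  expect_lt(abs(fit$k2 / default_truth$k2 - 1), 1e-3)
  expect_lt(abs(fit$bpnd / default_truth$bpnd - 1), 1e-3)
  # lesion = reference -> BP_ND ~ 0
  fit0 <- fit_srtm(default_ref, default_ref)
  expect_lt(abs(fit0$bpnd), 0.01)
  # objective at the optimum is no worse than at any start
  for (s in srtm_default_starts()) {
    pred <- srtm_predict(list(R1 = s[["R1"]], k2 = s[["k2"]], bpnd = s[["bpnd"]]),
                         default_ref)
    rss <- sum(les$weight * (les$conc_Bq_ml - pred$conc_Bq_ml)^2)
    expect_lte(fit$wrss, rss + 1e-9)
  }
})

test_that("measured-TAC fits (frame-interpolated reference) stay close to truth", {
  # strip the continuous curves: the fit must rebuild the reference from its
  # frame values, which carries a small discretization bias
  les <- simulate_lesion_tac_srtm(default_ref, default_truth)
  attr(les, "fine") <- NULL
  ref <- default_ref
  attr(ref, "fine") <- NULL
  fit <- fit_srtm(les, ref)
  expect_lt(abs(fit$bpnd / default_truth$bpnd - 1), 0.01)
  expect_lt(abs(fit$R1 / default_truth$R1 - 1), 0.02)
  expect_lt(abs(fit$k2 / default_truth$k2 - 1), 0.02)
})

test_that("fit is scale-equivariant and idempotent", {
  les <- simulate_lesion_tac_srtm(default_ref, default_truth)
  fit <- fit_srtm(les, default_ref)
  les_s <- les; les_s$conc_Bq_ml <- les$conc_Bq_ml * 250
  fs <- attr(les, "fine"); fs$y <- fs$y * 250; attr(les_s, "fine") <- fs
  ref_s <- default_ref; ref_s$conc_Bq_ml <- default_ref$conc_Bq_ml * 250
  fr <- attr(default_ref, "fine"); fr$y <- fr$y * 250; attr(ref_s, "fine") <- fr
  fit_s <- fit_srtm(les_s, ref_s)
  expect_equal(c(fit_s$R1, fit_s$k2, fit_s$bpnd),
               c(fit$R1, fit$k2, fit$bpnd), tolerance = 1e-6)
  # idempotence: refit on data simulated from the fitted parameters
  les2 <- srtm_predict(list(R1 = fit$R1, k2 = fit$k2, bpnd = fit$bpnd),
                       default_ref)
  les2$weight <- compute_fit_weights(les2)
  fit2 <- fit_srtm(les2, default_ref)
  expect_equal(c(fit2$R1, fit2$k2, fit2$bpnd),
               c(fit$R1, fit$k2, fit$bpnd), tolerance = 1e-6)
})

test_that("estimated BP_ND increases with true BP_ND", {
  ests <- vapply(c(0.5, 1, 2, 4), function(bp) {
    les <- simulate_lesion_tac_srtm(default_ref,
                                    list(R1 = 1.2, k2 = 0.3, bpnd = bp))
    fit_srtm(les, default_ref)$bpnd
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("fit agrees with a coarse grid-search oracle", {
  set.seed(21)
  for (i in 1:5) {
    truth <- list(R1 = runif(1, 0.9, 1.5), k2 = runif(1, 0.15, 0.45),
                  bpnd = runif(1, 0.8, 3.2))
    les <- simulate_lesion_tac_srtm(default_ref, truth)
    fit <- fit_srtm(les, default_ref)
    R1s <- seq(0.7, 1.7, length.out = 9)
    k2s <- seq(0.1, 0.5, length.out = 9)
    bps <- seq(0.4, 3.6, length.out = 9)
    g <- oracle_srtm_optim(les, default_ref, R1s, k2s, bps)
    # the independent grid + simplex route must land on the same optimum
    expect_equal(fit$R1, g$R1, tolerance = 1e-2)
    expect_equal(fit$k2, g$k2, tolerance = 1e-2)
    expect_equal(fit$bpnd, g$bpnd, tolerance = 1e-2)
    expect_lte(fit$wrss, g$grid_wrss + 1e-9)
  }
})

test_that("tidy and glance expose the fit as tibbles", {
  les <- simulate_lesion_tac_srtm(default_ref, default_truth)
  fit <- fit_srtm(les, default_ref)
  td <- tidy(fit)
  expect_equal(td$term, c("R1", "k2", "bpnd"))
  expect_true(all(td$std.error >= 0))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_gte(gl$wrss, 0)
  expect_error(fit_srtm(les[1:5, ], default_ref[1:5, ]), "10 frames")
  expect_s3_class(autoplot(fit), "ggplot")
})
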