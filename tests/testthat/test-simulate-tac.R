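test_that("reference TAC obeys one-tissue limiting cases", {
  # no uptake (the all-zero TAC also triggers the uniform-weights warning)
  expect_warning(
    z <- simulate_reference_tac(default_cp, c(K1p = 0, k2p = 0.25),
                                schedule = short_schedule),
    "All-zero")
  expect_equal(z$conc_Bq_ml, rep(0, 10))
  # constant input: steady state c * K1' / k2'
  const_in <- function(t) rep(1000, length(t))
  long <- frame_schedule(rep(120, 40)) # 80 min
  ss <- simulate_reference_tac(const_in, c(K1p = 0.1, k2p = 0.5), schedule = long)
  expect_equal(tail(ss$conc_Bq_ml, 1), 1000 * 0.1 / 0.5, tolerance = 1e-3)
  expect_true(all(ss$conc_Bq_ml >= 0))
})

test_that("reference TAC matches an independent stiff-ODE solve", {
  skip_if_not_installed("deSolve")
  K1p <- 0.1; k2p <- 0.25
  sched <- schedule_paper55()
  sol <- deSolve::ode(
    y = c(C = 0), times = seq(0, 40, by = 0.005),
    func = function(t, y, p) list(K1p * default_cp(t) - k2p * y),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10)
  # frame averages of the ODE solution by trapezoid on its own grid
  t <- sol[, "time"]; y <- sol[, "C"]
  Fc <- cumsum(c(0, diff(t) * (y[-1] + y[-length(y)]) / 2))
  Fa <- approx(t, Fc, xout = c(sched$start_s, 2400) / 60)$y
  oracle <- diff(Fa) / (sched$dur_s / 60)
  pkg <- simulate_reference_tac(default_cp, c(K1p = K1p, k2p = k2p))$conc_Bq_ml
  expect_lt(max(abs(pkg - oracle)) / max(oracle), 1e-3)
})

test_that("SRTM forward model reduces to the reference when R1 = 1, BP_ND = 0", {
  for (k2 in c(0.1, 0.3, 1)) {
    les <- simulate_lesion_tac_srtm(default_ref,
                                    list(R1 = 1, k2 = k2, bpnd = 0))
    expect_equal(les$conc_Bq_ml, default_ref$conc_Bq_ml, tolerance = 1e-12)
    fine_l <- attr(les, "fine"); fine_r <- attr(default_ref, "fine")
    expect_equal(fine_l$y, fine_r$y, tolerance = 1e-12)
  }
})

test_that("step-input tissue-to-reference ratio converges to 1 + BP_ND", {
  k2 <- 0.3; bpnd <- 2; k2a <- k2 / (1 + bpnd)
  t_conv <- 20 / k2a # minutes
  ref <- constant_reference(1000, total_min = ceiling(t_conv) + 10)
  les <- simulate_lesion_tac_srtm(ref, list(R1 = 1.2, k2 = k2, bpnd = bpnd))
  ratio <- les$conc_Bq_ml / ref$conc_Bq_ml
  after <- les$t_mid_min >= t_conv
  expect_true(any(after))
  expect_true(all(abs(ratio[after] - (1 + bpnd)) / (1 + bpnd) < 0.01))
  # closed form of the step-input convolution at each fine time point
  fine <- attr(les, "fine")
  analytic <- 1.2 * 1000 + (k2 - 1.2 * k2a) * 1000 * (1 - exp(-k2a * fine$t)) / k2a
  expect_lt(max(abs(fine$y - analytic)) / max(analytic), 1e-3)
})

test_that("SRTM convolution agrees with a brute-force discrete convolution", {
  # 10-minute window so the O(n^2) oracle stays cheap
  sched <- frame_schedule(rep(30, 20))
  ref <- simulate_reference_tac(default_cp, schedule = sched)
  les <- simulate_lesion_tac_srtm(ref, default_truth)
  fine <- attr(ref, "fine")
  k2a <- default_truth$k2 / (1 + default_truth$bpnd)
  conv <- oracle_exp_conv(fine$y, 0.01, k2a)
  oracle <- default_truth$R1 * fine$y +
    (default_truth$k2 - default_truth$R1 * k2a) * conv
  expect_lt(max(abs(attr(les, "fine")$y - oracle)) / max(oracle), 1e-3)
})

test_that("invalid kinetic parameters are rejected", {
  expect_error(simulate_lesion_tac_srtm(default_ref,
                                        list(R1 = 1, k2 = 0.3, bpnd = -1.2)),
               "BP_ND")
  expect_error(simulate_lesion_tac_srtm(default_ref,
                                        list(R1 = 1, k2 = -0.1, bpnd = 1)),
               "k2")
  expect_error(simulate_reference_tac(default_cp, c(K1p = 0.1, k2p = 0)),
               "k2p")
})

test_that("frame noise is reproducible, vanishes at scale 0, and follows the variance law", {
  les <- simulate_lesion_tac_srtm(default_ref, default_truth)
  expect_equal(add_tac_noise(les, 0)$conc_Bq_ml, les$conc_Bq_ml)
  n1 <- add_tac_noise(les, 0.05, seed = 42)
  n2 <- add_tac_noise(les, 0.05, seed = 42)
  expect_identical(n1$conc_Bq_ml, n2$conc_Bq_ml)
  expect_error(add_tac_noise(les, -0.1), ">= 0")

  # Monte-Carlo check of the stated law on a small TAC
  small <- les[c(5, 25, 50), ]
  attr(small, "schedule") <- NULL
  class(small) <- class(les)
  lambda <- log(2) / GA68_HALF_LIFE_MIN
  expected_var <- 0.05^2 * max(small$conc_Bq_ml) * small$conc_Bq_ml *
    exp(lambda * small$t_mid_min) * mean(small$dt_min) / small$dt_min
  set.seed(7)
  reps <- replicate(10000, add_tac_noise(small, 0.05)$conc_Bq_ml)
  emp_var <- apply(reps, 1, var)
  expect_true(all(abs(emp_var / expected_var - 1) < 0.05))
})
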