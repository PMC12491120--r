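#' Frame-duration/count fitting weights
#'
#' Inverse-variance weights under the PET frame-statistics noise model for
#' decay-corrected data: \eqn{w_i \propto \Delta t_i / (C_i e^{\lambda t_i})},
#' with the concentration clamped below at 5% of the TAC maximum so that
#' near-empty early frames do not dominate the fit. Weights are normalized to
#' mean 1.
#'
#' @param tac A TAC tibble (`t_mid_min`, `dt_min`, `conc_Bq_ml`).
#' @param half_life Radionuclide half-life in minutes.
#' @param eps Clamp fraction of the maximum concentration (default 0.05).
#' @return Numeric weight vector, mean 1.
#' @export
compute_fit_weights <- function(tac, half_life = GA68_HALF_LIFE_MIN, eps = 0.05) {
  if (any(tac$dt_min <= 0)) abort("Frame durations must be > 0.")
  cmax <- max(tac$conc_Bq_ml)
  if (cmax <= 0) {
    warn("All-zero TAC: returning uniform weights.")
    return(rep(1, nrow(tac)))
  }
  lambda <- log(2) / half_life
  w <- tac$dt_min / (pmax(tac$conc_Bq_ml, eps * cmax) * exp(lambda * tac$t_mid_min))
  w / mean(w)
}

#' Predict a lesion TAC from SRTM parameters
#'
#' Evaluates the SRTM operational equation for given parameters against a
#' measured (or simulated) reference TAC: the reference curve is linearly
#' interpolated to a fine grid (anchored at zero activity at injection), the
#' exponential convolution computed there, and the prediction averaged back
#' onto the reference frame schedule.
#'
#' @param params Named list/vector with `R1`, `k2` (> 0, per minute), `bpnd`
#'   (> -1).
#' @param reference A reference TAC tibble.
#' @param dt_fine_min Fine-grid step, minutes.
#' @return A `psma_tac` tibble of predicted lesion concentrations.
#' @export
srtm_predict <- function(params, reference, dt_fine_min = 0.01) {
  if (nrow(reference) < 3) abort("Reference TAC must have at least 3 frames.")
  p <- as.list(params)
  sched <- attr(reference, "schedule") %||%
    frame_schedule(reference$dt_min * 60)
  fine <- ref_fine_curve(reference, dt_fine_min,
                         max(sched$start_s + sched$dur_s) / 60)
  y <- srtm_fine(fine$y, dt_fine_min, p$R1, p$k2, p$bpnd)
  tac_from_schedule(sched, frame_average(fine$t, y, sched))
}

#' Fit the simplified reference tissue model
#'
#' Estimates (R1, k2, BP_ND) by weighted nonlinear least squares
#' (Levenberg--Marquardt) on the SRTM operational equation. Parameters are
#' fitted on a transformed scale (R1, log k2, log(1 + BP_ND)) to enforce
#' k2 > 0 and BP_ND > -1. The optimiser is multi-started from three fixed
#' initial points and the best converged solution is returned; approximate
#' standard errors come from the Jacobian at the optimum (delta method back
#' to the natural scale).
#'
#' @param lesion Lesion TAC tibble.
#' @param reference Reference TAC tibble on the same frame schedule.
#' @param weights Fitting weights; defaults to the lesion TAC's `weight`
#'   column.
#' @param starts List of named start vectors `(R1, k2, bpnd)`; three robust
#'   defaults are used if omitted.
#' @param dt_fine_min Fine-grid step for the model evaluation, minutes.
#' @param ftol Convergence tolerance on the objective.
#' @return An object of class `srtm_fit`: estimates, standard errors,
#'   weighted residual sum of squares, convergence flag and restart count.
#'   Use [tidy()] / [glance()] to extract tibbles.
#' @examples
#' cp <- make_input_function()
#' ref <- simulate_reference_tac(cp)
#' les <- simulate_lesion_tac_srtm(ref, list(R1 = 1.2, k2 = 0.3, bpnd = 2))
#' fit <- fit_srtm(les, ref)
#' tidy(fit)
#' @export
fit_srtm <- function(lesion, reference, weights = lesion$weight,
                     starts = srtm_default_starts(), dt_fine_min = 0.01,
                     ftol = 1e-8) {
  n <- nrow(lesion)
  if (n < 10) abort("SRTM fitting needs at least 10 frames.")
  if (nrow(reference) != n ||
      max(abs(lesion$t_mid_min - reference$t_mid_min)) > 1e-9) {
    abort("Lesion and reference TACs must share one frame schedule.")
  }
  sched <- attr(reference, "schedule") %||% attr(lesion, "schedule") %||%
    frame_schedule(reference$dt_min * 60)
  t_end <- max(sched$start_s + sched$dur_s) / 60
  ## resolve the reference curve once; each objective call reuses it
  fine <- ref_fine_curve(reference, dt_fine_min, t_end)
  t_fine <- fine$t
  ref_y <- fine$y
  sw <- sqrt(weights)
  obs <- lesion$conc_Bq_ml

  resid_fn <- function(theta) {
    R1 <- theta[1]; k2 <- exp(theta[2]); bpnd <- expm1(theta[3])
    pred <- frame_average(t_fine, srtm_fine(ref_y, dt_fine_min, R1, k2, bpnd),
                          sched)
    sw * (obs - pred)
  }

  best <- NULL
  n_used <- 0L
  for (s in starts) {
    n_used <- n_used + 1L
    theta0 <- c(s[["R1"]], log(s[["k2"]]), log1p(s[["bpnd"]]))
    res <- tryCatch(
      minpack.lm::nls.lm(theta0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = ftol, ptol = 1e-10, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res) || res$info %in% c(0, 5, 9)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }

  if (is.null(best)) {
    return(structure(list(R1 = NA_real_, k2 = NA_real_, bpnd = NA_real_,
                          se = c(R1 = NA_real_, k2 = NA_real_, bpnd = NA_real_),
                          wrss = NA_real_, converged = FALSE,
                          n_restarts_used = n_used, n_frames = n,
                          lesion = lesion, reference = reference,
                          fitted = NULL),
                     class = "srtm_fit"))
  }

  theta <- best$par
  est <- c(R1 = theta[1], k2 = exp(theta[2]), bpnd = expm1(theta[3]))
  ## SEs on the transformed scale from the LM Hessian approximation J'J
  sigma2 <- best$deviance / max(n - 3, 1)
  se_theta <- tryCatch(sqrt(diag(solve(best$hessian)) * sigma2),
                       error = function(e) rep(NA_real_, 3))
  se <- c(R1 = se_theta[1],
          k2 = est[["k2"]] * se_theta[2],
          bpnd = (1 + est[["bpnd"]]) * se_theta[3])
  pred <- frame_average(t_fine,
                        srtm_fine(ref_y, dt_fine_min, est[["R1"]],
                                  est[["k2"]], est[["bpnd"]]), sched)
  structure(list(R1 = est[["R1"]], k2 = est[["k2"]], bpnd = est[["bpnd"]],
                 se = se, wrss = best$deviance, converged = TRUE,
                 n_restarts_used = n_used, n_frames = n,
                 lesion = lesion, reference = reference,
                 fitted = tac_from_schedule(sched, pred)),
            class = "srtm_fit")
}

#' Default multi-start points for [fit_srtm()]
#' @return List of three named `(R1, k2, bpnd)` vectors.
#' @export
srtm_default_starts <- function() {
  list(c(R1 = 1, k2 = 0.1, bpnd = 1),
       c(R1 = 0.5, k2 = 0.3, bpnd = 0.3),
       c(R1 = 1.5, k2 = 0.05, bpnd = 3))
}

#' @export
print.srtm_fit <- function(x, ...) {
  cat("SRTM fit (", x$n_frames, " frames)\n", sep = "")
  if (x$converged) {
    cat(sprintf("  R1    = %.4f (SE %.4f)\n", x$R1, x$se[["R1"]]))
    cat(sprintf("  k2    = %.4f /min (SE %.4f)\n", x$k2, x$se[["k2"]]))
    cat(sprintf("  BP_ND = %.4f (SE %.4f)\n", x$bpnd, x$se[["bpnd"]]))
    cat(sprintf("  weighted RSS = %.4g; restarts used = %d\n",
                x$wrss, x$n_restarts_used))
  } else {
    cat("  did not converge from any start\n")
  }
  invisible(x)
}

#' @rdname fit_srtm
#' @param x,object An `srtm_fit` object.
#' @param ... Unused.
#' @method tidy srtm_fit
#' @export
tidy.srtm_fit <- function(x, ...) {
  tibble(term = c("R1", "k2", "bpnd"),
         estimate = c(x$R1, x$k2, x$bpnd),
         std.error = unname(x$se[c("R1", "k2", "bpnd")]))
}

#' @rdname fit_srtm
#' @method glance srtm_fit
#' @export
glance.srtm_fit <- function(x, ...) {
  tibble(wrss = x$wrss, converged = x$converged,
         n_restarts_used = x$n_restarts_used, n_frames = x$n_frames)
}

#' Plot an SRTM fit
#'
#' Observed lesion TAC (points), reference TAC (dashed) and the fitted model
#' curve (solid).
#'
#' @param object An `srtm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot srtm_fit
#' @export
autoplot.srtm_fit <- function(object, ...) {
  d <- dplyr::bind_rows(
    lesion = object$lesion[, c("t_mid_min", "conc_Bq_ml")],
    reference = object$reference[, c("t_mid_min", "conc_Bq_ml")],
    .id = "series")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$t_mid_min, .data$conc_Bq_ml)) +
    ggplot2::geom_point(data = d[d$series == "lesion", ], size = 0.8) +
    ggplot2::geom_line(data = d[d$series == "reference", ], linetype = 2) +
    ggplot2::labs(x = "Time post-injection (min)",
                  y = "Concentration (Bq/ml)",
                  title = sprintf("SRTM fit: BP_ND = %.2f", object$bpnd))
  if (!is.null(object$fitted)) {
    p <- p + ggplot2::geom_line(data = object$fitted, colour = "red")
  }
  p
}
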