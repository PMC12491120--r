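#' Fit a longitudinal linear mixed-effects model
#'
#' REML fit of a trajectory model with random intercepts, the statistical
#' workhorse for biomarker fold-change series: e.g.
#' `pct_change ~ day + I(day^2) + I(day^3) + (1 | patient_id)`.
#' Inference on fixed effects uses t-statistics on residual degrees of
#' freedom (n_obs - n fixed effects), with 95% confidence intervals from the
#' same t distribution; this matches the default of the era's common mixed-
#' model tooling and deliberately avoids Satterthwaite approximations. Rows
#' with missing response or predictors are dropped and counted. If the model
#' has no estimable random variation (e.g. a zero-noise degenerate cohort),
#' the fit falls back to ordinary least squares, which is the exact limit of
#' the mixed model there; the `engine` field records which path was used.
#'
#' @param data A data frame (long visit or trajectory table).
#' @param formula An lme4-style formula with exactly the fixed terms wanted
#'   and `(1 | group)` random intercepts.
#' @param reml Use REML (default) or ML.
#' @return A `psma_lme` object; `tidy()` returns the fixed-effect table,
#'   `glance()` the fit summary, `varcomp(fit)` the variance components.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 12, seed = 7))
#' traj <- compute_fold_changes(coh)
#' adc <- dplyr::filter(traj, metric == "ADC", day > 0)
#' fit_lme(adc, pct_change ~ day + (1 | patient_id))
#' @export
fit_lme <- function(data, formula, reml = TRUE) {
  fixed_form <- lme4::nobars(formula)
  has_bars <- !is.null(lme4::findbars(formula))
  resp <- all.vars(fixed_form)[1]
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("Variables not in `data`: ", paste(missing_vars, collapse = ", ")))
  }
  keep <- stats::complete.cases(data[vars])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]

  X <- model.matrix(fixed_form, d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    abort(paste0("Singular fixed-effect design; collinear terms: ",
                 paste(bad, collapse = ", ")))
  }
  p <- ncol(X)
  n <- nrow(d)
  if (n < p) abort("Fewer observations than fixed effects.")

  fit <- NULL
  engine <- "lmer"
  if (has_bars) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(formula, data = d, REML = reml))),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    engine <- "lm"
    fit <- lm(fixed_form, data = d)
  }

  if (engine == "lmer") {
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- tibble(group = vc$grp, variance = vc$vcov)
    n_groups <- min(vapply(lme4::getME(fit, "flist"),
                           function(f) length(levels(f)), integer(1)))
  } else {
    beta <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    varcomp <- tibble(group = c("(random)", "Residual"),
                      variance = c(0, summary(fit)$sigma^2))
    n_groups <- NA_integer_
  }
  df <- n - p
  tstat <- beta / se
  pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  crit <- qt(0.975, df)
  fixed <- tibble(term = names(beta), estimate = unname(beta),
                  std.error = unname(se), df = df,
                  statistic = unname(tstat), p.value = unname(pval),
                  conf.low = unname(beta - crit * se),
                  conf.high = unname(beta + crit * se))
  structure(list(fixed = fixed, varcomp = varcomp, n_obs = n,
                 n_groups = n_groups, n_dropped = n_dropped, reml = reml,
                 engine = engine, formula = formula, fit = fit,
                 converged = TRUE),
            class = "psma_lme")
}

#' Variance components of a mixed-model fit
#' @param fit A `psma_lme`.
#' @return Tibble `group`, `variance`.
#' @export
varcomp <- function(fit) fit$varcomp

#' @export
print.psma_lme <- function(x, ...) {
  cat("Linear mixed-effects fit (", x$engine,
      if (x$reml) ", REML" else ", ML", "); n_obs = ", x$n_obs,
      if (!is.na(x$n_groups)) paste0(", n_groups = ", x$n_groups), "\n", sep = "")
  print(x$fixed, n = Inf)
  cat("Variance components:\n")
  print(x$varcomp)
  invisible(x)
}

#' @rdname fit_lme
#' @param x,object A `psma_lme` object.
#' @param ... Unused.
#' @method tidy psma_lme
#' @export
tidy.psma_lme <- function(x, ...) x$fixed

#' @rdname fit_lme
#' @method glance psma_lme
#' @export
glance.psma_lme <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_groups = x$n_groups, n_dropped = x$n_dropped,
         reml = x$reml, engine = x$engine,
         sigma2_residual = x$varcomp$variance[x$varcomp$group == "Residual"])
}

#' Marginal F-tests of the fixed effects
#'
#' Per-coefficient Wald F-statistics (the squared residual-df t-statistics,
#' df1 = 1) with p-values on residual degrees of freedom.
#'
#' @param fit A converged `psma_lme`.
#' @return Tibble `term`, `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
anova_fixed <- function(fit) {
  if (!inherits(fit, "psma_lme")) abort("`fit` must be a psma_lme.")
  if (!isTRUE(fit$converged)) abort("Cannot run ANOVA on a non-converged fit.")
  with(fit$fixed,
       tibble(term = term, statistic = statistic^2, df1 = 1, df2 = df,
              p.value = stats::pf(statistic^2, 1, df, lower.tail = FALSE)))
}

#' Plot fitted fixed-effect trajectory over the data
#'
#' Draws the observed response against the first fixed-effect covariate with
#' the population-level fitted curve.
#'
#' @param object A `psma_lme` fitted with a single continuous time variable
#'   (possibly with polynomial terms).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psma_lme
#' @export
autoplot.psma_lme <- function(object, ...) {
  fixed_form <- lme4::nobars(object$formula)
  vars <- all.vars(fixed_form)
  resp <- vars[1]; xvar <- vars[2]
  d <- if (object$engine == "lmer") lme4::getME(object$fit, "X") else NULL
  mf <- stats::model.frame(fixed_form,
                           if (object$engine == "lmer")
                             object$fit@frame else object$fit$model)
  xs <- seq(min(mf[[xvar]]), max(mf[[xvar]]), length.out = 100)
  nd <- setNames(data.frame(xs), xvar)
  Xp <- model.matrix(stats::delete.response(stats::terms(fixed_form)), nd)
  pred <- as.numeric(Xp %*% object$fixed$estimate)
  ggplot2::ggplot(mf, ggplot2::aes(.data[[xvar]], .data[[resp]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = data.frame(x = xs, y = pred),
                       ggplot2::aes(.data$x, .data$y),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = xvar, y = resp)
}
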