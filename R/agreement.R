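#' Repeated-measures agreement: bias and limits of agreement
#'
#' Bland--Altman-style agreement between two biomarker-change series with
#' repeated measures per lesion. The per-observation difference
#' d = value1 - value2 is modelled as `d ~ 1 + (1 | group)`; the bias is the
#' fixed intercept and the 95% limits of agreement are
#' bias +/- 1.96 * sqrt(sigma2_group + sigma2_residual), so both the
#' between-lesion and within-lesion spread of the disagreement widen the
#' limits. When the differences carry no variance (identical series, or a
#' pure constant offset) the limits collapse onto the bias.
#'
#' @param pairs Data frame of paired observations.
#' @param value1,value2 Columns holding the two methods' values (tidy-eval),
#'   e.g. ΔSUV% and ΔBP_ND%.
#' @param group Column identifying the repeated-measures unit (lesion).
#' @return One-row tibble: `bias`, `loa_low`, `loa_high`, `sigma2_group`,
#'   `sigma2_residual`, `n_pairs`.
#' @export
agreement_lme <- function(pairs, value1, value2, group) {
  v1 <- dplyr::pull(pairs, {{ value1 }})
  v2 <- dplyr::pull(pairs, {{ value2 }})
  g <- dplyr::pull(pairs, {{ group }})
  ok <- is.finite(v1) & is.finite(v2) & !is.na(g)
  d <- (v1 - v2)[ok]; g <- factor(g[ok])
  if (length(unique(g)) < 2) abort("Agreement needs at least 2 lesions.")
  if (sd(d) < 1e-12) {
    bias <- mean(d); s2g <- 0; s2e <- 0
  } else {
    dd <- data.frame(d = d, g = g)
    m <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(d ~ 1 + (1 | g), data = dd, REML = TRUE))),
      error = function(e) NULL)
    if (is.null(m)) {
      bias <- mean(d); s2g <- 0; s2e <- var(d)
    } else {
      bias <- unname(lme4::fixef(m)[1])
      vc <- as.data.frame(lme4::VarCorr(m))
      s2g <- vc$vcov[vc$grp == "g"]
      s2e <- vc$vcov[vc$grp == "Residual"]
    }
  }
  hw <- 1.96 * sqrt(s2g + s2e)
  tibble(bias = bias, loa_low = bias - hw, loa_high = bias + hw,
         sigma2_group = s2g, sigma2_residual = s2e, n_pairs = length(d))
}

#' Generalized concordance correlation coefficient
#'
#' Agreement between two measurement methods with repeated measures, by the
#' variance-components estimator: the long-format model
#' `value ~ method + (1 | subject)` is fitted by REML and
#' \deqn{CCC = \sigma^2_{subject} / (\sigma^2_{subject} + s^2_{method} +
#'   \sigma^2_{residual}),}
#' where \eqn{s^2_{method}} is the squared method fixed-effect difference
#' divided by 2. Each paired observation (here: a lesion-visit) is one
#' subject. When the grouping is degenerate (the mixed model fails or the
#' subject variance collapses to zero), Lin's sample CCC
#' \eqn{2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)} is reported
#' instead (it can be negative for anticorrelated methods); the `estimator`
#' field records which path was used.
#'
#' @param pairs Data frame of paired observations (>= 3 pairs).
#' @param value1,value2 Columns holding the two methods' values (tidy-eval).
#' @return One-row tibble: `ccc`, `estimator` ("variance_components" or
#'   "lin"), `n_pairs`.
#' @export
concordance_correlation <- function(pairs, value1, value2) {
  x <- dplyr::pull(pairs, {{ value1 }})
  y <- dplyr::pull(pairs, {{ value2 }})
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Concordance needs at least 3 pairs.")
  if (var(c(x, y)) < 1e-24) abort("Zero total variance: concordance undefined.")
  long <- data.frame(value = c(x, y),
                     method = rep(c("m1", "m2"), each = n),
                     subject = factor(rep(seq_len(n), 2)))
  m <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ method + (1 | subject), data = long, REML = TRUE))),
    error = function(e) NULL)
  use_lin <- is.null(m)
  if (!use_lin) {
    vc <- as.data.frame(lme4::VarCorr(m))
    s2s <- vc$vcov[vc$grp == "subject"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    s2m <- unname(lme4::fixef(m)["methodm2"])^2 / 2
    tot <- s2s + s2m + s2e
    use_lin <- !is.finite(s2s) || s2s <= 1e-10 * max(tot, 1e-300)
  }
  if (use_lin) {
    sxy <- mean((x - mean(x)) * (y - mean(y)))
    sx2 <- mean((x - mean(x))^2)
    sy2 <- mean((y - mean(y))^2)
    ccc <- 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
    return(tibble(ccc = ccc, estimator = "lin", n_pairs = n))
  }
  tibble(ccc = s2s / tot, estimator = "variance_components", n_pairs = n)
}
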