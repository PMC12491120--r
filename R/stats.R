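#' Percent fold change from baseline
#'
#' \eqn{100 (x_{follow} - x_{base}) / x_{base}}: declines are negative,
#' increases positive.
#'
#' @param baseline,followup Numeric vectors (baseline != 0).
#' @return Percent change, same length as the longer input.
#' @examples
#' fold_change(59.0, 6.9) # -88.3
#' @export
fold_change <- function(baseline, followup) {
  if (any(baseline == 0, na.rm = TRUE)) abort("Baseline value of 0: fold change undefined.")
  100 * (followup - baseline) / baseline
}

#' Median and interquartile range
#'
#' Quantiles use midpoint plotting positions (k - 0.5)/n with linear
#' interpolation (`stats::quantile` type 5).
#'
#' @param values Numeric vector; NAs dropped.
#' @return One-row tibble: `median`, `q1`, `q3`, `n`.
#' @examples
#' median_iqr(c(1, 2, 3)) # median 2, q1 1.25, q3 2.75
#' @export
median_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) abort("No finite values.")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 5))
  tibble(median = q[2], q1 = q[1], q3 = q[3], n = length(values))
}

#' Fold-change table from a long visit table
#'
#' Joins each follow-up value to its own series baseline (day 0, same
#' patient/lesion/metric) and computes the percent change. Series without a
#' baseline, or with baseline 0, are dropped with a message.
#'
#' @param records Long tibble: `patient_id`, `lesion_id`, `day`, `metric`,
#'   `value`.
#' @param exclude_patients Character vector of patient IDs to drop before
#'   computing changes (e.g. PET-negative patients for imaging metrics);
#'   exclusions are explicit, never inferred.
#' @return Tibble `patient_id`, `lesion_id`, `day`, `metric`, `value`,
#'   `pct_change` (0 at day 0 by construction).
#' @export
compute_fold_changes <- function(records, exclude_patients = character()) {
  d <- dplyr::filter(records, !.data$patient_id %in% exclude_patients)
  base <- d |>
    dplyr::filter(.data$day == 0) |>
    dplyr::select("patient_id", "lesion_id", "metric", baseline = "value")
  out <- d |>
    dplyr::left_join(base, by = c("patient_id", "lesion_id", "metric"))
  n_drop <- sum(is.na(out$baseline) | out$baseline == 0)
  if (n_drop > 0) {
    rlang::inform(sprintf("Dropping %d rows without a usable baseline.", n_drop))
    out <- dplyr::filter(out, !is.na(.data$baseline), .data$baseline != 0)
  }
  out |>
    dplyr::mutate(pct_change = fold_change(.data$baseline, .data$value)) |>
    dplyr::select(-"baseline")
}

#' Group-level trajectory summary (median and IQR per metric and day)
#'
#' Applies [median_iqr()] to the percent changes of every metric at every
#' follow-up day (day 0 is identically zero and excluded). Rows with missing
#' `pct_change` are dropped.
#'
#' @param trajectories Tibble with `metric`, `day`, `pct_change` (from
#'   [compute_fold_changes()]).
#' @return Tidy tibble: `metric`, `day`, `median`, `q1`, `q3`, `n`.
#' @export
summarize_trajectories <- function(trajectories) {
  if (nrow(trajectories) == 0) abort("Empty trajectory table.")
  trajectories |>
    dplyr::filter(.data$day > 0, is.finite(.data$pct_change)) |>
    dplyr::group_by(.data$metric, .data$day) |>
    dplyr::reframe(median_iqr(.data$pct_change)) |>
    dplyr::arrange(.data$metric, .data$day)
}

#' Spaghetti plot of biomarker fold-change trajectories
#'
#' One line per series (patient or lesion), faceted by metric, with the
#' group median overlaid.
#'
#' @param trajectories Output of [compute_fold_changes()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories) {
  d <- dplyr::mutate(trajectories,
                     series = dplyr::coalesce(.data$lesion_id, .data$patient_id))
  med <- d |>
    dplyr::group_by(.data$metric, .data$day) |>
    dplyr::summarise(pct_change = median(.data$pct_change, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$day, .data$pct_change,
                                  group = .data$series)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(data = med, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Days on treatment", y = "Change from baseline (%)")
}
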