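#' Build a study pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: where the visit table comes
#' from (simulated cohort, CSV on disk, or the packaged PSA table), explicit
#' patient exclusions for imaging-based summaries, which models to fit, an
#' optional imaging demonstration arm (dynamic phantom -> segmentation ->
#' TAC -> SRTM per visit), and the global seed recorded in every output.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param cohort List: `source` one of "simulate", "csv", "psa_fixture";
#'   `config` a [cohort_config()] when simulating; `path` when reading CSV
#'   (columns patient_id, lesion_id, day, metric, value).
#' @param exclude_patients Patient IDs excluded from fold-change summaries.
#' @param models Character subset of
#'   `c("psa-linear", "bpnd-cubic", "bpnd-extended", "agreement")`.
#' @param imaging Optional list with `visits`: a list of per-visit lists,
#'   each with `day`, `truth` (R1, k2, bpnd) and `seed_vox` (lesion seed
#'   voxel for segmentation); and optionally `noise_scale`.
#' @return A validated `study_config` list.
#' @export
study_config <- function(out_dir, seed = 1L,
                         cohort = list(source = "simulate",
                                       config = cohort_config(seed = seed)),
                         exclude_patients = character(),
                         models = c("psa-linear", "bpnd-cubic",
                                    "bpnd-extended", "agreement"),
                         imaging = NULL) {
  if (!cohort$source %in% c("simulate", "csv", "psa_fixture")) {
    abort("cohort$source must be 'simulate', 'csv' or 'psa_fixture'.")
  }
  if (cohort$source == "csv" && !file.exists(cohort$path)) {
    abort(paste0("Cohort CSV not found: ", cohort$path))
  }
  bad <- setdiff(models, c("psa-linear", "bpnd-cubic", "bpnd-extended",
                           "agreement"))
  if (length(bad) > 0) abort(paste0("Unknown models: ", paste(bad, collapse = ", ")))
  if (!is.null(imaging)) {
    for (v in imaging$visits) {
      if (is.null(v$day)) abort("Every imaging visit needs a `day`.")
      if (is.null(v$seed_vox)) {
        abort(paste0("Imaging visit at day ", v$day,
                     " is missing its lesion seed point (`seed_vox`)."))
      }
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 exclude_patients = exclude_patients, models = models,
                 imaging = imaging),
            class = "study_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- acquire visit table, optional imaging
#' demonstration, fold changes and group summaries, mixed-effects trajectory
#' models, agreement analysis -- writing per-stage artifacts under
#' `config$out_dir`: `visits.csv`, `trajectories.csv`,
#' `summary_by_day.csv` (group medians/IQRs), `models.json`,
#' `agreement.json`, `imaging_quant.csv` (if imaging requested) and
#' `provenance.json` (package version, seed, config hash). Re-running with
#' an identical config reproduces identical numeric outputs.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with the in-memory results (`visits`,
#'   `trajectories`, `summary`, `models`, `agreement`, `imaging`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "study_config")) abort("`config` must be a study_config.")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  ## stage 1: visit table
  visits <- switch(config$cohort$source,
    simulate = generate_cohort(config$cohort$config),
    csv = as_tibble(utils::read.csv(config$cohort$path,
                                    stringsAsFactors = FALSE)),
    psa_fixture = dplyr::select(load_psa_fixture(), -"pet_negative"))
  utils::write.csv(visits, file.path(config$out_dir, "visits.csv"),
                   row.names = FALSE)

  ## stage 2: imaging demonstration arm
  imaging <- NULL
  if (!is.null(config$imaging)) {
    imaging <- run_imaging_stage(config)
    utils::write.csv(imaging, file.path(config$out_dir, "imaging_quant.csv"),
                     row.names = FALSE)
  }

  ## stage 3: fold changes and group summary
  traj <- suppressMessages(
    compute_fold_changes(visits, exclude_patients = config$exclude_patients))
  utils::write.csv(traj, file.path(config$out_dir, "trajectories.csv"),
                   row.names = FALSE)
  summ <- summarize_trajectories(traj)
  utils::write.csv(summ, file.path(config$out_dir, "summary_by_day.csv"),
                   row.names = FALSE)

  ## stage 4: trajectory models
  models <- list()
  ## day-0 rows (identically zero change) stay in the trajectory models:
  ## with the 4-day visit grid they are what identifies the intercept of the
  ## cubic time polynomial
  wide <- traj |>
    dplyr::select("patient_id", "lesion_id", "day", "metric", "pct_change") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "pct_change")
  if ("psa-linear" %in% config$models && "PSA" %in% traj$metric) {
    psa <- dplyr::filter(traj, .data$metric == "PSA")
    models$psa_linear <- fit_lme(psa, pct_change ~ day + (1 | patient_id))
  }
  if ("bpnd-cubic" %in% config$models && "BPND" %in% traj$metric) {
    bp <- dplyr::filter(traj, .data$metric == "BPND")
    models$bpnd_cubic <- fit_lme(
      bp, pct_change ~ day + I(day^2) + I(day^3) + (1 | patient_id))
  }
  if ("bpnd-extended" %in% config$models &&
      all(c("BPND", "ADC") %in% traj$metric)) {
    ## in degenerate cohorts ΔADC% can be exactly collinear with time;
    ## the extended model is then skipped rather than aborting the run
    models$bpnd_extended <- tryCatch(
      fit_lme(wide, BPND ~ day + I(day^2) + I(day^3) + ADC + (1 | patient_id)),
      error = function(e) {
        rlang::warn(paste("Extended model skipped:", conditionMessage(e)))
        NULL
      })
  }
  models <- models[!vapply(models, is.null, logical(1))]
  if (length(models) > 0) {
    jsonlite::write_json(
      lapply(models, function(m) list(fixed = tidy(m), varcomp = varcomp(m),
                                      glance = glance(m))),
      file.path(config$out_dir, "models.json"), dataframe = "rows",
      auto_unbox = TRUE, digits = NA, na = "null")
  }

  ## stage 5: agreement between static and dynamic PET response metrics
  agreement <- NULL
  if ("agreement" %in% config$models &&
      all(c("BPND", "SUVpeak") %in% traj$metric)) {
    pr <- dplyr::filter(wide, .data$day > 0, is.finite(.data$SUVpeak),
                        is.finite(.data$BPND))
    agreement <- list(
      bland_altman = agreement_lme(pr, SUVpeak, BPND, lesion_id),
      ccc = concordance_correlation(pr, SUVpeak, BPND))
    jsonlite::write_json(agreement,
                         file.path(config$out_dir, "agreement.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }

  ## provenance
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  jsonlite::write_json(
    list(package = "psmadyn",
         version = as.character(utils::packageVersion("psmadyn")),
         seed = config$seed, config_hash = cfg_hash,
         stages = c("visits", if (!is.null(imaging)) "imaging",
                    "trajectories", "models",
                    if (!is.null(agreement)) "agreement")),
    file.path(config$out_dir, "provenance.json"), auto_unbox = TRUE)

  invisible(list(visits = visits, trajectories = traj, summary = summ,
                 models = models, agreement = agreement, imaging = imaging))
}

## phantom -> segment -> extract -> SRTM, one row per imaging visit
run_imaging_stage <- function(config) {
  cp <- make_input_function()
  ref <- simulate_reference_tac(cp)
  rows <- list()
  for (v in config$imaging$visits) {
    les <- simulate_lesion_tac_srtm(ref, v$truth)
    ph <- generate_dynamic_phantom(les, ref,
                                   noise_scale = v$noise_scale %||% 0,
                                   seed = config$seed + round(v$day))
    mask <- segment_lesion_40pct(apply(ph$image$data, 1:3, mean), v$seed_vox,
                                 search_radius_mm = 15,
                                 voxel_size_mm = ph$image$voxel_size_mm)
    tac <- extract_tac(ph$image, mask)
    fit <- fit_srtm(tac, extract_tac(ph$image, ph$reference_mask))
    rows[[length(rows) + 1]] <- tibble(
      day = v$day, true_bpnd = v$truth$bpnd, est_bpnd = fit$bpnd,
      est_R1 = fit$R1, est_k2 = fit$k2, converged = fit$converged,
      n_mask_voxels = sum(mask))
  }
  dplyr::bind_rows(rows)
}
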