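#!/usr/bin/env Rscript
# Thin shell entry point over psmadyn::run_pipeline(). Usage:
#   Rscript scripts/pipeline.R --out-dir <dir> [--seed <int>]
#       [--source simulate|psa_fixture|csv] [--cohort-csv <path>]
#       [--n-patients <int>] [--exclude-patients P2,P5]

suppressMessages(library(psmadyn))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

seed <- as.integer(get_arg("--seed", "1"))
source <- get_arg("--source", "simulate")
out_dir <- get_arg("--out-dir", "pipeline_out")
excl <- get_arg("--exclude-patients", "")
excl <- if (nzchar(excl)) strsplit(excl, ",")[[1]] else character()

cohort <- switch(source,
  simulate = list(source = "simulate", config = cohort_config(
    n_patients = as.integer(get_arg("--n-patients", "8")), seed = seed)),
  psa_fixture = list(source = "psa_fixture"),
  csv = list(source = "csv", path = get_arg("--cohort-csv", "cohort.csv")))

cfg <- study_config(out_dir = out_dir, seed = seed, cohort = cohort,
                    exclude_patients = excl)
res <- run_pipeline(cfg)
cat("Pipeline complete:", out_dir, "\n")
print(res$summary, n = Inf)
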