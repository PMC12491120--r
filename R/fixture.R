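#' Packaged serum-PSA series of the 8-patient study cohort
#'
#' Per-patient serum PSA (ng/mL) at treatment days 0, 7, 21 and 28 after the
#' start of first-generation nonsteroidal antiandrogen, as printed in the
#' study's baseline table. Week labels map to days as w1 = 7, w3 = 21,
#' w4 = 28. Two patients have missing week-1 and week-3 draws (explicit
#' `NA`); one patient remained PSMA-PET-negative throughout and is flagged so
#' that imaging-based summaries can exclude it explicitly.
#'
#' @return Tibble with 32 rows (8 patients x 4 days): `patient_id`,
#'   `lesion_id` (all `NA`; PSA is a per-patient metric), `day`, `metric`
#'   ("PSA"), `value` (ng/mL), `pet_negative`.
#' @examples
#' psa <- load_psa_fixture()
#' dplyr::filter(psa, patient_id == "P4", day == 0)$value # 59.0
#' @export
load_psa_fixture <- function() {
  path <- system.file("extdata", "table1_psa.csv", package = "psmadyn",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble(patient_id = d$patient_id, lesion_id = NA_character_,
         day = as.numeric(d$day), metric = "PSA",
         value = as.numeric(d$psa_ng_ml),
         pet_negative = as.logical(d$pet_negative))
}
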