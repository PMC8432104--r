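#' Anthropometric records of the study cohort
#'
#' The printed anthropometrics (gender, age, weight, height) of the ten
#' patients and ten matched healthy controls, shipped as a plain-text
#' fixture. These columns fully reproduce the published group comparisons
#' (pooled t-test: age p = 0.801, height p = 0.851).
#'
#' @return `data.frame` with `pair`, `group`, `gender`, `age_y`,
#'   `weight_kg`, `height_cm`.
#' @export
copd_anthropometrics <- function() {
  read.csv(system.file("extdata", "table1_anthropometrics.csv",
                       package = "spectromyo"),
           stringsAsFactors = FALSE)
}

#' Clinical lung-function records of the patients
#'
#' Per-patient spirometry and symptom scores: FEV1, FVC (percent predicted),
#' FEV1/FVC (percent), D_LCO (percent predicted), mMRC (0-4) and GOLD group,
#' with `patient_id` keys `P01..P10` matching the synthetic cohort's COPD
#' participant ids so the severity-regression layer can be exercised on
#' synthetic features (a synthetic pairing, not a clinical claim).
#'
#' @return `data.frame` of clinical records.
#' @export
copd_clinical <- function() {
  x <- read.csv(system.file("extdata", "table2_clinical.csv",
                            package = "spectromyo"),
                stringsAsFactors = FALSE)
  stopifnot(all(x$FEV1 >= 0), all(x$mMRC %in% 0:4))
  x
}
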