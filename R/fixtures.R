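#' The 12 published basal-marker-positive cases
#'
#' Clinicopathological characteristics of the 12 basal-marker-positive
#' cases of the source cohort, transcribed from the published case tables:
#' IHC and molecular (expression-based) subtype, per-marker CK5/6, EGFR and
#' CK14 status, Ki-67/PR/ER percentages, grade, P53, immune group, TILs
#' level, ROR risk class and recurrence/metastasis outcome.
#'
#' Three cases (4, 8, 9) had ambiguously concatenated numeric columns in
#' the published layout; the fixed column order determines the transcription
#' used here and those rows carry `ambiguous_parse = TRUE`. The printed IHC
#' subtype label is kept verbatim in `ihc_subtype_printed`; note that for
#' case 7 the printed label (LumB) disagrees with the stated surrogate rule
#' (Ki-67 = 30 is "low", PR = 90), so rule-based calls from
#' [modifiedIHCSubtype()] can differ from that column.
#'
#' @return data.frame of 12 rows.
#' @examples
#' nrow(table3Fixture())  # 12
#' @export
table3Fixture <- function() {
  path <- system.file("extdata", "table3_cases.csv", package = "lumityper",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published subtype-by-risk-class distribution
#'
#' The published cross-tabulation of intrinsic subtype against ROR and RS
#' risk class for the 87-patient source cohort (counts per subtype row:
#' low/medium/high under each score).
#'
#' @return data.frame with one row per subtype and columns `n`,
#'   `ror_low/medium/high`, `rs_low/medium/high`.
#' @examples
#' sum(table2Fixture()$n)  # 87
#' @export
table2Fixture <- function() {
  path <- system.file("extdata", "table2_risk_class.csv",
                      package = "lumityper", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
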