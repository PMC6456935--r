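#' Clinical annotations of the untreated apical-periodontitis patients
#'
#' The published clinical table for the 23 untreated (NRCT) patients of
#' the root-apex cohort whose structure this package's simulator
#' defaults emulate: per-patient gender, age, radiographic lesion
#' dimension string, the clinical LSA/SSA lesion-size level, and the A/B
#' community cluster each sample was assigned to. It serves as a real
#' worked input for the lesion parser and the cluster-label concordance
#' machinery: counting the printed columns directly gives 9 A-and-LSA
#' plus 10 B-and-SSA agreements, i.e. an accuracy of 19/23.
#'
#' @return A tibble with columns `sample_id`, `gender`, `age`, `lesion`,
#'   `level`, `cluster`.
#' @examples
#' clin <- nrct_clinical()
#' concordance(
#'   clin[, c("sample_id", "cluster")],
#'   data.frame(sample_id = clin$sample_id, label = clin$level)
#' )
#' @export
nrct_clinical <- function() {
  path <- system.file("extdata", "nrct_clinical.tsv", package = "apexbiome",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "cciccc", col_names = TRUE,
                  locale = readr::locale(encoding = "UTF-8"))
}
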