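#' Published summary statistics for the study-area soils
#'
#' The printed per-parameter summary table for the 51 study-area soil
#' samples: minimum, median, maximum, arithmetic mean and SD, geometric mean
#' and (multiplicative) SD, regional background value (BV), soil screening
#' value (SV) and the printed coefficient of variation. Shipped as package
#' data so the published contamination indices can be recomputed without the
#' raw per-sample data (which were not deposited).
#'
#' Two rows are known to carry typographical inconsistencies in the source
#' table and are kept verbatim: the DCB-Al and DCB-Fe minima (146 and 537,
#' inconsistent with their means; presumably 0.146/0.537 g/kg), and the
#' metal-row `cv_printed` values, which do not equal `sd_arith / mean_arith`
#' from the same row. No auto-correction is applied.
#'
#' @return data.frame with one row per soil parameter.
#' @export
study_soil_summary <- function() {
  path <- system.file("extdata", "study_soil_summary.csv",
                      package = "vegrisk", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
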