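#' Bundled reference cluster case tables
#'
#' Published per-case ventricular measurements of the two rare
#' pathological clusters found in a 3,822-case population imaging cohort:
#' an 11-case right-ventricular-abnormality cluster (RV end-diastolic
#' volume and RV ejection fraction) and a 4-case dilated-cardiomyopathy
#' cluster (LV end-diastolic volume and LV ejection fraction, with the
#' cohort's reference-channel re-measurements).  Ejection fractions are
#' stored as fractions.  Useful as worked examples for the threshold rule
#' engine.
#'
#' @param which \code{"rva"} or \code{"dcm"}.
#' @return data.frame of the requested table.
#' @export
#' @examples
#' rva <- referenceClusterCases("rva")
#' sum(ruleRVA(rva$V_RV_ED, rva$EF_RV))   # all 11
referenceClusterCases <- function(which = c("rva", "dcm")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_cluster_cases.csv"),
                      package = "cardioclust", mustWork = TRUE)
  read.csv(path, colClasses = c(case_id = "character"))
}
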