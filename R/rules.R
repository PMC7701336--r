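# ACDC-style threshold rule engine.  All inequalities are strict
# ("higher than" / "lower than"): values exactly at a threshold do not
# trigger.  Ejection fractions are fractions in (0, 1); volumes are
# BSA-indexed mL/m^2; thickness is mm.

#' Pathology threshold rules
#'
#' Vectorized ACDC-style rules:
#' \itemize{
#'   \item RVA (right-ventricular abnormality): RV end-diastolic volume
#'     above 110 mL/m^2 OR RV ejection fraction below 0.40.
#'   \item DCM (dilated cardiomyopathy): LV end-diastolic volume above
#'     100 mL/m^2 AND LV ejection fraction below 0.40.
#'   \item HCM (hypertrophic cardiomyopathy), surrogate rule: maximal
#'     myocardial thickness above 15 mm AND preserved LV ejection fraction
#'     (at least 0.50).  The full definition also requires LV mass, which
#'     the nine-feature set does not carry; the surrogate uses the
#'     thickness and normal-EF criteria only.
#' }
#'
#' @param vRvEd,efRv,vLvEd,efLv,mt numeric vectors (recycled per rule).
#' @return Logical vector.
#' @export
#' @examples
#' ruleRVA(c(133.13, 80), c(0.6361, 0.60))   # TRUE FALSE
ruleRVA <- function(vRvEd, efRv) {
  .checkEF(efRv, "EF_RV")
  vRvEd > 110 | efRv < 0.40
}

#' @rdname ruleRVA
#' @export
ruleDCM <- function(vLvEd, efLv) {
  .checkEF(efLv, "EF_LV")
  vLvEd > 100 & efLv < 0.40
}

#' @rdname ruleRVA
#' @export
ruleHCM <- function(mt, efLv) {
  .checkEF(efLv, "EF_LV")
  mt > 15 & efLv >= 0.50
}

.checkEF <- function(ef, what) {
  if (any(ef <= 0 | ef >= 1))
    stop(what, " must lie strictly in (0, 1); values like 66.41 look ",
         "like percentages")
  invisible(TRUE)
}

#' Classify cases by the pathology threshold rules
#'
#' Applies the RVA, DCM and HCM rules to each case of a nine-feature
#' table.  The LV end-diastolic volume (not itself a feature) is
#' reconstructed from the stored identity EF_LV = 1 - V_LV_ES / V_LV_ED,
#' i.e. V_LV_ED = V_LV_ES / (1 - EF_LV).  Cases with a low LV ejection
#' fraction (< 0.40) but non-dilated LV receive an advisory note (possible
#' myocardial-infarction physiology, which the scalar features cannot
#' establish) and no label.  A case triggering no rule is normal (NOR).
#'
#' @param x a \linkS4class{CardioCohort} or a data.frame/matrix with the
#'   nine canonical feature columns (a \code{case_id} column is carried
#'   through if present).
#' @return data.frame with case_id, the derived \code{V_LV_ED}, logical
#'   columns RVA/DCM/HCM, \code{is_NOR}, a combined \code{labels} string
#'   and an advisory \code{note}.
#' @export
#' @examples
#' coh <- simulateCohort(cohortSimConfig(nTotal = 400), seed = 1)
#' table(classifyCases(coh)$labels)
classifyCases <- function(x) {
  if (is(x, "CardioCohort")) {
    tab <- featureTable(x)
  } else {
    tab <- as.data.frame(x)
    if (!"case_id" %in% colnames(tab))
      tab <- data.frame(case_id = sprintf("case_%05d", seq_len(nrow(tab))),
                        tab)
  }
  miss <- setdiff(.FEATURES, colnames(tab))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  .checkEF(tab$EF_LV, "EF_LV")
  if (any(tab$EF_LV == 1))
    stop("EF_LV = 1: V_LV_ED cannot be derived")
  vLvEd <- tab$V_LV_ES / (1 - tab$EF_LV)
  rva <- ruleRVA(tab$V_RV_ED, tab$EF_RV)
  dcm <- ruleDCM(vLvEd, tab$EF_LV)
  hcm <- ruleHCM(tab$MT_LVM_ED, tab$EF_LV)
  labels <- vapply(seq_len(nrow(tab)), function(i)
    paste(c("RVA", "DCM", "HCM")[c(rva[i], dcm[i], hcm[i])],
          collapse = "+"), character(1))
  note <- ifelse(tab$EF_LV < 0.40 & vLvEd <= 100,
                 "low LV EF without dilation; possible MINF", "")
  data.frame(case_id = tab$case_id, V_LV_ED = vLvEd, RVA = rva, DCM = dcm,
             HCM = hcm, is_NOR = !(rva | dcm | hcm), labels = labels,
             note = note, row.names = NULL)
}

#' Label clusters by member rule satisfaction
#'
#' For every cluster, computes the fraction of members satisfying each
#' pathology rule.  Under the default policy only small clusters (size at
#' most \code{smallThreshold}) can receive a pathological label: a small
#' cluster is labeled with the pathology of highest satisfaction fraction
#' provided that fraction reaches \code{minFrac}; every other cluster is
#' UNLABELED.  Pathology in a general population is rare, so a large
#' cluster satisfying a rule wholesale would indicate a miscalibrated rule
#' rather than a pathological cluster; \code{labelLarge = TRUE} disables
#' the gate.
#'
#' @param assignments integer cluster ids covering all cases.
#' @param x the feature table (\code{CardioCohort} or data.frame).
#' @param smallThreshold small-cluster size gate, typically
#'   \code{\link{smallClusterThreshold}(n)}.
#' @param minFrac minimal member satisfaction fraction in (0, 1].
#' @param labelLarge allow labeling large clusters too.
#' @return A \linkS4class{ClusterLabeling}.
#' @export
labelClusters <- function(assignments, x, smallThreshold,
                          minFrac = 0.9, labelLarge = FALSE) {
  if (minFrac <= 0 || minFrac > 1) stop("minFrac must lie in (0, 1]")
  caseLabels <- classifyCases(x)
  assignments <- as.integer(assignments)
  if (length(assignments) != nrow(caseLabels))
    stop("assignments must cover all cases")
  ids <- sort(unique(assignments))
  pat <- c("DCM", "HCM", "RVA")   # tie order: alphabetical
  rows <- lapply(ids, function(cl) {
    mem <- assignments == cl
    fr <- vapply(pat, function(p) mean(caseLabels[[p]][mem]), numeric(1))
    size <- sum(mem)
    small <- size <= smallThreshold
    label <- "UNLABELED"
    if ((small || labelLarge) && max(fr) >= minFrac)
      label <- pat[which.max(fr)]
    data.frame(cluster = cl, size = size, small = small,
               frac_DCM = fr[["DCM"]], frac_HCM = fr[["HCM"]],
               frac_RVA = fr[["RVA"]], label = label)
  })
  new("ClusterLabeling", assignments = assignments,
      clusters = do.call(rbind, rows), caseLabels = caseLabels,
      smallThreshold = as.integer(smallThreshold), minFrac = minFrac)
}
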