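#' CardioCohort: a cohort of cardiac shape/motion features
#'
#' A \linkS4class{SummarizedExperiment} subclass holding the nine cardiac
#' features as a \code{features} assay (features x cases) with per-case
#' metadata in \code{colData}: simulated cohorts additionally carry the
#' latent physiological truth (\code{V_LV_ED}, subgroup and pathology
#' labels) and, when generated, a noisy reference measurement channel
#' (\code{gt_V_LV_ED}, \code{gt_V_LV_ES}, \code{gt_EF_LV},
#' \code{gt_is_outlier}).
#'
#' @slot .
#'   Inherits all slots from \code{SummarizedExperiment}.
#' @export
setClass("CardioCohort", contains = "SummarizedExperiment")

setValidity("CardioCohort", function(object) {
  msg <- character()
  if (!"features" %in% assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  else {
    m <- assay(object, "features")
    if (!identical(rownames(m), .FEATURES))
      msg <- c(msg, paste0("feature rows must be exactly: ",
                           paste(.FEATURES, collapse = ", ")))
    else {
      if (any(!is.finite(m)))
        msg <- c(msg, "all feature values must be finite")
      ef <- m[.EF_FEATURES, , drop = FALSE]
      if (length(ef) && (any(ef <= 0) || any(ef >= 1)))
        msg <- c(msg, paste0("ejection fractions must lie strictly in ",
                             "(0, 1); values that look like percentages ",
                             "(e.g. 66.41) must be divided by 100"))
      pos <- m[c("V_RV_ED", "V_LV_ES", "R_RVLV_ED", "R_LVMLV_ED",
                 "MT_LVM_ED"), , drop = FALSE]
      if (length(pos) && any(pos <= 0))
        msg <- c(msg, "volumes, ratios and thickness must be positive")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CardioCohort
#'
#' @param features Numeric matrix of feature values, either features x cases
#'   with rownames equal to \code{cohortFeatureNames()}, or its transpose
#'   (cases x features with those colnames).
#' @param colData Optional \code{DataFrame}/\code{data.frame} of per-case
#'   metadata.
#' @param metadata Optional list of cohort-level metadata.
#' @return A \linkS4class{CardioCohort}.
#' @export
#' @examples
#' m <- matrix(0.5, nrow = 9, ncol = 3,
#'             dimnames = list(cohortFeatureNames(), paste0("case_", 1:3)))
#' m["V_RV_ED", ] <- 80; m["V_LV_ES", ] <- 24
#' m["R_RVLV_ED", ] <- 1.1; m["R_LVMLV_ED", ] <- 0.65
#' m["MT_LVM_ED", ] <- 9; m["RMD", ] <- 1; m["TMD", ] <- 0.8
#' CardioCohort(m)
CardioCohort <- function(features, colData = NULL, metadata = list()) {
  features <- as.matrix(features)
  if (!is.null(colnames(features)) &&
      identical(colnames(features), .FEATURES))
    features <- t(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("case_%05d", seq_len(ncol(features)))
  if (is.null(colData))
    colData <- DataFrame(case_id = colnames(features),
                         row.names = colnames(features))
  se <- SummarizedExperiment(assays = list(features = features),
                             colData = colData, metadata = metadata)
  new("CardioCohort", se)
}

#' @describeIn CardioCohort Feature values as a cases x features matrix,
#'   the orientation expected by the statistical stages.
#' @param x A \code{CardioCohort}.
#' @param features Optional character vector selecting (and ordering)
#'   features.
#' @export
featureMatrix <- function(x, features = NULL) {
  stopifnot(is(x, "CardioCohort"))
  m <- t(assay(x, "features"))
  if (!is.null(features)) {
    bad <- setdiff(features, colnames(m))
    if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "))
    m <- m[, features, drop = FALSE]
  }
  m
}

#' @describeIn CardioCohort Feature table as a data.frame in canonical
#'   column order (\code{case_id} first), as written to CSV.
#' @export
featureTable <- function(x) {
  m <- featureMatrix(x)
  data.frame(case_id = rownames(m), m, row.names = NULL,
             check.names = FALSE)
}

#' @describeIn CardioCohort The reference ("ground-truth") measurement
#'   channel, or NULL if the cohort carries none.
#' @export
groundTruthTable <- function(x) {
  stopifnot(is(x, "CardioCohort"))
  cd <- colData(x)
  cols <- c("gt_V_LV_ED", "gt_V_LV_ES", "gt_EF_LV", "gt_is_outlier")
  if (!all(cols %in% colnames(cd))) return(NULL)
  data.frame(case_id = colnames(x), as.data.frame(cd[, cols]),
             row.names = NULL)
}

setMethod("show", "CardioCohort", function(object) {
  cat("CardioCohort with", ncol(object), "cases and", nrow(object),
      "features\n")
  if ("subgroup" %in% colnames(colData(object))) {
    tab <- table(colData(object)$subgroup)
    cat("subgroups:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  if (!is.null(groundTruthTable(object)))
    cat("reference measurement channel: present\n")
})

#' ScreeningReport: pairwise redundancy screen of the feature set
#'
#' Result of \code{\link{screenFeatures}}: pairwise Pearson and MIC
#' matrices, the pairs exceeding either threshold, and the resulting
#' dropped/selected feature lists.
#'
#' @slot featureNames character, features screened (original order).
#' @slot pearson symmetric correlation matrix.
#' @slot mic symmetric MIC matrix.
#' @slot pairs data.frame with one row per unordered feature pair
#'   (\code{feature_a}, \code{feature_b}, \code{r}, \code{mic},
#'   \code{flagged}, \code{trigger}).
#' @slot dropped,selected character feature lists (disjoint, union =
#'   \code{featureNames}).
#' @slot rThreshold,micThreshold numeric thresholds used.
#' @export
setClass("ScreeningReport",
         representation(featureNames = "character", pearson = "matrix",
                        mic = "matrix", pairs = "data.frame",
                        dropped = "character", selected = "character",
                        rThreshold = "numeric", micThreshold = "numeric"))

setValidity("ScreeningReport", function(object) {
  msg <- character()
  fn <- object@featureNames
  if (!setequal(c(object@selected, object@dropped), fn) ||
      length(intersect(object@selected, object@dropped)))
    msg <- c(msg, "selected and dropped must partition featureNames")
  if (!isTRUE(all.equal(unname(diag(object@pearson)),
                        rep(1, length(fn)))))
    msg <- c(msg, "pearson matrix diagonal must be 1")
  if (max(abs(object@mic - t(object@mic))) > 1e-12)
    msg <- c(msg, "mic matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScreeningReport Features retained for clustering.
#' @param x A \code{ScreeningReport}.
#' @export
selectedFeatures <- function(x) x@selected

#' @describeIn ScreeningReport Features removed as redundant.
#' @export
droppedFeatures <- function(x) x@dropped

#' @describeIn ScreeningReport Per-pair table (one row per unordered pair,
#'   the data behind an r-vs-MIC scatter).
#' @export
pairTable <- function(x) x@pairs

#' @describeIn ScreeningReport Pairs exceeding a threshold.
#' @export
flaggedPairs <- function(x) x@pairs[x@pairs$flagged, , drop = FALSE]

setMethod("show", "ScreeningReport", function(object) {
  cat("ScreeningReport:", length(object@featureNames), "features,",
      nrow(object@pairs), "pairs\n")
  cat("thresholds: |r| >", object@rThreshold, "or MIC >",
      object@micThreshold, "\n")
  fl <- flaggedPairs(object)
  if (nrow(fl) == 0) cat("no flagged pairs\n")
  else for (i in seq_len(nrow(fl)))
    cat(sprintf("flagged: (%s, %s) r=%.3f mic=%.3f [%s]\n",
                fl$feature_a[i], fl$feature_b[i], fl$r[i], fl$mic[i],
                fl$trigger[i]))
  cat("dropped:", if (length(object@dropped))
    paste(object@dropped, collapse = ", ") else "none", "\n")
  cat("selected:", paste(object@selected, collapse = ", "), "\n")
})

#' GaussianMixture: a fitted Gaussian mixture model
#'
#' Parameters and fit metadata of a Gaussian mixture fitted by EM with one
#' of three covariance structures: \code{"tied"} (one covariance matrix
#' shared by all components), \code{"diag"} (per-component diagonal), or
#' \code{"full"} (per-component unrestricted).
#'
#' @slot k integer, number of components.
#' @slot covType one of "tied", "diag", "full".
#' @slot weights mixing weights (sum to 1).
#' @slot means k x d matrix of component means (on the fitting scale).
#' @slot covariances a single d x d matrix (tied), a k x d matrix of
#'   variances (diag), or a list of k d x d matrices (full).
#' @slot logLik total log-likelihood of the training data.
#' @slot logLikTrace per-iteration log-likelihood of the best restart.
#' @slot converged logical.
#' @slot nParams free parameter count used by BIC.
#' @slot standardizer list(center, scale) applied to the data before
#'   fitting, or NULL-lengths if fitted on the raw scale.
#' @slot featureNames column names of the training data.
#' @slot control list of EM settings (nInit, tol, maxIter, regCovar, seed,
#'   nReinit).
#' @export
setClass("GaussianMixture",
         representation(k = "integer", covType = "character",
                        weights = "numeric", means = "matrix",
                        covariances = "ANY", logLik = "numeric",
                        logLikTrace = "numeric", converged = "logical",
                        nParams = "integer", standardizer = "list",
                        featureNames = "character", control = "list"))

setValidity("GaussianMixture", function(object) {
  msg <- character()
  if (!object@covType %in% c("tied", "diag", "full"))
    msg <- c(msg, "covType must be tied, diag or full")
  if (abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1")
  if (any(object@weights <= 0))
    msg <- c(msg, "weights must be strictly positive")
  if (nrow(object@means) != object@k)
    msg <- c(msg, "means must have k rows")
  if (length(msg)) msg else TRUE
})

#' @describeIn GaussianMixture Number of mixture components.
#' @param x A \code{GaussianMixture}.
#' @export
nComponents <- function(x) x@k

#' @describeIn GaussianMixture Covariance structure tag.
#' @export
covarianceType <- function(x) x@covType

#' @describeIn GaussianMixture Mixing weights.
#' @export
mixtureWeights <- function(x) x@weights

#' @describeIn GaussianMixture Component means on the fitting scale.
#' @export
mixtureMeans <- function(x) x@means

#' @describeIn GaussianMixture Covariance parameters (layout depends on
#'   \code{covarianceType}).
#' @export
mixtureCovariances <- function(x) x@covariances

#' @describeIn GaussianMixture Per-iteration log-likelihood of the winning
#'   EM restart.
#' @export
logLikTrace <- function(x) x@logLikTrace

#' @describeIn GaussianMixture Free parameter count entering the BIC.
#' @export
nParameters <- function(x) x@nParams

#' @describeIn GaussianMixture Component means transformed back to the raw
#'   feature scale (undoing the stored standardization).
#' @export
componentCenters <- function(x) {
  m <- x@means
  if (length(x@standardizer$center))
    m <- sweep(sweep(m, 2, x@standardizer$scale, "*"), 2,
               x@standardizer$center, "+")
  colnames(m) <- x@featureNames
  m
}

setMethod("show", "GaussianMixture", function(object) {
  cat(sprintf("GaussianMixture: k=%d, covType=%s, d=%d\n", object@k,
              object@covType, ncol(object@means)))
  cat(sprintf("logLik=%.2f after %d EM iterations (%s)\n", object@logLik,
              length(object@logLikTrace),
              if (object@converged) "converged" else "not converged"))
  cat("weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
      "\n")
})

#' BICGrid: BIC sweep over covariance structures and component numbers
#'
#' @slot table data.frame with one row per fitted (covType, k): BIC,
#'   log-likelihood, parameter count, convergence flag and the hard-assigned
#'   cluster sizes (list column \code{sizes}).
#' @slot models named list of the fitted \linkS4class{GaussianMixture}
#'   objects (names "covType_k").
#' @slot n integer, number of cases fitted.
#' @export
setClass("BICGrid",
         representation(table = "data.frame", models = "list",
                        n = "integer"))

setMethod("show", "BICGrid", function(object) {
  cat("BICGrid:", nrow(object@table), "fits on", object@n, "cases\n")
  tab <- object@table
  best <- tab[which.min(tab$bic), ]
  cat(sprintf("min BIC: %.1f at covType=%s, k=%d\n", best$bic,
              best$covType, best$k))
})

#' @describeIn BICGrid The sweep table (without model objects); the data
#'   behind a BIC-versus-k curve per covariance type.
#' @param x A \code{BICGrid}.
#' @export
gridTable <- function(x) x@table

#' @describeIn BICGrid Retrieve one fitted model from the grid.
#' @param covType,k coordinates of the requested fit.
#' @export
gridModel <- function(x, covType, k) {
  key <- paste0(covType, "_", k)
  if (is.null(x@models[[key]])) stop("no fit stored for ", key)
  x@models[[key]]
}

#' ModelSelection: covariance structure and component-number choice
#'
#' Result of \code{\link{selectModel}}: the covariance structure with the
#' lowest BIC, the candidate component numbers whose BIC is within
#' tolerance of the minimum, the per-candidate count of small clusters
#' (size at or below the prevalence threshold), and the chosen model.
#'
#' @slot covType chosen covariance structure.
#' @slot candidates integer vector of candidate component numbers.
#' @slot smallThreshold integer prevalence-gate cluster size.
#' @slot smallCounts named integer, small-cluster count per candidate.
#' @slot k chosen number of components.
#' @slot model the chosen \linkS4class{GaussianMixture}.
#' @slot rationale list recording every quantity entering the decision.
#' @export
setClass("ModelSelection",
         representation(covType = "character", candidates = "integer",
                        smallThreshold = "integer",
                        smallCounts = "integer", k = "integer",
                        model = "GaussianMixture", rationale = "list"))

setMethod("show", "ModelSelection", function(object) {
  cat(sprintf("ModelSelection: covType=%s, k=%d\n", object@covType,
              object@k))
  cat("candidate k:", paste(object@candidates, collapse = ", "), "\n")
  cat("small-cluster threshold:", object@smallThreshold, "cases\n")
  cat("small clusters per candidate:",
      paste(names(object@smallCounts), object@smallCounts, sep = ":",
            collapse = " "), "\n")
})

#' @describeIn ModelSelection The chosen fitted model.
#' @param x A \code{ModelSelection}.
#' @export
selectedModel <- function(x) x@model

#' ClusterLabeling: pathology labels for hard-assigned clusters
#'
#' Result of \code{\link{labelClusters}}: per-case hard assignments plus a
#' per-cluster table with size, small/large status, the fraction of members
#' satisfying each pathology rule, and the resulting label (or UNLABELED).
#'
#' @slot assignments integer vector of per-case cluster ids.
#' @slot clusters data.frame: cluster, size, small, frac_RVA, frac_DCM,
#'   frac_HCM, label.
#' @slot caseLabels data.frame of per-case rule results (see
#'   \code{\link{classifyCases}}).
#' @slot smallThreshold integer small-cluster size gate.
#' @slot minFrac minimum member satisfaction fraction for a label.
#' @export
setClass("ClusterLabeling",
         representation(assignments = "integer", clusters = "data.frame",
                        caseLabels = "data.frame",
                        smallThreshold = "integer", minFrac = "numeric"))

setValidity("ClusterLabeling", function(object) {
  if (sum(object@clusters$size) != length(object@assignments))
    return("cluster sizes must sum to the number of cases")
  TRUE
})

setMethod("show", "ClusterLabeling", function(object) {
  cat("ClusterLabeling:", length(object@assignments), "cases in",
      nrow(object@clusters), "clusters (small threshold",
      object@smallThreshold, ")\n")
  tab <- object@clusters
  lab <- tab[tab$label != "UNLABELED", , drop = FALSE]
  if (nrow(lab) == 0) cat("no pathological clusters\n")
  else for (i in seq_len(nrow(lab)))
    cat(sprintf("cluster %d: %d cases -> %s (fraction %.2f)\n",
                lab$cluster[i], lab$size[i], lab$label[i],
                max(lab$frac_RVA[i], lab$frac_DCM[i], lab$frac_HCM[i])))
})

#' @describeIn ClusterLabeling Per-cluster summary table.
#' @param x A \code{ClusterLabeling}.
#' @export
clusterTable <- function(x) x@clusters

#' @describeIn ClusterLabeling Per-case cluster assignments.
#' @export
clusterAssignments <- function(x) x@assignments
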