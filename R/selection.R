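# Model selection: BIC sweep over (covariance structure, k), then the
# prevalence-gated small-cluster rule for the component number.

#' Small-cluster prevalence threshold
#'
#' The largest size a cluster may have while still being a candidate for a
#' rare pathological category: floor(prevalenceFrac * n).  With the default
#' 2 percent and a cohort of 3,822 this is 76 cases, reflecting that
#' clinically apparent cardiac pathology is rare in a general-population
#' cohort.
#'
#' @param n cohort size (non-negative).
#' @param prevalenceFrac assumed maximal prevalence, in [0, 1].
#' @return Integer threshold.
#' @export
#' @examples
#' smallClusterThreshold(3822)        # 76
smallClusterThreshold <- function(n, prevalenceFrac = 0.02) {
  if (n < 0) stop("n must be non-negative")
  if (prevalenceFrac < 0 || prevalenceFrac > 1)
    stop("prevalenceFrac must lie in [0, 1]")
  as.integer(floor(prevalenceFrac * n))
}

#' Sweep Gaussian mixtures over covariance structures and k
#'
#' Fits every requested (covType, k) combination with
#' \code{\link{fitGMM}} and records BIC and the hard-assignment cluster
#' sizes.
#'
#' @param x cases x features matrix (or \code{CardioCohort}).
#' @param ks integer vector of component numbers.
#' @param covTypes covariance structures to try.
#' @param seed master seed; each fit derives its own restart seed from it.
#' @param ... further arguments passed to \code{\link{fitGMM}}.
#' @return A \linkS4class{BICGrid}.
#' @export
sweepModels <- function(x, ks = 2:12, covTypes = c("tied", "diag", "full"),
                        seed, ...) {
  X <- .asMatrixX(x)
  ks <- sort(unique(as.integer(ks)))
  if (max(ks) >= nrow(X)) stop("max(ks) must be below the number of cases")
  covTypes <- match.arg(covTypes, c("tied", "diag", "full"),
                        several.ok = TRUE)
  # one Ward tree of the standardized data serves every fit in the sweep
  Xs <- scale(X)
  tree <- if (nrow(X) <= 8000)
    stats::hclust(stats::dist(Xs), method = "ward.D2")
  else NULL
  rows <- list()
  models <- list()
  allTypes <- c("tied", "diag", "full")
  for (ct in covTypes) for (k in ks) {
    # per-fit seed depends on (covType, k) only, not on sweep ordering
    fitSeed <- seed + 131L * k + 30011L * match(ct, allTypes)
    fit <- tryCatch(
      fitGMM(X, k = k, covType = ct, seed = fitSeed,
             wardTree = tree, ...),
      error = function(e)
        stop("fit failed for covType=", ct, ", k=", k, ": ",
             conditionMessage(e)))
    sizes <- tabulate(predictClusters(fit, X)$assignments, nbins = k)
    key <- paste0(ct, "_", k)
    models[[key]] <- fit
    rows[[key]] <- data.frame(covType = ct, k = k, bic = bic(fit, X),
                              loglik = fit@logLik, nParams = fit@nParams,
                              converged = fit@converged)
    rows[[key]]$sizes <- list(sizes)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("BICGrid", table = tab, models = models, n = nrow(X))
}

#' Select covariance structure and component number
#'
#' Two-stage rule mirroring how mixture models are chosen for rare-cluster
#' discovery: (1) the covariance structure whose best (minimum over k) BIC
#' is lowest is fixed; (2) within that structure, every k whose BIC lies
#' within \code{bicTolerance} of the minimum is a candidate, and the chosen
#' k is the smallest candidate attaining the maximal number of small
#' clusters (size at most \code{smallClusterThreshold(n, prevalenceFrac)}).
#' The parsimony tie-break means that when no candidate produces small
#' clusters the smallest candidate k wins.
#'
#' @param grid a \linkS4class{BICGrid} from \code{\link{sweepModels}}.
#' @param n cohort size (defaults to the grid's).
#' @param prevalenceFrac assumed maximal pathology prevalence.
#' @param bicTolerance candidate band above the minimum BIC: either a
#'   single number interpreted as a relative fraction of |min BIC|, or a
#'   list \code{list(type = "absolute"|"relative", value = ...)}.
#' @return A \linkS4class{ModelSelection}; the full rationale (per-stage
#'   quantities) is in its \code{rationale} slot, and re-running on the
#'   same grid reproduces the identical choice.
#' @export
selectModel <- function(grid, n = grid@n, prevalenceFrac = 0.02,
                        bicTolerance = 0.005) {
  stopifnot(is(grid, "BICGrid"))
  tab <- grid@table
  if (nrow(tab) == 0) stop("empty BIC grid")
  if (is.numeric(bicTolerance))
    bicTolerance <- list(type = "relative", value = bicTolerance)

  byType <- vapply(split(tab$bic, tab$covType), min, numeric(1))
  covType <- names(byType)[which.min(byType)]
  sub <- tab[tab$covType == covType, , drop = FALSE]
  minBic <- min(sub$bic)
  tolAbs <- switch(bicTolerance$type,
                   relative = bicTolerance$value * abs(minBic),
                   absolute = bicTolerance$value,
                   stop("bicTolerance$type must be 'relative' or 'absolute'"))
  candidates <- sort(sub$k[sub$bic <= minBic + tolAbs])
  if (!length(candidates))
    stop("empty candidate set; BIC grid: ",
         paste(sprintf("%s k=%d bic=%.1f", tab$covType, tab$k, tab$bic),
               collapse = "; "))

  thr <- smallClusterThreshold(n, prevalenceFrac)
  smallCounts <- vapply(candidates, function(k) {
    sizes <- sub$sizes[[match(k, sub$k)]]
    sum(sizes > 0 & sizes <= thr)
  }, integer(1))
  names(smallCounts) <- candidates
  chosen <- candidates[smallCounts == max(smallCounts)][1]

  new("ModelSelection", covType = covType,
      candidates = as.integer(candidates), smallThreshold = thr,
      smallCounts = smallCounts, k = as.integer(chosen),
      model = gridModel(grid, covType, chosen),
      rationale = list(
        bicByType = byType, covType = covType, minBic = minBic,
        tolerance = bicTolerance, toleranceAbs = tolAbs,
        candidates = candidates, prevalenceFrac = prevalenceFrac,
        smallThreshold = thr, smallCounts = smallCounts,
        chosenK = chosen,
        clusterSizes = sub$sizes[[match(chosen, sub$k)]]))
}
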