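# Confirmation battery: PCA projection of cases and cluster centers,
# pairwise Welch and Mann-Whitney tests across the large clusters, and
# comparison of the pipeline's LV measures against the reference channel
# with Huber robust regression.

#' PCA projection of cases and cluster centers
#'
#' Principal components of the standardized feature matrix (via singular
#' value decomposition); the cluster centers are transformed with the
#' case-derived standardizer and loadings, never refit.
#'
#' @param x cases x features matrix (or \code{CardioCohort}).
#' @param centers optional k x d matrix of cluster centers on the raw
#'   feature scale (e.g. \code{\link{componentCenters}}).
#' @param nComponents number of components to keep.
#' @param standardize z-score features before the decomposition.
#' @return list of class \code{PCAProjection}: \code{scores} (n x
#'   nComponents), \code{centerScores}, \code{rotation} (orthonormal
#'   loadings), \code{explainedVariance} (fractions over all d
#'   components), \code{standardizer}.
#' @export
pcaProject <- function(x, centers = NULL, nComponents = 2,
                       standardize = TRUE) {
  X <- .asMatrixX(x)
  if (nComponents > ncol(X))
    stop("nComponents exceeds the feature dimension")
  if (nrow(X) <= ncol(X)) stop("need more cases than features")
  ctr <- colMeans(X)
  scl <- if (standardize) apply(X, 2, sd) else rep(1, ncol(X))
  if (any(scl == 0)) stop("constant feature; cannot standardize")
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(nComponents), drop = FALSE]
  scores <- pc$x[, seq_len(nComponents), drop = FALSE]
  centerScores <- NULL
  if (!is.null(centers)) {
    centers <- as.matrix(centers)
    if (ncol(centers) != ncol(X))
      stop("centers must share the feature space of x")
    cs <- sweep(sweep(centers, 2, ctr), 2, scl, "/")
    centerScores <- cs %*% rot
  }
  structure(list(scores = scores, centerScores = centerScores,
                 rotation = rot,
                 explainedVariance = pc$sdev^2 / sum(pc$sdev^2),
                 standardizer = list(center = ctr, scale = scl)),
            class = "PCAProjection")
}

#' Welch's unequal-variance t-test
#'
#' Unpaired two-sided t-test with the Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param a,b numeric samples (each of size >= 2 with finite variance).
#' @return list with \code{statistic}, \code{df} and \code{p.value}.
#' @export
welchTTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs size >= 2")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite")
  if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b))
    return(list(statistic = 0, df = length(a) + length(b) - 2,
                p.value = 1))
  ht <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Mann-Whitney U rank test
#'
#' Unpaired two-sided rank test.  Without ties and with both samples of
#' size at most \code{exactLimit} the exact null distribution of U is
#' used; otherwise a tie-corrected normal approximation with continuity
#' correction.
#'
#' @param a,b numeric samples (size >= 2).
#' @param exactLimit largest per-group size for the exact distribution.
#' @return list with \code{U} (for the first sample), \code{p.value} and
#'   \code{method} ("exact" or "normal").
#' @export
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
mannWhitneyU <- function(a, b, exactLimit = 20) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs size >= 2")
  all_ <- c(a, b)
  if (length(unique(all_)) == 1)
    stop("degenerate test: all values tied across both samples")
  r <- rank(all_)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(all_))
  if (!ties && na <= exactLimit && nb <= exactLimit) {
    pLo <- pwilcox(U, na, nb)
    pHi <- 1 - pwilcox(U - 1, na, nb)
    p <- min(1, 2 * min(pLo, pHi))
    return(list(U = U, p.value = p, method = "exact"))
  }
  if (ties && na <= exactLimit && nb <= exactLimit &&
      choose(na + nb, na) <= 20000) {
    # exact permutation null of U under ties: enumerate group labelings
    N <- na + nb
    mu <- na * nb / 2
    combs <- combn(N, na)
    Us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p.value = p, method = "exact"))
  }
  N <- na + nb
  tieTab <- table(all_)
  sigma2 <- na * nb / 12 * ((N + 1) - sum(tieTab^3 - tieTab) /
                              (N * (N - 1)))
  mu <- na * nb / 2
  z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
  list(U = U, p.value = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Pairwise inter-cluster tests over features
#'
#' For every pair of the listed clusters and every feature, runs the Welch
#' t-test and the Mann-Whitney test of the two member samples; with m
#' clusters and d features this yields choose(m, 2) * d p-values per test
#' family.  Per-cell failures (e.g. degenerate samples) are recorded as NA
#' cells, not aborts.
#'
#' @param x feature table (\code{CardioCohort}, matrix or data.frame).
#' @param assignments integer cluster ids per case.
#' @param clusters cluster ids to compare (e.g. the large clusters).
#' @param features feature columns to test (default: all).
#' @param alpha significance level for the below/above counts.
#' @return list of class \code{TestMatrixReport}: \code{table}
#'   (cluster_a, cluster_b, feature, welch_p, mw_p), \code{counts}
#'   (below/above alpha per family), \code{alpha}, \code{nPairs},
#'   \code{nFeatures}.
#' @export
pairwiseClusterTests <- function(x, assignments, clusters = NULL,
                                 features = NULL, alpha = 0.05) {
  if (is(x, "CardioCohort")) x <- featureMatrix(x)
  X <- as.matrix(as.data.frame(x))
  assignments <- as.integer(assignments)
  if (length(assignments) != nrow(X))
    stop("assignments must cover all cases")
  if (is.null(clusters)) clusters <- sort(unique(assignments))
  if (is.null(features)) features <- colnames(X)
  for (cl in clusters)
    if (sum(assignments == cl) < 2)
      stop("cluster ", cl, " has fewer than 2 members")
  pairs <- combn(sort(clusters), 2)
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    ca <- pairs[1, p]; cb <- pairs[2, p]
    for (f in features) {
      a <- X[assignments == ca, f]
      b <- X[assignments == cb, f]
      wp <- tryCatch(welchTTest(a, b)$p.value, error = function(e) NA_real_)
      mp <- tryCatch(mannWhitneyU(a, b)$p.value,
                     error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster_a = ca, cluster_b = cb, feature = f,
                   welch_p = wp, mw_p = mp)
    }
  }
  tab <- do.call(rbind, rows)
  counts <- list(
    welch = c(below = sum(tab$welch_p < alpha, na.rm = TRUE),
              above = sum(tab$welch_p >= alpha, na.rm = TRUE)),
    mannwhitney = c(below = sum(tab$mw_p < alpha, na.rm = TRUE),
                    above = sum(tab$mw_p >= alpha, na.rm = TRUE)))
  structure(list(table = tab, counts = counts, alpha = alpha,
                 nPairs = ncol(pairs), nFeatures = length(features)),
            class = "TestMatrixReport")
}

#' Huber robust simple linear regression
#'
#' Iteratively reweighted least squares minimizing the Huber loss on
#' residuals standardized by the median absolute deviation (re-estimated
#' each iteration); tuning constant 1.345 gives 95 percent efficiency
#' under Gaussian errors.
#'
#' @param x,y numeric vectors, \code{x} non-constant, n >= 3.
#' @param delta Huber tuning constant.
#' @param maxIter,tol IRLS iteration cap and coefficient tolerance.
#' @return list with \code{slope}, \code{intercept}, \code{iterations},
#'   \code{converged}.
#' @export
#' @examples
#' x <- 1:20
#' huberFit(x, 1.002 * x + 3.373)
huberFit <- function(x, y, delta = 1.345, maxIter = 100, tol = 1e-8) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (sd(x) == 0) stop("x is constant; slope is not identifiable")
  Xd <- cbind(1, x)
  beta <- stats::lm.fit(Xd, y)$coefficients
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(maxIter)) {
    r <- y - Xd %*% beta
    s <- mad(r)
    if (s < .Machine$double.eps^0.5 * (1 + max(abs(y)))) {
      converged <- TRUE   # (near-)perfect fit for over half the points
      break
    }
    u <- abs(r) / s
    w <- ifelse(u <= delta, 1, delta / u)
    betaNew <- stats::lm.wfit(Xd, y, as.numeric(w))$coefficients
    if (max(abs(betaNew - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- betaNew
      converged <- TRUE
      break
    }
    beta <- betaNew
  }
  list(slope = unname(beta[2]), intercept = unname(beta[1]),
       iterations = iter, converged = converged)
}

#' Compare pipeline LV measures against the reference channel
#'
#' Joins the pipeline-derived LV volumes (EDV reconstructed from
#' V_LV_ES / (1 - EF_LV)) with the reference measurements by case id and
#' reports, per measure, mean, standard deviation and the relative mean
#' difference gt_mean / pipeline_mean - 1, plus Huber regressions of the
#' reference volumes on the pipeline volumes.
#'
#' @param pipeline a \code{CardioCohort}, or a data.frame with case_id,
#'   V_LV_ED, V_LV_ES (and optionally EF_LV; otherwise derived).
#' @param gt a data.frame with case_id, gt_V_LV_ED, gt_V_LV_ES (and
#'   optionally gt_EF_LV; otherwise derived), e.g.
#'   \code{\link{groundTruthTable}}.
#' @return list of class \code{GroundTruthComparison}: \code{table}
#'   (measure, pipeline_mean, pipeline_sd, gt_mean, gt_sd, pct_diff) and
#'   \code{huber} (fits for EDV and ESV).
#' @export
compareToGroundTruth <- function(pipeline, gt) {
  if (is(pipeline, "CardioCohort")) {
    ft <- featureTable(pipeline)
    pipeline <- data.frame(case_id = ft$case_id,
                           V_LV_ED = ft$V_LV_ES / (1 - ft$EF_LV),
                           V_LV_ES = ft$V_LV_ES, EF_LV = ft$EF_LV)
  }
  pipeline <- as.data.frame(pipeline)
  gt <- as.data.frame(gt)
  if (!"EF_LV" %in% colnames(pipeline))
    pipeline$EF_LV <- 1 - pipeline$V_LV_ES / pipeline$V_LV_ED
  if (!"gt_EF_LV" %in% colnames(gt))
    gt$gt_EF_LV <- 1 - gt$gt_V_LV_ES / gt$gt_V_LV_ED
  onlyP <- setdiff(pipeline$case_id, gt$case_id)
  onlyG <- setdiff(gt$case_id, pipeline$case_id)
  if (length(onlyP) || length(onlyG))
    stop("unmatched case ids; pipeline-only: ",
         paste(utils::head(onlyP, 5), collapse = ", "),
         if (length(onlyP) > 5) " ...", "; reference-only: ",
         paste(utils::head(onlyG, 5), collapse = ", "),
         if (length(onlyG) > 5) " ...")
  m <- merge(pipeline, gt, by = "case_id")
  meas <- data.frame(
    measure = c("V_LV_ED", "V_LV_ES", "EF_LV"),
    pipeline_mean = c(mean(m$V_LV_ED), mean(m$V_LV_ES), mean(m$EF_LV)),
    pipeline_sd = c(sd(m$V_LV_ED), sd(m$V_LV_ES), sd(m$EF_LV)),
    gt_mean = c(mean(m$gt_V_LV_ED), mean(m$gt_V_LV_ES), mean(m$gt_EF_LV)),
    gt_sd = c(sd(m$gt_V_LV_ED), sd(m$gt_V_LV_ES), sd(m$gt_EF_LV)))
  meas$pct_diff <- meas$gt_mean / meas$pipeline_mean - 1
  structure(list(
    table = meas,
    huber = list(V_LV_ED = huberFit(m$V_LV_ED, m$gt_V_LV_ED),
                 V_LV_ES = huberFit(m$V_LV_ES, m$gt_V_LV_ES)),
    n = nrow(m)), class = "GroundTruthComparison")
}
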