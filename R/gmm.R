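# Gaussian mixture fitting: k-means++-style seeding, multiple EM restarts
# (compiled core), BIC, and hard assignment.

.COV_CODE <- c(tied = 0L, diag = 1L, full = 2L)

# number of free parameters for BIC:
# (k-1) mixing weights + k*d means + covariance parameters
.gmmNParams <- function(k, d, covType) {
  covP <- switch(covType,
                 tied = d * (d + 1) / 2,
                 diag = k * d,
                 full = k * d * (d + 1) / 2)
  as.integer((k - 1) + k * d + covP)
}

# k-means++ seeding: first center uniform, subsequent centers drawn with
# probability proportional to squared distance to the nearest chosen center
.kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) idx <- sample.int(n, 1)
      else idx <- sample.int(n, 1, prob = d2)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

# Ward agglomerative initialization (the classic model-based-clustering
# starting point): deterministic, and recovers compact well-separated
# groups -- including rare far-out ones -- as their own branch, giving EM a
# complete parameter set (weights, means, covariances) to start from.
.wardInitParams <- function(X, k, covType, regCovar, tree) {
  groups <- stats::cutree(tree, k)
  idx <- split(seq_len(nrow(X)), groups)
  n <- nrow(X); d <- ncol(X)
  means <- do.call(rbind, lapply(idx, function(i)
    colMeans(X[i, , drop = FALSE])))
  w <- vapply(idx, length, numeric(1)) / n
  pooled <- cov(X) * (n - 1) / n
  diag(pooled) <- diag(pooled) + regCovar
  grpCov <- function(i) {
    if (length(i) < 2) return(pooled)
    S <- cov(X[i, , drop = FALSE]) * (length(i) - 1) / length(i)
    diag(S) <- diag(S) + regCovar
    S
  }
  covs <- switch(covType,
                 full = lapply(idx, grpCov),
                 tied = {
                   S <- Reduce(`+`, lapply(idx, function(i) {
                     C <- X[i, , drop = FALSE]
                     crossprod(sweep(C, 2, colMeans(C)))
                   })) / n
                   diag(S) <- diag(S) + regCovar
                   list(S)
                 },
                 diag = {
                   V <- do.call(rbind, lapply(idx, function(i)
                     diag(grpCov(i))))
                   list(V)
                 })
  list(weights = unname(w), means = unname(means),
       covs = unname(covs))
}

# k-means++ seeding followed by Lloyd refinement: EM restarts start from a
# k-means partition's centers, which keeps rare far-out groups as their own
# component instead of letting a broad component absorb them
.initCenters <- function(X, k) {
  seeds <- .kmeansppCenters(X, k)
  if (k == 1) return(seeds)
  km <- tryCatch(
    suppressWarnings(stats::kmeans(X, centers = seeds, iter.max = 25,
                                   algorithm = "Lloyd")),
    error = function(e) NULL)
  if (is.null(km)) seeds else km$centers
}

.asMatrixX <- function(x) {
  if (is(x, "CardioCohort")) x <- featureMatrix(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("X must be finite")
  x
}

#' Fit a Gaussian mixture model by EM
#'
#' Runs one deterministic EM start from a Ward agglomerative partition
#' (weights, means and covariances of the cut-tree groups) plus
#' \code{nInit} short EM restarts from k-means-refined k-means++ seeds
#' (covariances initialized to the pooled covariance), then polishes the
#' best run to full convergence with a warm start from its complete
#' parameter set.  Convergence is declared when the mean per-case
#' log-likelihood improvement falls below \code{tol}.  A component whose
#' responsibility mass vanishes is re-seeded from the worst-fit case
#' rather than crashing; \code{regCovar} is added to every covariance
#' diagonal so no eigenvalue falls below it.
#'
#' @param x cases x features numeric matrix (or \code{CardioCohort}).
#' @param k number of components (>= 1).
#' @param covType covariance structure: "tied", "diag" or "full".
#' @param seed integer seed for restart seeding.
#' @param nInit number of EM restarts.
#' @param tol convergence tolerance on mean per-case log-likelihood gain.
#'   The default 1e-5 leaves fits converged to within a few log-likelihood
#'   units, so BIC differences across k reflect the models rather than
#'   residual EM drift.
#' @param maxIter maximum EM iterations for the polishing run; the
#'   screening restarts use at most 100.
#' @param regCovar covariance eigenvalue floor.
#' @param standardize z-score each feature before fitting (recommended:
#'   the features span orders of magnitude and tied/diag structures are
#'   scale-sensitive).  The standardizer is stored with the model.
#' @param wardTree optional pre-computed \code{hclust} tree (method
#'   "ward.D2") of the standardized data, so a model sweep can reuse one
#'   tree; computed internally when NULL (skipped for n > 8000).
#' @return A \linkS4class{GaussianMixture}.
#' @export
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(200), ncol = 2),
#'            matrix(rnorm(200, mean = 10), ncol = 2))
#' fit <- fitGMM(X, k = 2, covType = "full", seed = 1)
#' mixtureWeights(fit)
fitGMM <- function(x, k, covType = c("full", "tied", "diag"), seed,
                   nInit = 10, tol = 1e-5, maxIter = 500,
                   regCovar = 1e-6, standardize = TRUE,
                   wardTree = NULL) {
  covType <- match.arg(covType)
  X <- .asMatrixX(x)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (nrow(X) <= k) stop("need more cases than components")
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("feature_", seq_len(ncol(X)))

  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    if (any(scl == 0)) stop("constant feature; cannot standardize")
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    std <- list(center = ctr, scale = scl)
  } else {
    Xs <- X
    std <- list(center = numeric(0), scale = numeric(0))
  }

  set.seed(seed)
  # one deterministic Ward-initialized run plus random k-means restarts to
  # locate the best basin, then a warm-started polish of the winner
  shortTol <- max(tol, 1e-3)
  shortIter <- min(maxIter, 100L)
  best <- NULL
  if (k > 1 && nrow(Xs) <= 8000) {
    if (is.null(wardTree))
      wardTree <- stats::hclust(stats::dist(Xs), method = "ward.D2")
    wi <- .wardInitParams(Xs, k, covType, regCovar, wardTree)
    best <- .gmm_em_cpp(Xs, wi$means, .COV_CODE[[covType]], shortTol,
                        shortIter, regCovar, weights0 = wi$weights,
                        covs0 = wi$covs)
  }
  for (i in seq_len(nInit)) {
    fit <- .gmm_em_cpp(Xs, .initCenters(Xs, k), .COV_CODE[[covType]],
                       shortTol, shortIter, regCovar)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (tol < shortTol || maxIter > shortIter) {
    polish <- .gmm_em_cpp(Xs, best$means, .COV_CODE[[covType]], tol,
                          maxIter, regCovar, weights0 = best$weights,
                          covs0 = best$covariances)
    polish$loglik_trace <- c(best$loglik_trace,
                             polish$loglik_trace[-1])
    polish$n_reinit <- best$n_reinit + polish$n_reinit
    best <- polish
  }

  covs <- switch(covType,
                 tied = best$covariances[[1]],
                 diag = best$covariances[[1]],
                 full = best$covariances)
  new("GaussianMixture", k = k, covType = covType,
      weights = as.numeric(best$weights), means = best$means,
      covariances = covs, logLik = best$loglik,
      logLikTrace = as.numeric(best$loglik_trace),
      converged = isTRUE(best$converged),
      nParams = .gmmNParams(k, ncol(Xs), covType), standardizer = std,
      featureNames = fn,
      control = list(nInit = nInit, tol = tol, maxIter = maxIter,
                     regCovar = regCovar, seed = seed,
                     nReinit = best$n_reinit))
}

.applyStandardizer <- function(model, X) {
  if (length(model@standardizer$center))
    X <- sweep(sweep(X, 2, model@standardizer$center), 2,
               model@standardizer$scale, "/")
  X
}

.modelCovList <- function(model) {
  switch(model@covType,
         tied = list(model@covariances),
         diag = list(model@covariances),
         full = model@covariances)
}

#' Bayesian information criterion of a fitted mixture
#'
#' BIC = -2 logL(X) + p log(n), where p is the free parameter count of the
#' model ((k-1) weights, k*d means, and d(d+1)/2, k*d or k*d(d+1)/2
#' covariance parameters for tied, diag and full structures).  Lower is
#' better.
#'
#' @param model a \linkS4class{GaussianMixture}.
#' @param x data on the raw feature scale (the model's stored
#'   standardization is applied before evaluation).
#' @return The BIC score (numeric scalar).
#' @export
bic <- function(model, x) {
  stopifnot(is(model, "GaussianMixture"))
  X <- .asMatrixX(x)
  if (ncol(X) != ncol(model@means))
    stop("dimension mismatch: model has ", ncol(model@means),
         " features, data has ", ncol(X))
  Xs <- .applyStandardizer(model, X)
  ll <- .gmm_logprob_cpp(Xs, model@weights, model@means,
                         .COV_CODE[[model@covType]],
                         .modelCovList(model))$loglik
  -2 * ll + model@nParams * log(nrow(X))
}

#' Hard cluster assignment and responsibilities
#'
#' Posterior component responsibilities for each case (rows sum to 1) and
#' the hard assignment to the most probable component, ties broken toward
#' the lowest component index.
#'
#' @param model a \linkS4class{GaussianMixture}.
#' @param x data on the raw feature scale.
#' @return list with \code{assignments} (integer) and
#'   \code{responsibilities} (n x k matrix).
#' @export
predictClusters <- function(model, x) {
  stopifnot(is(model, "GaussianMixture"))
  X <- .asMatrixX(x)
  if (ncol(X) != ncol(model@means))
    stop("dimension mismatch: model has ", ncol(model@means),
         " features, data has ", ncol(X))
  Xs <- .applyStandardizer(model, X)
  resp <- .gmm_logprob_cpp(Xs, model@weights, model@means,
                           .COV_CODE[[model@covType]],
                           .modelCovList(model))$resp
  list(assignments = max.col(resp, ties.method = "first"),
       responsibilities = resp)
}
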