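# Redundancy screening: pairwise Pearson r and MIC over all feature pairs,
# with greedy exclusion of one member of every highly correlated pair.

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper: errors on constant input (an undefined
#' correlation signals an upstream bug, and is never silently 0).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1].
#' @export
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4))
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input")
  cor(x, y)
}

#' Maximal information coefficient (MIC)
#'
#' Maximal normalized mutual information over all x-by-y grids with at most
#' B(n) = n^alpha cells, computed by the characteristic-matrix
#' approximation: one axis is equipartitioned, the other optimally
#' partitioned by dynamic programming over clump boundaries (with at most
#' c times the column budget of superclumps), and both orientations are
#' searched.
#'
#' @param x,y numeric vectors of equal length.
#' @param alpha grid-budget exponent, B(n) = n^alpha.
#' @param c superclump factor (maximum clumps per allowed column).
#' @return MIC in [0, 1].  A constant vector yields 0.
#' @export
#' @examples
#' x <- seq_len(200)
#' micScore(x, x^2)        # noiseless functional relationship, near 1
micScore <- function(x, y, alpha = 0.6, c = 15) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  n <- length(x)
  if (n < 8 || floor(n^alpha) < 4)
    stop("sample too small: need n >= 8 with floor(n^alpha) >= 4")
  .mic_cpp(as.numeric(x), as.numeric(y), alpha, c)
}

#' Screen a feature table for redundant pairs
#'
#' Evaluates Pearson r and MIC for every feature pair and flags pairs with
#' |r| above \code{rThreshold} or MIC above \code{micThreshold}.  Flagged
#' pairs are resolved greedily in descending trigger strength, re-checking
#' remaining pairs after each drop; within a pair, the dropped member is
#' taken from \code{dropPreference} if listed, otherwise it is the member
#' with the larger mean |r| against all other features (the hallmark of a
#' feature that is a deterministic function of others), with ties broken
#' toward the later column.
#'
#' @param x a \linkS4class{CardioCohort}, or a numeric cases x features
#'   matrix / data.frame.
#' @param rThreshold Pearson flag threshold in (0, 1].
#' @param micThreshold MIC flag threshold in (0, 1].
#' @param dropPreference optional character vector of features to drop
#'   preferentially when they occur in a flagged pair.
#' @param micAlpha,micC MIC parameters, see \code{\link{micScore}}.
#' @return A \linkS4class{ScreeningReport}.
#' @export
#' @examples
#' set.seed(1)
#' tab <- data.frame(a = rnorm(100), b = rnorm(100))
#' tab$dup <- tab$a
#' screenFeatures(tab)
screenFeatures <- function(x, rThreshold = 0.8, micThreshold = 0.5,
                           dropPreference = NULL, micAlpha = 0.6, micC = 15) {
  if (is(x, "CardioCohort")) x <- featureMatrix(x)
  x <- as.matrix(as.data.frame(x))
  if (!is.numeric(x)) stop("feature table must be numeric")
  d <- ncol(x)
  if (d < 2) stop("need at least 2 features")
  if (nrow(x) < 8) stop("need at least 8 cases")
  if (rThreshold <= 0 || rThreshold > 1 || micThreshold <= 0 ||
      micThreshold > 1)
    stop("thresholds must lie in (0, 1]")
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("feature_", seq_len(d))
  const <- which(apply(x, 2, sd) == 0)
  if (length(const))
    stop("constant feature column(s): ", paste(fn[const], collapse = ", "))

  R <- cor(x)
  dimnames(R) <- list(fn, fn)
  M <- diag(d) * 0 + 1
  dimnames(M) <- list(fn, fn)
  pairs <- combn(d, 2)
  rows <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    mic <- micScore(x[, i], x[, j], alpha = micAlpha, c = micC)
    M[i, j] <- M[j, i] <- mic
    r <- R[i, j]
    flag <- abs(r) > rThreshold || mic > micThreshold
    trigger <- if (!flag) "none"
    else if (abs(r) > rThreshold && mic > micThreshold) "both"
    else if (abs(r) > rThreshold) "pearson" else "mic"
    rows[[p]] <- data.frame(feature_a = fn[i], feature_b = fn[j], r = r,
                            mic = mic, flagged = flag, trigger = trigger)
  }
  pairTab <- do.call(rbind, rows)

  # greedy drop: strongest trigger first, re-check after each drop
  meanAbsR <- (rowSums(abs(R)) - 1) / (d - 1)
  active <- fn
  dropped <- character()
  repeat {
    live <- pairTab$feature_a %in% active & pairTab$feature_b %in% active &
      pairTab$flagged
    if (!any(live)) break
    strength <- pmax(abs(pairTab$r) / rThreshold,
                     pairTab$mic / micThreshold)
    strength[!live] <- -Inf
    p <- which.max(strength)
    a <- pairTab$feature_a[p]; b <- pairTab$feature_b[p]
    drop <- if (a %in% dropPreference && !(b %in% dropPreference)) a
    else if (b %in% dropPreference && !(a %in% dropPreference)) b
    else if (meanAbsR[a] > meanAbsR[b]) a
    else if (meanAbsR[b] > meanAbsR[a]) b
    else fn[max(match(a, fn), match(b, fn))]   # tie: later column goes
    dropped <- c(dropped, drop)
    active <- setdiff(active, drop)
  }
  new("ScreeningReport", featureNames = fn, pearson = R, mic = M,
      pairs = pairTab, dropped = dropped,
      selected = fn[fn %in% active], rThreshold = rThreshold,
      micThreshold = micThreshold)
}
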