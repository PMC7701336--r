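# Independent oracles used across the suite.  Each is a brute-force or
# textbook-formula route kept deliberately separate from the package's own
# implementation path.

# Welch statistic and two-sided p from the textbook formulas
welchOracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = tstat, df = df,
       p.value = 2 * stats::pt(-abs(tstat), df))
}

# exact two-sided Mann-Whitney p by enumerating all group labelings
mwOracle <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  combs <- utils::combn(N, na)
  Us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
  mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
}

# exhaustive MIC: search every admissible grid (all cut placements) with
# p*q <= floor(n^alpha); feasible only for very small n
micOracle <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- floor(n^alpha)
  xs <- sort(unique(x)); ys <- sort(unique(y))
  xcuts <- (head(xs, -1) + tail(xs, -1)) / 2
  ycuts <- (head(ys, -1) + tail(ys, -1)) / 2
  best <- 0
  for (p in 2:max(2, floor(B / 2))) for (q in 2:max(2, floor(B / p))) {
    if (p * q > B) next
    if (length(xcuts) < p - 1 || length(ycuts) < q - 1) next
    for (a in utils::combn(xcuts, p - 1, simplify = FALSE))
      for (b in utils::combn(ycuts, q - 1, simplify = FALSE)) {
        xi <- findInterval(x, a)
        yi <- findInterval(y, b)
        tab <- table(xi, yi)
        px <- rowSums(tab) / n
        py <- colSums(tab) / n
        pj <- tab / n
        mi <- sum(pj * log(pj / outer(px, py)), na.rm = TRUE)
        v <- mi / log(min(p, q))
        if (v > best) best <- v
      }
  }
  best
}

# multivariate-normal mixture log-likelihood from first principles
gmmLoglikOracle <- function(X, w, means, covs) {
  n <- nrow(X); k <- length(w)
  dens <- sapply(seq_len(k), function(j) {
    S <- covs[[j]]
    L <- chol(S)
    z <- backsolve(L, t(sweep(X, 2, means[j, ])), transpose = TRUE)
    -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(z^2))
  })
  sum(log(rowSums(sweep(exp(dens), 2, w, "*"))))
}

# small feature table with physiologically normal values, for rule tests
normalFeatureRow <- function(n = 1) {
  data.frame(case_id = sprintf("nor_%03d", seq_len(n)),
             V_RV_ED = rep(80, n), V_LV_ES = rep(24, n),
             EF_RV = rep(0.60, n), EF_LV = rep(0.66, n),
             R_RVLV_ED = rep(1.1, n), R_LVMLV_ED = rep(0.65, n),
             MT_LVM_ED = rep(9, n), RMD = rep(1, n), TMD = rep(0.8, n))
}

# default-condition cohort at reduced size, shared by module tests
smallCohort <- function(seed = 1, n = 1200) {
  simulateCohort(cohortSimConfig(nTotal = n), seed = seed)
}
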