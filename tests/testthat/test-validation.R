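test_that("PCA projection matches the eigendecomposition oracle", {
  set.seed(1)
  X <- matrix(rnorm(80), ncol = 4)
  pr <- pcaProject(X, nComponents = 2)
  S <- cov(scale(X))
  eig <- eigen(S, symmetric = TRUE)
  for (j in 1:2) {
    v <- pr$rotation[, j]
    w <- eig$vectors[, j]
    expect_equal(abs(sum(v * w)), 1, tolerance = 1e-8)  # same up to sign
  }
  expect_equal(unname(colMeans(pr$scores)), c(0, 0), tolerance = 1e-9)
  expect_equal(crossprod(pr$rotation), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # total score variance equals the top-2 eigenvalue mass
  expect_equal(sum(apply(pr$scores, 2, var)), sum(eig$values[1:2]),
               tolerance = 1e-8)
  expect_true(all(diff(pr$explainedVariance) <= 1e-12))
})

test_that("rank-2 data is explained entirely by two components", {
  set.seed(2)
  basis <- matrix(rnorm(16), 8, 2)
  X <- matrix(rnorm(200), ncol = 2) %*% t(basis)
  pr <- pcaProject(X, nComponents = 2, standardize = FALSE)
  expect_equal(sum(pr$explainedVariance[1:2]), 1, tolerance = 1e-9)
})

test_that("cluster centers are transformed with the case standardizer", {
  set.seed(3)
  X <- matrix(rnorm(300), ncol = 3)
  pr <- pcaProject(X, centers = X[1:5, ])
  expect_equal(unname(pr$centerScores), unname(pr$scores[1:5, ]),
               tolerance = 1e-9)
  expect_error(pcaProject(X, centers = matrix(0, 2, 5)),
               "feature space")
  expect_error(pcaProject(X, nComponents = 9), "exceeds")
})

test_that("Welch test matches the textbook formulas", {
  expect_equal(welchTTest(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(welchTTest(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  set.seed(4)
  for (i in 1:50) {
    a <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    got <- welchTTest(a, b)
    want <- welchOracle(a, b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
  }
  set.seed(5)
  a <- rnorm(200)
  b <- rnorm(200, mean = 1)
  expect_lt(welchTTest(a, b)$p.value, 1e-7)
  expect_error(welchTTest(1, c(1, 2)), "size")
})

test_that("Mann-Whitney exact path agrees with enumeration", {
  res <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$U, 0)
  expect_equal(res$p.value, 0.1)   # 2 of the 20 labelings are as extreme
  expect_identical(res$method, "exact")
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  set.seed(6)
  for (i in 1:30) {
    a <- rnorm(sample(3:7, 1))
    b <- rnorm(sample(3:7, 1))
    expect_equal(mannWhitneyU(a, b)$p.value, mwOracle(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mannWhitneyU(rep(1, 5), rep(1, 4)), "degenerate")
})

test_that("the normal approximation tracks the exact 4v4 distribution", {
  # largest discrepancy over all attainable U values, frozen from the
  # enumeration itself
  diffs <- vapply(0:16, function(u) {
    pE <- min(1, 2 * min(pwilcox(u, 4, 4), 1 - pwilcox(u - 1, 4, 4)))
    z <- (u - 8 - 0.5 * sign(u - 8)) / sqrt(4 * 4 * 9 / 12)
    abs(pE - min(1, 2 * pnorm(-abs(z))))
  }, numeric(1))
  expect_lt(max(diffs), 0.035)
  # and the large-sample path is used when requested
  set.seed(7)
  a <- rnorm(30); b <- rnorm(35)
  expect_identical(mannWhitneyU(a, b)$method, "normal")
  expect_identical(mannWhitneyU(a, b, exactLimit = 40)$method, "exact")
})

test_that("pairwise cluster tests enumerate pair-by-feature cells", {
  set.seed(8)
  n <- 700
  assignments <- rep(1:7, each = 100)
  X <- matrix(rnorm(n * 8), ncol = 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  X <- X + assignments  # separate the cluster means
  rep7 <- pairwiseClusterTests(X, assignments)
  expect_identical(nrow(rep7$table), 21L * 8L)
  expect_identical(rep7$nPairs, 21L)
  expect_true(all(rep7$table$welch_p >= 0 & rep7$table$welch_p <= 1))
  expect_identical(sum(rep7$counts$welch), 168L)
  rep1 <- pairwiseClusterTests(X[1:200, 1, drop = FALSE],
                               assignments[1:200])
  expect_identical(nrow(rep1$table), 1L)
  expect_error(pairwiseClusterTests(X, c(assignments[-1], 99)),
               "fewer than 2")
})

test_that("pairwise tests hold their nominal size under the null", {
  set.seed(9)
  ps <- replicate(200, {
    x <- rnorm(60)
    g <- rep(1:2, each = 30)
    r <- pairwiseClusterTests(matrix(x, ncol = 1,
                                     dimnames = list(NULL, "f")), g)
    c(r$table$welch_p, r$table$mw_p)
  })
  expect_lt(abs(mean(ps[1, ] < 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(ps[2, ] < 0.05) - 0.05), 0.03)
})

test_that("Huber regression recovers lines and resists outliers", {
  x <- seq(1, 100, length.out = 50)
  f <- huberFit(x, 1.002 * x + 3.373)
  expect_equal(f$slope, 1.002, tolerance = 1e-6)
  expect_equal(f$intercept, 3.373, tolerance = 1e-6)
  expect_true(f$converged)

  fconst <- huberFit(x, rep(5, 50))
  expect_equal(fconst$slope, 0, tolerance = 1e-9)
  expect_equal(fconst$intercept, 5, tolerance = 1e-9)

  set.seed(10)
  x <- runif(1000, 0, 100)
  y <- 2 + 0.9 * x + rnorm(1000)
  out <- sample(1000, 100)
  y[out] <- y[out] * 3          # gross multiplicative outliers
  fh <- huberFit(x, y)
  ols <- stats::lm.fit(cbind(1, x), y)$coefficients
  expect_lt(abs(fh$slope - 0.9), 0.02)
  expect_gt(abs(ols[2] - 0.9), 0.05)
  expect_error(huberFit(rep(1, 10), rnorm(10)), "constant")
})

test_that("Huber IRLS agrees with the reference M-estimator", {
  set.seed(11)
  for (i in 1:10) {
    x <- runif(200, 0, 50)
    y <- 1 + 0.5 * x + rnorm(200)
    y[sample(200, 10)] <- y[sample(200, 10)] + 40
    fh <- huberFit(x, y)
    rl <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345,
                    maxit = 100)
    expect_equal(fh$slope, unname(coef(rl)[2]), tolerance = 5e-3)
    expect_equal(fh$intercept, unname(coef(rl)[1]), tolerance = 5e-2)
  }
})

test_that("comparison against the reference channel reports exact
           relative differences", {
  pip <- data.frame(case_id = c("a", "b", "c"),
                    V_LV_ED = 70.56 + c(-1, 0, 1),
                    V_LV_ES = 24.06 + c(-1, 0, 1))
  gt <- data.frame(case_id = c("a", "b", "c"),
                   gt_V_LV_ED = 75.48 + c(-1, 0, 1),
                   gt_V_LV_ES = 33.87 + c(-1, 0, 1))
  cmp <- compareToGroundTruth(pip, gt)
  tab <- cmp$table
  expect_equal(round(100 * tab$pct_diff[tab$measure == "V_LV_ED"], 1), 7.0)
  expect_equal(round(100 * tab$pct_diff[tab$measure == "V_LV_ES"], 1), 40.8)
  expect_equal(tab$pct_diff, tab$gt_mean / tab$pipeline_mean - 1,
               tolerance = 1e-12)

  # identical channel: zero differences, identity regression
  gt0 <- data.frame(case_id = pip$case_id, gt_V_LV_ED = pip$V_LV_ED,
                    gt_V_LV_ES = pip$V_LV_ES)
  cmp0 <- compareToGroundTruth(pip, gt0)
  expect_equal(cmp0$table$pct_diff[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(cmp0$huber$V_LV_ED$slope, 1, tolerance = 1e-8)
  expect_equal(cmp0$huber$V_LV_ED$intercept, 0, tolerance = 1e-6)

  expect_error(compareToGroundTruth(pip, gt[-1, ]), "unmatched")
})

test_that("Huber recovers the generative reference coefficients under
           default contamination", {
  slopes <- inters <- numeric(10)
  for (s in 1:10) {
    coh <- simulateCohort(seed = 100 + s)
    cmp <- compareToGroundTruth(coh, groundTruthTable(coh))
    slopes[s] <- cmp$huber$V_LV_ED$slope
    inters[s] <- cmp$huber$V_LV_ED$intercept
  }
  expect_true(all(abs(slopes - 1.002) < 0.03))
  expect_true(all(abs(inters - 3.373) < 1.5))
})
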