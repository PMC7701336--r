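test_that("k = 1 reduces to the closed-form Gaussian fit", {
  set.seed(1)
  X <- matrix(rnorm(300), ncol = 3)
  fit <- fitGMM(X, k = 1, covType = "full", seed = 1, standardize = FALSE)
  expect_equal(unname(as.vector(componentCenters(fit))),
               unname(colMeans(X)), tolerance = 1e-8)
  S <- cov(X) * (nrow(X) - 1) / nrow(X)
  diag(S) <- diag(S) + 1e-6
  expect_equal(unname(mixtureCovariances(fit)[[1]]), unname(S),
               tolerance = 1e-6)
  expect_equal(mixtureWeights(fit), 1)
})

test_that("two well-separated clusters are recovered", {
  set.seed(2)
  X <- rbind(matrix(rnorm(400), ncol = 2),
             matrix(rnorm(400, mean = 10), ncol = 2))
  for (ct in c("full", "diag", "tied")) {
    fit <- fitGMM(X, k = 2, covType = ct, seed = 3)
    mu <- componentCenters(fit)
    mu <- mu[order(mu[, 1]), ]
    expect_lt(max(abs(mu - rbind(c(0, 0), c(10, 10)))), 0.5)
    expect_lt(max(abs(mixtureWeights(fit) - 0.5)), 0.05)
    expect_true(all(diff(logLikTrace(fit)) > -1e-8))
  }
})

test_that("the log-likelihood trace is monotone on messy data too", {
  set.seed(5)
  X <- matrix(rt(600, df = 3), ncol = 3)
  for (k in c(2, 4)) {
    fit <- fitGMM(X, k = k, covType = "full", seed = k)
    expect_true(all(diff(logLikTrace(fit)) > -1e-8))
  }
})

test_that("free-parameter counts follow the covariance structure", {
  expect_identical(cardioclust:::.gmmNParams(9, 8, "full"), 404L)
  expect_identical(cardioclust:::.gmmNParams(9, 8, "diag"),
                   as.integer(8 + 72 + 72))
  expect_identical(cardioclust:::.gmmNParams(9, 8, "tied"),
                   as.integer(8 + 72 + 36))
  expect_identical(cardioclust:::.gmmNParams(1, 1, "full"), 2L)
})

test_that("BIC matches a hand computation at k = 1, d = 1", {
  x <- matrix(c(-1, 0, 1), ncol = 1)
  fit <- fitGMM(x, k = 1, covType = "full", seed = 1,
                standardize = FALSE, regCovar = 0)
  s2 <- 2 / 3
  ll <- -3 / 2 * log(2 * pi * s2) - sum(x^2) / (2 * s2)
  expect_equal(bic(fit, x), -2 * ll + 2 * log(3), tolerance = 1e-6)
})

test_that("BIC prefers one component on single-Gaussian data", {
  wins <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    X <- matrix(rnorm(1600), ncol = 2)
    b1 <- bic(fitGMM(X, 1, "full", seed = s), X)
    b5 <- bic(fitGMM(X, 5, "full", seed = s), X)
    wins <- wins + (b1 < b5)
  }
  expect_gte(wins, 19)
})

test_that("responsibilities normalize and dominate at component centers", {
  set.seed(7)
  X <- rbind(matrix(rnorm(300, sd = 0.5), ncol = 3),
             matrix(rnorm(300, mean = 30, sd = 0.5), ncol = 3))
  fit <- fitGMM(X, k = 2, covType = "full", seed = 7)
  pr <- predictClusters(fit, X)
  expect_equal(unname(rowSums(pr$responsibilities)),
               rep(1, nrow(X)), tolerance = 1e-9)
  atCenter <- predictClusters(fit, componentCenters(fit))
  expect_true(all(apply(atCenter$responsibilities, 1, max) > 0.999))
  # permutation of cases permutes assignments identically
  set.seed(8)
  p <- sample(nrow(X))
  expect_identical(predictClusters(fit, X[p, ])$assignments,
                   pr$assignments[p])
})

test_that("final log-likelihood matches an independent mixture oracle and
           a reference implementation", {
  suppressMessages(library(mclust))  # Mclust resolves helpers by attachment
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 150 + 10 * s
    d <- 2 + s %% 3
    X <- rbind(matrix(rnorm(n * d), ncol = d),
               matrix(rnorm(n * d, mean = 6), ncol = d))
    fit <- fitGMM(X, k = 2, covType = "full", seed = s,
                  standardize = FALSE, tol = 1e-8, regCovar = 1e-10)
    # oracle recomputation of the model's own likelihood
    llOracle <- gmmLoglikOracle(X, mixtureWeights(fit),
                                fit@means, mixtureCovariances(fit))
    expect_equal(fit@logLik, llOracle, tolerance = 1e-6)
    # reference EM at matched settings finds the same optimum
    mc <- suppressWarnings(mclust::Mclust(X, G = 2, modelNames = "VVV",
                                          verbose = FALSE))
    expect_lt(abs(fit@logLik - mc$loglik) / nrow(X), 1e-3)
  }
})

test_that("rescaling one feature shifts BIC by a constant for full
           covariances", {
  set.seed(9)
  X <- rbind(matrix(rnorm(400), ncol = 2),
             matrix(rnorm(400, mean = 8), ncol = 2))
  X2 <- X
  X2[, 1] <- X2[, 1] * 10
  f1 <- fitGMM(X, 2, "full", seed = 4, standardize = FALSE)
  f2 <- fitGMM(X2, 2, "full", seed = 4, standardize = FALSE)
  expect_equal(bic(f2, X2) - bic(f1, X), 2 * nrow(X) * log(10),
               tolerance = 0.1)
  a1 <- predictClusters(f1, X)$assignments
  a2 <- predictClusters(f2, X2)$assignments
  expect_gt(abs(cor(a1 == 1, a2 == 1)), 0.999)
})

test_that("no covariance eigenvalue falls below the regularization floor", {
  set.seed(10)
  X <- matrix(rnorm(200), ncol = 2)
  X <- rbind(X, X[1:20, ])  # duplicated points invite degeneracy
  for (ct in c("full", "diag", "tied")) {
    fit <- fitGMM(X, k = 3, covType = ct, seed = 2, regCovar = 1e-4)
    covs <- mixtureCovariances(fit)
    eigs <- switch(ct,
                   full = unlist(lapply(covs, function(S)
                     eigen(S, symmetric = TRUE, only.values = TRUE)$values)),
                   tied = eigen(covs, symmetric = TRUE,
                                only.values = TRUE)$values,
                   diag = as.numeric(covs))
    expect_true(all(eigs >= 1e-4 - 1e-12))
  }
})

test_that("degenerate inputs raise informative errors", {
  X <- matrix(rnorm(40), ncol = 2)
  expect_error(fitGMM(X, k = 0, covType = "full", seed = 1), "k must be")
  expect_error(fitGMM(X, k = 25, covType = "full", seed = 1),
               "more cases")
  expect_error(fitGMM(cbind(X, 1), k = 2, covType = "full", seed = 1),
               "constant")
  fit <- fitGMM(X, k = 2, covType = "full", seed = 1)
  expect_error(bic(fit, cbind(X, X)), "dimension mismatch")
  expect_error(predictClusters(fit, cbind(X, X)), "dimension mismatch")
})
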