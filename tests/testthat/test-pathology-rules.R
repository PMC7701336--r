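test_that("the bundled RVA cluster table is fully rule-positive", {
  rva <- referenceClusterCases("rva")
  expect_identical(nrow(rva), 11L)
  expect_true(all(ruleRVA(rva$V_RV_ED, rva$EF_RV)))
  expect_gte(min(rva$V_RV_ED), 130)
})

test_that("the bundled DCM cluster table is fully rule-positive", {
  dcm <- referenceClusterCases("dcm")
  expect_identical(nrow(dcm), 4L)
  expect_true(all(ruleDCM(dcm$V_LV_ED, dcm$EF_LV)))
  expect_lte(max(dcm$EF_LV), 0.30)
  expect_gt(min(dcm$V_LV_ED), 130)
})

test_that("thresholds are strict inequalities", {
  expect_false(ruleRVA(110, 0.40))
  expect_true(ruleRVA(110.0001, 0.40))
  expect_true(ruleRVA(110, 0.3999))
  expect_false(ruleDCM(100, 0.39))
  expect_false(ruleDCM(101, 0.40))
  expect_true(ruleDCM(100.0001, 0.3999))
  expect_false(ruleHCM(15, 0.60))
  expect_true(ruleHCM(15.0001, 0.50))
  expect_false(ruleHCM(16, 0.4999))
})

test_that("classifyCases derives the LV EDV and applies all rules", {
  tab <- normalFeatureRow(3)
  # case 2: RVA by volume; case 3: DCM (derived EDV > 100 with low EF)
  tab$V_RV_ED[2] <- 133.13
  tab$EF_RV[2] <- 0.6361
  tab$EF_LV[3] <- 0.1974
  tab$V_LV_ES[3] <- 189.28 * (1 - 0.1974)
  res <- classifyCases(tab)
  expect_equal(res$V_LV_ED[3], 189.28, tolerance = 1e-9)
  expect_identical(res$RVA, c(FALSE, TRUE, FALSE))
  expect_identical(res$DCM, c(FALSE, FALSE, TRUE))
  expect_identical(res$is_NOR, c(TRUE, FALSE, FALSE))
  expect_identical(res$labels, c("", "RVA", "DCM"))
  # low EF without dilation earns a note, never a label
  tab2 <- normalFeatureRow(1)
  tab2$EF_LV <- 0.35
  tab2$V_LV_ES <- 90 * (1 - 0.35)
  res2 <- classifyCases(tab2)
  expect_true(res2$is_NOR)
  expect_match(res2$note, "MINF")
  # unit validation
  tabBad <- normalFeatureRow(1)
  tabBad$EF_LV <- 66.41
  expect_error(classifyCases(tabBad), "percent")
})

test_that("classification commutes with row permutation", {
  coh <- smallCohort(seed = 4, n = 400)
  tab <- featureTable(coh)
  res <- classifyCases(tab)
  set.seed(1)
  p <- sample(nrow(tab))
  resP <- classifyCases(tab[p, ])
  rownames(resP) <- NULL
  expect_identical(resP, {
    x <- res[p, ]
    rownames(x) <- NULL
    x
  })
})

test_that("labelClusters labels only rule-saturated small clusters", {
  rva <- referenceClusterCases("rva")
  dcm <- referenceClusterCases("dcm")
  tab <- normalFeatureRow(nrow(rva) + nrow(dcm) + 30)
  # plant the printed measurements into the padded table
  tab$V_RV_ED[1:11] <- rva$V_RV_ED
  tab$EF_RV[1:11] <- rva$EF_RV
  tab$EF_LV[12:15] <- dcm$EF_LV
  tab$V_LV_ES[12:15] <- dcm$V_LV_ED * (1 - dcm$EF_LV)
  assignments <- c(rep(1, 11), rep(2, 4), rep(3, 30))
  lab <- labelClusters(assignments, tab, smallThreshold = 76)
  ct <- clusterTable(lab)
  expect_identical(ct$label, c("RVA", "DCM", "UNLABELED"))
  expect_equal(ct$frac_RVA[1], 1)
  expect_equal(ct$frac_DCM[2], 1)
  expect_identical(ct$size, c(11L, 4L, 30L))
  expect_identical(sum(ct$size), length(assignments))

  # a large cluster is never labeled under the default policy, even if
  # every member satisfies a rule
  tabL <- normalFeatureRow(100)
  tabL$V_RV_ED <- 140
  labL <- labelClusters(rep(1, 100), tabL, smallThreshold = 76)
  expect_identical(clusterTable(labL)$label, "UNLABELED")
  labL2 <- labelClusters(rep(1, 100), tabL, smallThreshold = 76,
                         labelLarge = TRUE)
  expect_identical(clusterTable(labL2)$label, "RVA")

  expect_error(labelClusters(assignments, tab, 76, minFrac = 0),
               "minFrac")
  expect_error(labelClusters(assignments[-1], tab, 76), "cover")
})

test_that("minFrac tolerates a single boundary member", {
  tab <- normalFeatureRow(10)
  tab$V_RV_ED <- c(rep(140, 9), 80)   # 9 of 10 satisfy the RVA rule
  lab <- labelClusters(rep(1, 10), tab, smallThreshold = 76)
  expect_identical(clusterTable(lab)$label, "RVA")
  lab2 <- labelClusters(rep(1, 10), tab, smallThreshold = 76,
                        minFrac = 0.95)
  expect_identical(clusterTable(lab2)$label, "UNLABELED")
})
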