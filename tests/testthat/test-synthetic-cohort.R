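test_that("subgroup counts, truncation rules and labels are exact", {
  cfg <- cohortSimConfig()
  expect_identical(sum(cfg$counts), 3822L)
  expect_identical(cfg$counts[["RVA"]], 11L)
  expect_identical(cfg$counts[["DCM"]], 4L)

  lat <- generateLatent(cohortSimConfig(nTotal = 600), seed = 5)
  expect_identical(nrow(lat), 600L)
  expect_identical(as.vector(table(lat$subgroup)[c("RVA", "DCM")]),
                   c(11L, 4L))
  expect_true(all(lat$V_LV_ES < lat$V_LV_ED))
  expect_true(all(lat$V_RV_ES < lat$V_RV_ED))
  expect_true(all(lat$V_LV_ED > 0 & lat$MT_LVM_ED > 0 & lat$RMD >= 0))
  rva <- lat[lat$subgroup == "RVA", ]
  dcm <- lat[lat$subgroup == "DCM", ]
  expect_true(all(rva$V_RV_ED > 130))
  expect_true(all(dcm$V_LV_ED > 130))
  expect_true(all(1 - dcm$V_LV_ES / dcm$V_LV_ED < 0.30))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- cohortSimConfig(nTotal = 400)
  a <- simulateCohort(cfg, seed = 9)
  b <- simulateCohort(cfg, seed = 9)
  expect_identical(featureTable(a), featureTable(b))
  expect_identical(groundTruthTable(a), groundTruthTable(b))
  c2 <- simulateCohort(cfg, seed = 10)
  expect_false(identical(featureTable(a), featureTable(c2)))
})

test_that("derived features satisfy the defining identities exactly", {
  lat <- generateLatent(cohortSimConfig(nTotal = 500), seed = 3)
  coh <- deriveFeatures(lat)
  m <- featureMatrix(coh)
  expect_equal(unname(m[, "EF_LV"]), 1 - lat$V_LV_ES / lat$V_LV_ED,
               tolerance = 1e-12)
  expect_equal(unname(m[, "EF_RV"]), 1 - lat$V_RV_ES / lat$V_RV_ED,
               tolerance = 1e-12)
  expect_equal(unname(m[, "R_RVLV_ED"]), lat$V_RV_ED / lat$V_LV_ED,
               tolerance = 1e-12)
  expect_equal(unname(m[, "R_LVMLV_ED"]), lat$V_LVM_ED / lat$V_LV_ED,
               tolerance = 1e-12)

  # a dilated low-EF case: ESV = 189.28 * (1 - 0.1974) = 151.9161
  one <- lat[1, ]
  one$V_LV_ED <- 189.28
  one$V_LV_ES <- 189.28 * (1 - 0.1974)
  expect_equal(unname(featureMatrix(deriveFeatures(one))[, "EF_LV"]),
               0.1974, tolerance = 1e-12)
  expect_equal(unname(round(one$V_LV_ES, 2)), 151.92)

  # identical RV and LV volumes give a unit ratio
  one$V_RV_ED <- one$V_LV_ED
  one$V_RV_ES <- one$V_LV_ED * 0.4
  expect_equal(unname(featureMatrix(deriveFeatures(one))[, "R_RVLV_ED"]),
               1, tolerance = 1e-12)
})

test_that("near-degenerate subgroup covariances collapse to their means", {
  cfg <- cohortSimConfig()
  sub <- cfg$subgroups
  for (nm in names(sub)) sub[[nm]]$cov <- diag(1e-10, 8)
  cfg2 <- cohortSimConfig(nTotal = 400, subgroups = sub)
  lat <- generateLatent(cfg2, seed = 2)
  rva <- lat[lat$subgroup == "RVA", ]
  mu <- sub$RVA$mean
  expect_equal(rva$V_RV_ED,
               rep(mu[["V_LV_ED"]] * exp(mu[["log_R_RVLV"]]), nrow(rva)),
               tolerance = 1e-3)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortSimConfig(nTotal = 100, counts = c(NOR_1 = 50)),
               "sum|subgroup")
  bad <- cohortSimConfig()$subgroups
  bad$NOR_1$cov[1, 2] <- 99   # asymmetric
  expect_error(cohortSimConfig(subgroups = bad), "positive definite")
  expect_error(cohortSimConfig(outlierRate = 1.5), "outlierRate")
})

test_that("pooled LV calibration matches the cohort moments", {
  coh <- simulateCohort(seed = 11)
  cd <- SummarizedExperiment::colData(coh)
  m <- featureMatrix(coh)
  expect_lt(abs(mean(cd$V_LV_ED) - 70.56), 2.0)
  expect_lt(abs(mean(m[, "EF_LV"]) - 0.6641), 0.02)
})

test_that("the planted ESV/EF redundancy survives sampling", {
  coh <- simulateCohort(cohortSimConfig(nTotal = 600), seed = 8)
  m <- featureMatrix(coh)
  expect_gt(abs(cor(m[, "V_LV_ES"], m[, "EF_LV"])), 0.7)
})

test_that("reference channel behaves as configured", {
  cfg0 <- cohortSimConfig(nTotal = 400, gtSlopeEdv = 1, gtInterceptEdv = 0,
                          gtSlopeEsv = 1, gtInterceptEsv = 0,
                          gtNoiseSd = 0, outlierRate = 0)
  coh <- deriveFeatures(generateLatent(cfg0, seed = 4))
  gt <- generateGroundTruth(coh, cfg0, seed = 4)
  cd <- SummarizedExperiment::colData(coh)
  expect_equal(gt$gt_V_LV_ED, unname(cd$V_LV_ED), tolerance = 1e-12)
  expect_equal(gt$gt_V_LV_ES, unname(featureMatrix(coh)[, "V_LV_ES"]),
               tolerance = 1e-12)
  expect_false(any(gt$gt_is_outlier))

  cfg5 <- cohortSimConfig(nTotal = 1000, outlierRate = 0.05)
  coh5 <- deriveFeatures(generateLatent(cfg5, seed = 4))
  gt5 <- generateGroundTruth(coh5, cfg5, seed = 4)
  expect_lte(abs(sum(gt5$gt_is_outlier) - 50), 1)

  # defaults inflate the reference means above the pipeline means
  cohD <- simulateCohort(cohortSimConfig(nTotal = 2000), seed = 6)
  gtD <- groundTruthTable(cohD)
  cdD <- SummarizedExperiment::colData(cohD)
  expect_gt(mean(gtD$gt_V_LV_ED), mean(cdD$V_LV_ED))
  expect_gt(mean(gtD$gt_V_LV_ES), mean(featureMatrix(cohD)[, "V_LV_ES"]))
})

test_that("cohort validity enforces the unit conventions", {
  m <- t(as.matrix(normalFeatureRow(3)[, cohortFeatureNames()]))
  colnames(m) <- paste0("c", 1:3)
  expect_s4_class(CardioCohort(m), "CardioCohort")
  m2 <- m
  m2["EF_LV", 1] <- 66.41   # percent instead of fraction
  expect_error(CardioCohort(m2), "percent")
})
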