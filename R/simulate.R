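# Synthetic cohort simulator.
#
# Latent parameterization: per case we draw, within its subgroup, a
# multivariate Gaussian over
#   (V_LV_ED, EF_LV, EF_RV, log R_RVLV, log R_LVMLV, log MT, log RMD,
#    log TMD)
# and derive the remaining physiology:
#   V_LV_ES = V_LV_ED * (1 - EF_LV),   V_RV_ED = V_LV_ED * R_RVLV,
#   V_RV_ES = V_RV_ED * (1 - EF_RV),   V_LVM_ED = V_LV_ED * R_LVMLV.
# Generating EF and EDV and deriving ESV makes the low-EF truncation of the
# dilated-cardiomyopathy subgroup exact, and generating the RV/LV and
# LVM/LV ratios independently of V_LV_ED gives ratio features that do not
# inherit the LV-size signal.

.LATENT <- c("V_LV_ED", "EF_LV", "EF_RV", "log_R_RVLV", "log_R_LVMLV",
             "log_MT", "log_RMD", "log_TMD")

# Within-subgroup correlation structure shared by all subgroups.  Signs
# encode: bigger LV <-> slightly lower EF; the two ejection fractions share
# a contractility factor; the motion-disparity scores rise as LV function
# falls; relative LV mass tracks function and wall thickness.
.latentCorrelation <- function() {
  nm <- .LATENT
  R <- diag(8)
  dimnames(R) <- list(nm, nm)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set2("V_LV_ED", "EF_LV", -0.48)
  set2("V_LV_ED", "EF_RV", -0.29)
  set2("V_LV_ED", "log_RMD", 0.20)
  set2("V_LV_ED", "log_TMD", 0.20)
  set2("EF_LV", "EF_RV", 0.70)
  set2("EF_LV", "log_R_LVMLV", 0.35)
  set2("EF_LV", "log_MT", 0.15)
  set2("EF_LV", "log_RMD", -0.72)
  set2("EF_LV", "log_TMD", -0.68)
  set2("EF_RV", "log_R_RVLV", -0.15)
  set2("EF_RV", "log_RMD", -0.30)
  set2("EF_RV", "log_TMD", -0.30)
  set2("log_R_LVMLV", "log_MT", 0.55)
  set2("log_R_LVMLV", "log_RMD", -0.20)
  set2("log_R_LVMLV", "log_TMD", -0.20)
  set2("log_MT", "log_RMD", -0.10)
  set2("log_MT", "log_TMD", -0.10)
  set2("log_RMD", "log_TMD", 0.55)
  R
}

.subgroupParams <- function() {
  corr <- .latentCorrelation()
  normalSd <- c(V_LV_ED = 15.4, EF_LV = 0.081, EF_RV = 0.046,
                log_R_RVLV = 0.114, log_R_LVMLV = 0.171, log_MT = 0.103,
                log_RMD = 0.342, log_TMD = 0.342)
  covFromSd <- function(sds) {
    S <- corr * (sds %o% sds)
    dimnames(S) <- list(.LATENT, .LATENT)
    S
  }
  # normal subgroups share LV size/function and RV volume and differ
  # jointly on RV ejection fraction, wall thickness, motion disparity and
  # relative LV mass -- a spread-out design (pairwise separation of about
  # 4 within-subgroup sd) so that the large clusters of the population are
  # genuinely distinguishable, as they are in screened cohorts
  efRv <- c(0.535, 0.626, 0.628, 0.533, 0.595, 0.628, 0.532)
  mt <- c(8.6, 7.6, 11.3, 11.3, 9.3, 7.6, 11.3)   # mm
  rmd <- c(-0.24, -0.21, 0.24, 0.02, 0.23, 0.24, -0.24)
  tmd <- c(-0.01, 0.04, 0.04, 0.04, -0.44, -0.40, -0.44)
  rlvm <- c(0.544, 0.854, 0.563, 0.850, 0.734, 0.502, 0.529)
  normals <- lapply(seq_len(7), function(i) {
    mu <- c(V_LV_ED = 71.45, EF_LV = 0.657, EF_RV = efRv[i],
            log_R_RVLV = log(75 / 71.45),
            log_R_LVMLV = log(rlvm[i]), log_MT = log(mt[i]),
            log_RMD = rmd[i], log_TMD = tmd[i])
    list(mean = mu, cov = covFromSd(normalSd), pathology = "NOR")
  })
  names(normals) <- paste0("NOR_", seq_len(7))

  # The rare pathological groups deviate from the population only on their
  # defining axes.  RVA: grossly dilated RV (RV/LV ratio about 2.2, an
  # empty moat above the normal ratio range) with a wide RV-EF spread; the
  # LV-myocardium motion-disparity scores stay at population level (RMD
  # and TMD quantify LV wall motion).  The group is internally compact on
  # the RV axes, matching the CV of about 0.12 in its published per-case
  # table.
  rvaSd <- normalSd
  rvaSd[["V_LV_ED"]] <- 7
  rvaSd[["EF_RV"]] <- 0.065
  rvaSd[["log_R_RVLV"]] <- 0.045
  rvaSd[["log_RMD"]] <- 0.18
  rvaSd[["log_TMD"]] <- 0.18
  rva <- list(mean = c(V_LV_ED = 70.45, EF_LV = 0.666, EF_RV = 0.58,
                       log_R_RVLV = log(2.20), log_R_LVMLV = log(0.652),
                       log_MT = log(9.3), log_RMD = 0.0, log_TMD = -0.2),
              cov = covFromSd(rvaSd), pathology = "RVA")

  # DCM: dilated LV with low ejection fraction (hence an extreme LV ESV),
  # reduced RV/LV and mass/volume ratios, moderately disturbed LV motion
  dcmSd <- normalSd
  dcmSd[["V_LV_ED"]] <- 18
  dcmSd[["EF_LV"]] <- 0.035
  dcmSd[["EF_RV"]] <- 0.05
  dcmSd[["log_R_RVLV"]] <- 0.10
  dcmSd[["log_RMD"]] <- 0.18
  dcmSd[["log_TMD"]] <- 0.18
  dcm <- list(mean = c(V_LV_ED = 182, EF_LV = 0.23, EF_RV = 0.55,
                       log_R_RVLV = log(0.45), log_R_LVMLV = log(0.45),
                       log_MT = log(8.6), log_RMD = 0.45, log_TMD = 0.25),
              cov = covFromSd(dcmSd), pathology = "DCM")

  c(normals, list(RVA = rva, DCM = dcm))
}

#' Simulation configuration for a synthetic cohort
#'
#' Defaults emulate a 3,822-case population cohort: seven overlapping
#' normal subgroups (differing in RV volume, RV ejection fraction and wall
#' thickness), a planted 11-case right-ventricular-abnormality (RVA)
#' subgroup with RV end-diastolic volumes truncated above 130 mL/m^2, and a
#' planted 4-case dilated-cardiomyopathy (DCM) subgroup with LV
#' end-diastolic volume above 130 mL/m^2 and LV ejection fraction below
#' 0.30.  Pooled LV end-diastolic volume, end-systolic volume and ejection
#' fraction are calibrated to means of about 70.6 mL/m^2, 24 mL/m^2 and
#' 0.664.  The reference ("ground-truth") measurement channel is generated
#' as a linear re-measurement of the LV volumes (default slopes/intercepts
#' 1.002/3.373 for EDV and 0.923/10.303 for ESV) with Gaussian noise and a
#' small fraction of gross multiplicative outliers.
#'
#' @param nTotal total number of cases.
#' @param counts named integer vector of subgroup sizes (names must match
#'   \code{subgroups}); must sum to \code{nTotal}.
#' @param subgroups named list of per-subgroup parameters, each a list with
#'   \code{mean} (named length-8 latent mean), \code{cov} (8 x 8 symmetric
#'   positive-definite latent covariance) and \code{pathology} ("NOR",
#'   "RVA" or "DCM").
#' @param gtSlopeEdv,gtInterceptEdv,gtSlopeEsv,gtInterceptEsv generative
#'   coefficients of the reference channel (mL/m^2 scale).
#' @param gtNoiseSd Gaussian noise of the reference channel, mL/m^2.
#' @param outlierRate fraction of reference rows replaced by outliers.
#' @param outlierScale multiplicative inflation applied to outlier rows.
#' @return A list of class \code{SimConfig}.
#' @export
#' @examples
#' cfg <- cohortSimConfig(nTotal = 400)
#' cfg$counts
cohortSimConfig <- function(nTotal = 3822L, counts = NULL,
                            subgroups = .subgroupParams(),
                            gtSlopeEdv = 1.002, gtInterceptEdv = 3.373,
                            gtSlopeEsv = 0.923, gtInterceptEsv = 10.303,
                            gtNoiseSd = 4, outlierRate = 0.02,
                            outlierScale = 2) {
  nTotal <- as.integer(nTotal)
  if (is.null(counts)) {
    # keep the planted rare subgroups at their default absolute sizes and
    # split the remainder over the 7 normal subgroups in fixed proportions
    rare <- c(RVA = 11L, DCM = 4L)
    if (nTotal < 200L)
      stop("default counts need nTotal >= 200; pass counts explicitly")
    prop <- c(889, 420, 380, 1075, 369, 350, 324) / 3807
    nor <- floor(prop * (nTotal - sum(rare)))
    nor[1] <- nor[1] + (nTotal - sum(rare) - sum(nor))
    counts <- c(setNames(as.integer(nor), paste0("NOR_", 1:7)), rare)
  }
  counts <- setNames(as.integer(counts), names(counts))
  if (sum(counts) != nTotal)
    stop("subgroup counts sum to ", sum(counts), ", not nTotal = ", nTotal)
  if (!setequal(names(counts), names(subgroups)))
    stop("counts and subgroups must name the same subgroups")
  if (outlierRate < 0 || outlierRate > 1)
    stop("outlierRate must lie in [0, 1]")
  for (nm in names(subgroups)) {
    S <- subgroups[[nm]]$cov
    if (max(abs(S - t(S))) > 1e-8 || min(eigen(S, symmetric = TRUE,
                                               only.values = TRUE)$values) <= 0)
      stop("latent covariance for subgroup ", nm,
           " is not symmetric positive definite")
  }
  structure(list(nTotal = nTotal, counts = counts, subgroups = subgroups,
                 gtSlopeEdv = gtSlopeEdv, gtInterceptEdv = gtInterceptEdv,
                 gtSlopeEsv = gtSlopeEsv, gtInterceptEsv = gtInterceptEsv,
                 gtNoiseSd = gtNoiseSd, outlierRate = outlierRate,
                 outlierScale = outlierScale),
            class = "SimConfig")
}

# subgroup-specific admissibility of a latent draw (truncation rules).
# Every subgroup is truncated at Mahalanobis distance 3 from its own
# center: a population screened free of overt disease carries no gross
# physiological outliers, which is what gives the rare pathological groups
# a real density gap to be discovered across (and keeps each subgroup a
# compact, near-Gaussian cloud).  The configured sds are drawn-scale
# values; truncation shrinks the realized marginal sds by about 12%, which
# the defaults already compensate for.
.latentOK <- function(L, sub) {
  ok <- L[, "V_LV_ED"] > 0 &
    L[, "EF_LV"] > 0.05 & L[, "EF_LV"] < 0.95 &
    L[, "EF_RV"] > 0.05 & L[, "EF_RV"] < 0.95
  z <- backsolve(chol(sub$cov), t(sweep(L, 2, sub$mean)),
                 transpose = TRUE)
  ok <- ok & colSums(z^2) <= 9
  if (sub$pathology == "RVA")
    ok <- ok & (L[, "V_LV_ED"] * exp(L[, "log_R_RVLV"])) > 130 &
      L[, "EF_RV"] > 0.28 & L[, "EF_RV"] < 0.74
  if (sub$pathology == "DCM")
    ok <- ok & L[, "V_LV_ED"] > 130 & L[, "EF_LV"] < 0.30 &
      L[, "EF_RV"] > 0.42
  ok
}

# the 8 non-redundant features (EF_LV excluded) derived from a latent
# matrix, used for the feature-space truncation test
.latentFeatures8 <- function(L) {
  cbind(V_RV_ED = L[, "V_LV_ED"] * exp(L[, "log_R_RVLV"]),
        V_LV_ES = L[, "V_LV_ED"] * (1 - L[, "EF_LV"]),
        EF_RV = L[, "EF_RV"],
        R_RVLV_ED = exp(L[, "log_R_RVLV"]),
        R_LVMLV_ED = exp(L[, "log_R_LVMLV"]),
        MT_LVM_ED = exp(L[, "log_MT"]),
        RMD = exp(L[, "log_RMD"]),
        TMD = exp(L[, "log_TMD"]))
}

#' Generate the latent physiological cohort
#'
#' Draws the latent multivariate-Gaussian physiology of every case (with
#' subgroup-specific truncation for the planted pathological subgroups) and
#' derives the end-systolic volumes.  Case order is shuffled so subgroups
#' are interleaved.
#'
#' @param config a \code{\link{cohortSimConfig}} object.
#' @param seed integer seed.
#' @return A data.frame (class \code{LatentCohort}) with case_id, subgroup,
#'   pathology and the physiological truth columns V_LV_ED, V_LV_ES,
#'   V_RV_ED, V_RV_ES, V_LVM_ED, MT_LVM_ED, RMD, TMD.
#' @export
#' @examples
#' lat <- generateLatent(cohortSimConfig(nTotal = 400), seed = 1)
#' table(lat$subgroup)[c("RVA", "DCM")]
generateLatent <- function(config, seed) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(.stageSeed(seed, "simulate"))
  pieces <- lapply(names(config$counts), function(nm) {
    n <- config$counts[[nm]]
    if (n == 0L) return(NULL)
    sub <- config$subgroups[[nm]]
    Lchol <- chol(sub$cov)
    draw <- function(m) {
      Z <- matrix(rnorm(m * 8), m, 8)
      L <- Z %*% Lchol
      L <- sweep(L, 2, sub$mean, "+")
      colnames(L) <- .LATENT
      L
    }
    drawTrunc <- function(m) {
      L <- draw(m)
      for (it in seq_len(200)) {
        bad <- which(!.latentOK(L, sub))
        if (!length(bad)) return(L)
        L[bad, ] <- draw(length(bad))
      }
      stop("truncation rejection did not terminate for ", nm)
    }
    L <- drawTrunc(n)
    # Normal subgroups are additionally ellipsoid-truncated in the
    # observable feature space (within-subgroup Mahalanobis^2 <= 9 over
    # the 8 non-redundant features): screened disease-free volunteers
    # carry no multivariate-outlying phenotypes, so the rare pathological
    # groups sit across real density gaps.  The nonlinear latent-to-
    # feature map would otherwise stretch latent-truncated corners into
    # feature-space outliers.
    if (sub$pathology == "NOR" && n >= 40L) {
      F8 <- .latentFeatures8(L)
      mu <- colMeans(F8)
      S <- cov(F8)
      M2 <- stats::mahalanobis(F8, mu, S)
      for (it in seq_len(500)) {
        bad <- which(M2 > 9)
        if (!length(bad)) break
        L[bad, ] <- drawTrunc(length(bad))
        M2[bad] <- stats::mahalanobis(.latentFeatures8(L[bad, , drop = FALSE]),
                                      mu, S)
        if (it == 500)
          stop("feature-space rejection did not terminate for ", nm)
      }
    }
    data.frame(subgroup = nm, pathology = sub$pathology, L,
               check.names = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  lat <- data.frame(
    case_id = sprintf("case_%05d", seq_len(nrow(out))),
    subgroup = out$subgroup, pathology = out$pathology,
    V_LV_ED = out$V_LV_ED,
    V_LV_ES = out$V_LV_ED * (1 - out$EF_LV),
    V_RV_ED = out$V_LV_ED * exp(out$log_R_RVLV),
    V_RV_ES = out$V_LV_ED * exp(out$log_R_RVLV) * (1 - out$EF_RV),
    V_LVM_ED = out$V_LV_ED * exp(out$log_R_LVMLV),
    MT_LVM_ED = exp(out$log_MT),
    RMD = exp(out$log_RMD),
    TMD = exp(out$log_TMD),
    row.names = NULL)
  class(lat) <- c("LatentCohort", "data.frame")
  lat
}

#' Derive the nine-feature table from latent physiology
#'
#' Computes the feature set from the latent volumes: ejection fractions as
#' 1 - ESV/EDV, the RV/LV and LVM/LV end-diastolic volume ratios, and the
#' pass-through features (RV EDV, LV ESV, maximal wall thickness, motion
#' disparities).
#'
#' @param latent a \code{LatentCohort} data.frame from
#'   \code{\link{generateLatent}}.
#' @return A \linkS4class{CardioCohort}; latent truth is kept in
#'   \code{colData}.
#' @export
#' @examples
#' coh <- deriveFeatures(generateLatent(cohortSimConfig(nTotal = 400), 1))
#' coh
deriveFeatures <- function(latent) {
  need <- c("case_id", "V_LV_ED", "V_LV_ES", "V_RV_ED", "V_RV_ES",
            "V_LVM_ED", "MT_LVM_ED", "RMD", "TMD")
  miss <- setdiff(need, colnames(latent))
  if (length(miss)) stop("latent table lacks: ", paste(miss, collapse = ", "))
  if (any(latent$V_LV_ED == 0) || any(latent$V_RV_ED == 0))
    stop("end-diastolic volumes must be non-zero")
  m <- rbind(
    V_RV_ED = latent$V_RV_ED,
    V_LV_ES = latent$V_LV_ES,
    EF_RV = 1 - latent$V_RV_ES / latent$V_RV_ED,
    EF_LV = 1 - latent$V_LV_ES / latent$V_LV_ED,
    R_RVLV_ED = latent$V_RV_ED / latent$V_LV_ED,
    R_LVMLV_ED = latent$V_LVM_ED / latent$V_LV_ED,
    MT_LVM_ED = latent$MT_LVM_ED,
    RMD = latent$RMD,
    TMD = latent$TMD)
  colnames(m) <- latent$case_id
  cd <- DataFrame(latent[, intersect(colnames(latent),
                                     c("case_id", "subgroup", "pathology",
                                       need)), drop = FALSE],
                  row.names = latent$case_id)
  CardioCohort(m, colData = cd)
}

#' Generate the noisy reference measurement channel
#'
#' Emulates an external ("ground-truth") measurement of the LV volumes: a
#' linear re-measurement of the pipeline values with Gaussian noise, plus a
#' configured fraction of rows replaced by gross multiplicative outliers
#' (both volumes inflated by \code{outlierScale}).  The reference ejection
#' fraction is computed from the reference volumes.
#'
#' @param cohort a \linkS4class{CardioCohort} whose colData carries the
#'   latent \code{V_LV_ED}.
#' @param config a \code{\link{cohortSimConfig}} object.
#' @param seed integer seed.
#' @return A data.frame with case_id, gt_V_LV_ED, gt_V_LV_ES, gt_EF_LV and
#'   the truth flag gt_is_outlier.
#' @export
generateGroundTruth <- function(cohort, config, seed) {
  stopifnot(is(cohort, "CardioCohort"), inherits(config, "SimConfig"))
  if (config$outlierRate < 0 || config$outlierRate > 1)
    stop("outlierRate must lie in [0, 1]")
  set.seed(.stageSeed(seed, "ground_truth"))
  n <- ncol(cohort)
  if (n == 0) stop("empty cohort")
  edv <- colData(cohort)$V_LV_ED
  esv <- featureMatrix(cohort)[, "V_LV_ES"]
  gtEdv <- config$gtSlopeEdv * edv + config$gtInterceptEdv +
    rnorm(n, 0, config$gtNoiseSd)
  gtEsv <- config$gtSlopeEsv * esv + config$gtInterceptEsv +
    rnorm(n, 0, config$gtNoiseSd)
  gtEsv <- pmin(gtEsv, 0.98 * gtEdv)  # keep the channel physiological
  gtEsv <- pmax(gtEsv, 0.02 * gtEdv)
  nOut <- round(config$outlierRate * n)
  isOut <- rep(FALSE, n)
  if (nOut > 0) {
    idx <- sample.int(n, nOut)
    isOut[idx] <- TRUE
    gtEdv[idx] <- gtEdv[idx] * config$outlierScale
    gtEsv[idx] <- gtEsv[idx] * config$outlierScale
  }
  data.frame(case_id = colnames(cohort), gt_V_LV_ED = gtEdv,
             gt_V_LV_ES = gtEsv, gt_EF_LV = 1 - gtEsv / gtEdv,
             gt_is_outlier = isOut, row.names = NULL)
}

#' Simulate a complete synthetic cohort
#'
#' Runs \code{\link{generateLatent}}, \code{\link{deriveFeatures}} and
#' \code{\link{generateGroundTruth}} and returns one
#' \linkS4class{CardioCohort} carrying features, subgroup/pathology truth
#' and the reference measurement channel.
#'
#' @param config a \code{\link{cohortSimConfig}}; defaults emulate the
#'   3,822-case study conditions.
#' @param seed integer master seed (per-stage seeds are derived from it).
#' @return A \linkS4class{CardioCohort}.
#' @export
#' @examples
#' coh <- simulateCohort(cohortSimConfig(nTotal = 400), seed = 7)
#' table(colData(coh)$pathology)
simulateCohort <- function(config = cohortSimConfig(), seed) {
  cohort <- deriveFeatures(generateLatent(config, seed))
  gt <- generateGroundTruth(cohort, config, seed)
  cd <- colData(cohort)
  cd$gt_V_LV_ED <- gt$gt_V_LV_ED
  cd$gt_V_LV_ES <- gt$gt_V_LV_ES
  cd$gt_EF_LV <- gt$gt_EF_LV
  cd$gt_is_outlier <- gt$gt_is_outlier
  colData(cohort) <- cd
  metadata(cohort)$seed <- seed
  metadata(cohort)$config <- config
  cohort
}
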