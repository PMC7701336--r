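# End-to-end orchestration: simulate -> screen -> sweep/select -> label ->
# validate, with optional artifact directory and content-hash manifest.

#' Run the full discovery pipeline
#'
#' Executes the stages in analysis order on a synthetic (or supplied)
#' cohort: redundancy screening of the nine features, a BIC sweep of
#' Gaussian mixtures over covariance structures and component numbers,
#' prevalence-gated model selection, threshold-rule labeling of the
#' resulting clusters, and the validation battery (PCA projection with
#' cluster centers, pairwise Welch/Mann-Whitney tests over the large
#' clusters, Huber comparison against the reference channel when present).
#' Per-stage seeds are derived deterministically from the master seed.
#'
#' @param config a \code{\link{cohortSimConfig}} used when no cohort is
#'   supplied.
#' @param seed master seed.
#' @param cohort optional pre-built \linkS4class{CardioCohort}; skips
#'   simulation.
#' @param ks,covTypes sweep grid, see \code{\link{sweepModels}}.
#' @param prevalenceFrac prevalence gate for small clusters.
#' @param rThreshold,micThreshold screening thresholds.
#' @param minFrac cluster-label satisfaction fraction.
#' @param outDir optional directory: writes all tabular/structured
#'   artifacts plus a content-hash manifest.
#' @param verbose print stage progress.
#' @return list of class \code{PipelineRun}: cohort, screening, grid,
#'   selection, assignments, labeling, pca, tests, gtComparison,
#'   parameters.
#' @export
#' @examples
#' \donttest{
#' run <- runPipeline(cohortSimConfig(nTotal = 600), seed = 1, ks = 2:6)
#' clusterTable(run$labeling)
#' }
runPipeline <- function(config = cohortSimConfig(), seed, cohort = NULL,
                        ks = 2:12, covTypes = c("tied", "diag", "full"),
                        prevalenceFrac = 0.02, rThreshold = 0.8,
                        micThreshold = 0.5, minFrac = 0.9, outDir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.null(cohort)) {
    say("simulating cohort")
    cohort <- simulateCohort(config, seed)
  }
  n <- ncol(cohort)

  say("screening features")
  screening <- screenFeatures(cohort, rThreshold = rThreshold,
                              micThreshold = micThreshold)
  X <- featureMatrix(cohort, selectedFeatures(screening))

  say("sweeping mixture models")
  grid <- sweepModels(X, ks = ks, covTypes = covTypes,
                      seed = .stageSeed(seed, "sweep"))
  selection <- selectModel(grid, n = n, prevalenceFrac = prevalenceFrac)
  model <- selectedModel(selection)
  assignments <- predictClusters(model, X)$assignments

  say("labeling clusters")
  labeling <- labelClusters(assignments, cohort,
                            smallThreshold = selection@smallThreshold,
                            minFrac = minFrac)

  say("validation battery")
  pca <- pcaProject(X, centers = componentCenters(model))
  sizes <- tabulate(assignments, nbins = nComponents(model))
  large <- which(sizes > selection@smallThreshold)
  tests <- if (length(large) >= 2)
    pairwiseClusterTests(X, assignments, clusters = large)
  else NULL
  gtComparison <- if (!is.null(groundTruthTable(cohort)))
    compareToGroundTruth(cohort, groundTruthTable(cohort))
  else NULL

  run <- structure(list(
    cohort = cohort, screening = screening, grid = grid,
    selection = selection, assignments = assignments,
    labeling = labeling, pca = pca, tests = tests,
    gtComparison = gtComparison,
    parameters = list(seed = seed, n = n, ks = ks, covTypes = covTypes,
                      prevalenceFrac = prevalenceFrac,
                      rThreshold = rThreshold,
                      micThreshold = micThreshold, minFrac = minFrac)),
    class = "PipelineRun")
  if (!is.null(outDir)) .writeRunArtifacts(run, outDir)
  run
}

.writeRunArtifacts <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outDir, f)
  writeCohortCSV(run$cohort, p("features.csv"))
  cd <- colData(run$cohort)
  truthCols <- intersect(c("case_id", "subgroup", "pathology"),
                         colnames(cd))
  write.csv(as.data.frame(cd[, truthCols, drop = FALSE]),
            p("truth_labels.csv"), row.names = FALSE)
  gt <- groundTruthTable(run$cohort)
  if (!is.null(gt)) write.csv(gt, p("ground_truth.csv"),
                              row.names = FALSE)
  .writeJSON(.screeningToList(run$screening), p("screening.json"))
  gtab <- gridTable(run$grid)
  gtab$sizes <- vapply(gtab$sizes, paste, character(1), collapse = ";")
  write.csv(gtab, p("bic_grid.csv"), row.names = FALSE)
  .writeJSON(.selectionToList(run$selection), p("selection.json"))
  write.csv(data.frame(case_id = colnames(run$cohort),
                       cluster = run$assignments),
            p("cluster_assignments.csv"), row.names = FALSE)
  write.csv(run$labeling@caseLabels, p("case_labels.csv"),
            row.names = FALSE)
  .writeJSON(clusterTable(run$labeling), p("cluster_labels.json"))
  write.csv(data.frame(case_id = colnames(run$cohort),
                       pc1 = run$pca$scores[, 1],
                       pc2 = run$pca$scores[, 2],
                       cluster = run$assignments),
            p("pca_scores.csv"), row.names = FALSE)
  write.csv(data.frame(cluster = seq_len(nrow(run$pca$centerScores)),
                       pc1 = run$pca$centerScores[, 1],
                       pc2 = run$pca$centerScores[, 2]),
            p("pca_center_scores.csv"), row.names = FALSE)
  if (!is.null(run$tests))
    write.csv(run$tests$table, p("test_matrix.csv"), row.names = FALSE)
  if (!is.null(run$gtComparison)) {
    gc <- run$gtComparison
    .writeJSON(list(table = gc$table, huber = gc$huber, n = gc$n),
               p("gt_comparison.json"))
  }
  .writeJSON(run$parameters, p("parameters.json"))
  files <- setdiff(list.files(outDir), "manifest.json")
  manifest <- list(files = lapply(setNames(files, files), function(f)
    unname(tools::md5sum(file.path(outDir, f)))))
  .writeJSON(manifest, p("manifest.json"))
  invisible(outDir)
}

#' @export
print.PipelineRun <- function(x, ...) {
  cat("PipelineRun on", x$parameters$n, "cases (seed",
      x$parameters$seed, ")\n")
  cat("selected features:",
      paste(selectedFeatures(x$screening), collapse = ", "), "\n")
  show(x$selection)
  show(x$labeling)
  invisible(x)
}
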