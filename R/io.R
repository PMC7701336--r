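# CSV / JSON / YAML readers and writers.  Convention enforced at the IO
# boundary: ejection fractions are stored as fractions in files; percent
# formatting is presentation only.  Feature values are written with 2
# decimals.

#' Read a cohort feature CSV
#'
#' Validates the canonical header (case_id plus the nine features, in
#' order), numeric parsing and the ejection-fraction unit convention.
#'
#' @param path CSV file path.
#' @return A \linkS4class{CardioCohort}.
#' @export
readCohortCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(read.csv(path, check.names = FALSE,
                           colClasses = c(case_id = "character")),
                  error = function(e)
                    stop("cannot parse ", path, ": ", conditionMessage(e)))
  want <- c("case_id", .FEATURES)
  if (!identical(colnames(tab), want)) {
    miss <- setdiff(want, colnames(tab))
    extra <- setdiff(colnames(tab), want)
    stop("schema mismatch in ", path,
         if (length(miss)) paste0("; missing: ",
                                  paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")),
         "; expected header: ", paste(want, collapse = ","))
  }
  if (nrow(tab) == 0) stop("no rows in ", path)
  for (f in .FEATURES) {
    v <- tab[[f]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in column ", f, ", row ", bad)
    }
    if (anyNA(v)) stop("missing value in column ", f, ", row ",
                       which(is.na(v))[1])
  }
  for (f in .EF_FEATURES)
    if (any(tab[[f]] <= 0 | tab[[f]] >= 1))
      stop(f, " outside (0, 1) in ", path, "; a value like 66.41 ",
           "suggests percent instead of fraction units")
  m <- t(as.matrix(tab[, .FEATURES]))
  colnames(m) <- tab$case_id
  CardioCohort(m)
}

#' Write a cohort feature CSV
#'
#' Writes the canonical feature table (values rounded to 2 decimals,
#' ejection fractions as fractions).
#'
#' @param x a \linkS4class{CardioCohort}.
#' @param path output file.
#' @param digits rounding applied on write.
#' @return \code{path}, invisibly.
#' @export
writeCohortCSV <- function(x, path, digits = 2) {
  tab <- featureTable(x)
  tab[.FEATURES] <- lapply(tab[.FEATURES], function(v)
    formatC(round(v, digits), format = "f", digits = digits))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a simulation configuration
#'
#' YAML (default) or JSON, chosen by file extension.  Matrices are stored
#' row-wise with their dimnames and restored exactly.
#'
#' @param config a \code{\link{cohortSimConfig}} object.
#' @param path file ending in .yaml/.yml or .json.
#' @return \code{readSimConfig} returns the restored \code{SimConfig};
#'   \code{writeSimConfig} returns \code{path} invisibly.
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(inherits(config, "SimConfig"))
  ser <- unclass(config)
  ser$counts <- as.list(ser$counts)
  ser$subgroups <- lapply(ser$subgroups, function(s)
    list(mean = as.list(s$mean),
         cov = list(values = as.numeric(t(s$cov)),
                    names = colnames(s$cov)),
         pathology = s$pathology))
  if (grepl("\\.json$", path))
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ser <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  subgroups <- lapply(ser$subgroups, function(s) {
    nm <- unlist(s$cov$names)
    S <- matrix(as.numeric(unlist(s$cov$values)), length(nm), length(nm),
                byrow = TRUE, dimnames = list(nm, nm))
    list(mean = unlist(s$mean), cov = S, pathology = s$pathology)
  })
  cohortSimConfig(
    nTotal = ser$nTotal, counts = unlist(ser$counts),
    subgroups = subgroups, gtSlopeEdv = ser$gtSlopeEdv,
    gtInterceptEdv = ser$gtInterceptEdv, gtSlopeEsv = ser$gtSlopeEsv,
    gtInterceptEsv = ser$gtInterceptEsv, gtNoiseSd = ser$gtNoiseSd,
    outlierRate = ser$outlierRate, outlierScale = ser$outlierScale)
}

# --- structured artifact writers used by runPipeline -----------------------

.writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)

.screeningToList <- function(report) {
  list(featureNames = report@featureNames,
       rThreshold = report@rThreshold, micThreshold = report@micThreshold,
       pairs = pairTable(report), dropped = report@dropped,
       selected = report@selected)
}

.selectionToList <- function(sel) {
  r <- sel@rationale
  r$smallCounts <- as.list(setNames(as.integer(r$smallCounts),
                                    names(sel@smallCounts)))
  r
}
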