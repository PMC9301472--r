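#' Assemble a cohort from connectivity matrices and phenotypes
#'
#' @param matrices A list of [ConnectivityMatrix-class] objects (or plain
#'   symmetric matrices) sharing ROI labels, one per subject.
#' @param phenotypes A data.frame with columns `subject_id`, `site`, `age`,
#'   `sex` and at least one severity-score column. Row order must match
#'   `matrices` unless matrices carry subject ids, in which case they are
#'   aligned by id.
#' @param targetName Name of the score column used for modeling.
#' @return A [ConnectivityCohort-class].
#' @export
#' @examples
#' m <- replicate(3, {
#'   a <- matrix(rnorm(16), 4); a <- a + t(a); diag(a) <- 0; a
#' }, simplify = FALSE)
#' ph <- data.frame(
#'   subject_id = c("s1", "s2", "s3"), site = "A",
#'   age = c(10, 12, 14), sex = c(0, 1, 0), score = c(4, 6, 8)
#' )
#' coh <- ConnectivityCohort(m, ph, targetName = "score")
#' coh
ConnectivityCohort <- function(matrices, phenotypes, targetName = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  cms <- lapply(seq_along(matrices), function(k) {
    m <- matrices[[k]]
    if (is(m, "ConnectivityMatrix")) m else ConnectivityMatrix(m)
  })
  n <- nrow(cms[[1]]@values)
  labs <- cms[[1]]@roiLabels
  for (cm in cms) {
    if (nrow(cm@values) != n)
      stop("all matrices must share the same number of ROIs (found ",
        nrow(cm@values), " and ", n, ")", call. = FALSE)
  }
  kinds <- unique(vapply(cms, function(x) x@kind, character(1)))
  thr <- unique(vapply(cms, function(x) x@isThresholded, logical(1)))
  std <- unique(vapply(cms, function(x) x@isStandardized, logical(1)))
  if (length(kinds) > 1 || length(thr) > 1 || length(std) > 1)
    stop("all matrices must share kind and preprocessing flags", call. = FALSE)

  phenotypes <- as.data.frame(phenotypes)
  if (nrow(phenotypes) != length(cms))
    stop("need exactly one phenotype row per matrix (", nrow(phenotypes),
      " rows, ", length(cms), " matrices)", call. = FALSE)
  ids <- vapply(cms, function(x) x@subjectId, character(1))
  if (all(nzchar(ids))) {
    miss <- setdiff(phenotypes$subject_id, ids)
    if (length(miss))
      stop("phenotype rows without a matrix: ", paste(miss, collapse = ", "),
        call. = FALSE)
    cms <- cms[match(phenotypes$subject_id, ids)]
  }
  if (!is.null(targetName)) {
    if (!targetName %in% colnames(phenotypes))
      stop("target column '", targetName, "' not found in phenotypes",
        call. = FALSE)
    if (anyNA(phenotypes[[targetName]]))
      stop("target column '", targetName, "' has missing values", call. = FALSE)
  }
  assay <- vapply(cms, function(x) as.vector(x@values), numeric(n * n))
  colnames(assay) <- phenotypes$subject_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(connectivity = assay),
    colData = S4Vectors::DataFrame(phenotypes)
  )
  S4Vectors::metadata(se) <- list(
    roiLabels = labs, kind = kinds, isThresholded = thr, isStandardized = std,
    targetName = targetName
  )
  new("ConnectivityCohort", se)
}

#' @describeIn ConnectivityCohort-class Number of ROIs.
#' @export
setMethod("nROIs", "ConnectivityCohort", function(x) {
  length(S4Vectors::metadata(x)$roiLabels)
})

#' @describeIn ConnectivityCohort-class ROI labels.
#' @export
setMethod("roiLabels", "ConnectivityCohort", function(x) {
  S4Vectors::metadata(x)$roiLabels
})

#' @describeIn ConnectivityCohort-class Preprocessing flag.
#' @export
setMethod("isThresholded", "ConnectivityCohort", function(x) {
  S4Vectors::metadata(x)$isThresholded
})

#' @describeIn ConnectivityCohort-class Preprocessing flag.
#' @export
setMethod("isStandardized", "ConnectivityCohort", function(x) {
  S4Vectors::metadata(x)$isStandardized
})

#' @describeIn ConnectivityCohort-class Edge estimation method.
#' @export
setMethod("edgeKind", "ConnectivityCohort", function(x) {
  S4Vectors::metadata(x)$kind
})

#' Extract one subject's connectivity matrix from a cohort
#'
#' @param x A [ConnectivityCohort-class].
#' @param subject Column index or subject id.
#' @return Numeric `n x n` matrix.
#' @export
connMatrix <- function(x, subject) {
  stopifnot(is(x, "ConnectivityCohort"))
  n <- nROIs(x)
  v <- SummarizedExperiment::assay(x, "connectivity")[, subject]
  matrix(v, n, n)
}

#' All connectivity matrices of a cohort as a list
#'
#' @param x A [ConnectivityCohort-class].
#' @return List of `n x n` matrices, one per subject.
#' @export
connMatrices <- function(x) {
  stopifnot(is(x, "ConnectivityCohort"))
  n <- nROIs(x)
  a <- SummarizedExperiment::assay(x, "connectivity")
  lapply(seq_len(ncol(a)), function(k) matrix(a[, k], n, n))
}

#' Modeling target of a cohort
#'
#' @param x A [ConnectivityCohort-class].
#' @param targetName Optional score column name; defaults to the cohort's
#'   stored target.
#' @return Numeric vector of severity scores (one per subject).
#' @export
severityTarget <- function(x, targetName = NULL) {
  if (is.null(targetName)) targetName <- S4Vectors::metadata(x)$targetName
  if (is.null(targetName))
    stop("cohort has no target column set; pass targetName", call. = FALSE)
  as.numeric(SummarizedExperiment::colData(x)[[targetName]])
}

#' @export
#' @describeIn ConnectivityCohort-class Compact display.
setMethod("show", "ConnectivityCohort", function(object) {
  md <- S4Vectors::metadata(object)
  cat("ConnectivityCohort:", ncol(object), "subjects x", nROIs(object),
    "ROIs\n")
  cat("  edge kind:", md$kind,
    "| thresholded:", md$isThresholded,
    "| standardized:", md$isStandardized, "\n")
  cat("  sites:", paste(names(table(object$site)), "(",
    as.integer(table(object$site)), ")", collapse = " "), "\n")
  if (!is.null(md$targetName)) {
    y <- severityTarget(object)
    cat(sprintf("  target '%s': mean %.3g, sd %.3g, range [%.3g, %.3g]\n",
      md$targetName, mean(y), stats::sd(y), min(y), max(y)))
  }
})

#' Load a cohort from files on disk
#'
#' Reads either per-subject ROI time-series files (rows = timepoints,
#' columns = labelled ROIs) or precomputed square connectivity files, plus a
#' phenotype CSV with columns `subject_id`, `site`, `age`, `sex` and score
#' columns. File base names (minus extension) must match `subject_id`
#' values. TSV and CSV are auto-detected from the extension.
#'
#' @param paths Character vector of time-series or matrix files.
#' @param phenotypePath Phenotype CSV path.
#' @param type `"timeseries"` or `"matrix"`.
#' @param targetName Score column used for modeling.
#' @param edge For `type = "timeseries"`: `"pearson"` or `"tikhonov"`.
#' @param rho Tikhonov regularization (used when `edge = "tikhonov"`).
#' @param verbose Print a cohort summary.
#' @return A [ConnectivityCohort-class].
#' @export
loadCohort <- function(paths, phenotypePath, type = c("matrix", "timeseries"),
                       targetName = NULL, edge = c("pearson", "tikhonov"),
                       rho = 0.1, verbose = TRUE) {
  type <- match.arg(type)
  edge <- match.arg(edge)
  ph <- utils::read.csv(phenotypePath, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "site", "age", "sex") %in% colnames(ph)))
    stop("phenotype file must have subject_id, site, age, sex columns",
      call. = FALSE)
  readTab <- function(p) {
    sep <- if (grepl("\\.tsv$", p, ignore.case = TRUE)) "\t" else ","
    out <- tryCatch(
      utils::read.table(p, header = TRUE, sep = sep, check.names = FALSE),
      error = function(e) stop("cannot read '", p, "': ", conditionMessage(e),
        call. = FALSE)
    )
    out
  }
  ids <- sub("\\.[^.]*$", "", basename(paths))
  miss <- setdiff(ph$subject_id, ids)
  if (length(miss))
    stop("phenotype rows without a data file: ", paste(miss, collapse = ", "),
      call. = FALSE)
  extra <- setdiff(ids, ph$subject_id)
  if (length(extra))
    stop("data files without a phenotype row: ", paste(extra, collapse = ", "),
      call. = FALSE)
  mats <- lapply(seq_along(paths), function(k) {
    tab <- readTab(paths[k])
    if (type == "timeseries") {
      ts <- as.matrix(tab)
      if (edge == "pearson") pearsonConnectivity(ts, subjectId = ids[k])
      else tikhonovConnectivity(ts, rho = rho, subjectId = ids[k])
    } else {
      labs <- colnames(tab)
      if (!is.numeric(as.matrix(tab)[, 1])) { # first column holds labels
        labs <- colnames(tab)[-1]
        tab <- tab[, -1]
      }
      m <- unname(as.matrix(tab))
      if (nrow(m) != ncol(m))
        stop("connectivity file '", paths[k], "' is not square", call. = FALSE)
      ConnectivityMatrix(m, roiLabels = labs, subjectId = ids[k])
    }
  })
  ns <- vapply(mats, function(m) nrow(m@values), integer(1))
  if (length(unique(ns)) != 1)
    stop("inconsistent ROI counts across files: ",
      paste(unique(ns), collapse = ", "), call. = FALSE)
  ## a sidecar written by writeCohort restores edge kind, preprocessing
  ## flags and the default modeling target
  metaPath <- file.path(dirname(phenotypePath), "cohort_meta.json")
  if (type == "matrix" && file.exists(metaPath)) {
    meta <- readCohortMeta(metaPath)
    mats <- lapply(mats, function(m) {
      initialize(m, kind = meta$kind, isThresholded = meta$isThresholded,
        isStandardized = meta$isStandardized)
    })
    if (is.null(targetName) && !is.null(meta$targetName) &&
      meta$targetName %in% colnames(ph))
      targetName <- meta$targetName
  }
  coh <- ConnectivityCohort(mats, ph, targetName = targetName)
  if (verbose) show(coh)
  coh
}

## minimal parser for the writeCohort sidecar (flat JSON object of
## strings/booleans; avoids a hard dependency on a JSON package)
readCohortMeta <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  grab <- function(key) {
    m <- regmatches(txt, regexec(
      sprintf('"%s"\\s*:\\s*("([^"]*)"|true|false)', key), txt))[[1]]
    if (length(m) < 2) return(NULL)
    if (m[2] %in% c("true", "false")) return(m[2] == "true")
    m[3]
  }
  list(
    kind = if (is.null(grab("kind"))) "raw" else grab("kind"),
    isThresholded = isTRUE(grab("isThresholded")),
    isStandardized = isTRUE(grab("isStandardized")),
    targetName = grab("targetName")
  )
}

#' Write a cohort to plain-text files
#'
#' Writes one square TSV per subject (ROI labels as header) plus a phenotype
#' CSV, the inverse of [loadCohort()] with `type = "matrix"`.
#'
#' @param x A [ConnectivityCohort-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written matrix paths.
#' @export
writeCohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- x$subject_id
  labs <- roiLabels(x)
  paths <- file.path(dir, paste0(ids, ".tsv"))
  for (k in seq_along(ids)) {
    m <- connMatrix(x, k)
    colnames(m) <- labs
    utils::write.table(m, paths[k], sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  ph <- as.data.frame(SummarizedExperiment::colData(x))
  utils::write.csv(ph, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  md <- S4Vectors::metadata(x)
  meta <- sprintf(
    '{"kind": "%s", "isThresholded": %s, "isStandardized": %s%s}',
    md$kind, tolower(md$isThresholded), tolower(md$isStandardized),
    if (is.null(md$targetName)) "" else
      sprintf(', "targetName": "%s"', md$targetName)
  )
  writeLines(meta, file.path(dir, "cohort_meta.json"))
  invisible(paths)
}
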