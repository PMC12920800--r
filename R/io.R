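#' Read a labelled matrix from a delimited text file
#'
#' Expects a header row of feature names and a first column of observation
#' labels. The delimiter is auto-detected from the header (comma, tab or
#' semicolon) unless forced. Parsing is locale-independent with '.' as the
#' decimal separator; any non-numeric cell is rejected with its row and
#' column named, as are ragged rows and duplicate labels.
#'
#' @param path file to read.
#' @param delim delimiter; NULL (default) auto-detects.
#' @return labelled numeric matrix.
#' @export
read_labeled_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    counts <- vapply(c(",", "\t", ";"),
                     function(d) lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
                     integer(1))
    delim <- names(which.max(counts))
    if (max(counts) == 0L)
      stop("could not detect a delimiter in the header of ", path,
           call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", check.names = FALSE,
                          row.names = NULL, quote = "\"",
                          strip.white = TRUE, comment.char = "")
  if (ncol(df) < 2L)
    stop("expected a label column plus at least one feature column",
         call. = FALSE)
  labels <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell '%s' at observation '%s', feature '%s'",
                 cells[bad[1L, , drop = FALSE]], labels[bad[1L, 1L]],
                 colnames(cells)[bad[1L, 2L]]), call. = FALSE)
  dimnames(values) <- list(labels, colnames(cells))
  as_labeled_matrix(values)
}

#' Write a labelled matrix to a delimited text file
#'
#' Values are written with 17 significant digits so a write-then-read
#' round trip is bit-identical.
#'
#' @param x labelled numeric matrix.
#' @param path output file.
#' @param delim delimiter (default comma).
#' @param label_header name of the label column in the header.
#' @return \code{path}, invisibly.
#' @export
write_labeled_matrix <- function(x, path, delim = ",", label_header = "id") {
  x <- as_labeled_matrix(x)
  lines <- c(paste(c(label_header, colnames(x)), collapse = delim),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])),
                     collapse = delim)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Serialise a grid report (or audit report) to JSON
#'
#' The JSON document carries the tool version, the input fingerprint, the
#' settings and the per-check outcomes with machine-readable status strings
#' (never display glyphs). Pairwise feature and observation tables, when
#' present, are written as CSV files next to the JSON. Re-running on
#' identical input yields an identical payload.
#'
#' @param report a \code{grid_report} or \code{audit_report}.
#' @param path output JSON file.
#' @param pair_csv write companion CSV tables next to the JSON
#'   (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, pair_csv = TRUE) {
  if (inherits(report, "grid_report")) {
    payload <- lapply(unname(report$outcomes), function(o) {
      list(check_id = o$check_id, status = o$status,
           max_abs_dev = o$max_abs_dev, tolerance = o$tolerance,
           detail = o$detail, approximation = isTRUE(o$approximation))
    })
    doc <- list(tool = "biplotgrid",
                version = as.character(utils::packageVersion("biplotgrid")),
                kind = "grid_report",
                fingerprint = report$fingerprint,
                settings = report$settings,
                outcomes = payload)
    if (pair_csv && !is.null(report$feature_pairs))
      utils::write.csv(report$feature_pairs,
                       sub("\\.json$", "_feature_pairs.csv", path),
                       row.names = FALSE)
    if (pair_csv && !is.null(report$observation_pairs))
      utils::write.csv(report$observation_pairs,
                       sub("\\.json$", "_observation_pairs.csv", path),
                       row.names = FALSE)
  } else if (inherits(report, "audit_report")) {
    doc <- list(tool = "biplotgrid",
                version = as.character(utils::packageVersion("biplotgrid")),
                kind = "audit_report",
                verdicts = lapply(seq_len(nrow(report)), function(i) {
                  list(artifact = report$artifact[i],
                       symbol = report$symbol[i],
                       max_abs_dev = report$max_abs_dev[i],
                       detail = report$detail[i])
                }))
  } else {
    stop("report must be a grid_report or audit_report", call. = FALSE)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Export model summary files for a fitted PCA
#'
#' Writes \code{<prefix>_scores.csv}, \code{<prefix>_loadings.csv} and
#' \code{<prefix>_summary.json} (eigenvalues, singular values, variance
#' explained) at full precision.
#'
#' @param fit a \code{pca_fit}.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_pca_outputs <- function(fit, prefix) {
  stopifnot(inherits(fit, "pca_fit"))
  files <- c(scores = paste0(prefix, "_scores.csv"),
             loadings = paste0(prefix, "_loadings.csv"),
             summary = paste0(prefix, "_summary.json"))
  write_labeled_matrix(fit$scores, files[["scores"]])
  write_labeled_matrix(fit$loadings, files[["loadings"]],
                       label_header = "feature")
  jsonlite::write_json(list(
    eigenvalues = fit$eigenvalues,
    singular_values = fit$singular_values,
    var_explained = fit$var_explained,
    n = fit$n, m = fit$m, method = fit$method
  ), files[["summary"]], digits = NA, pretty = TRUE)
  invisible(files)
}

#' Export biplot coordinates as a stacked CSV
#'
#' Observation rows (role \code{observation}) and feature rows (role
#' \code{feature}) are stacked with a role column, at full precision.
#'
#' @param coords a \code{biplot_coords}.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
write_biplot_coords <- function(coords, path) {
  stopifnot(inherits(coords, "biplot_coords"))
  df <- rbind(
    data.frame(label = rownames(coords$A), role = "observation",
               coords$A, check.names = FALSE),
    data.frame(label = rownames(coords$B), role = "feature",
               coords$B, check.names = FALSE))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(z) sprintf("%.17g", z))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
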