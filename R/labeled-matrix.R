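#' Validate a labelled data matrix
#'
#' The basic data container throughout the package is a plain numeric matrix
#' of n observations (rows) by m features (columns) carrying unique row and
#' column labels in its \code{dimnames}. Data frames of numeric columns are
#' coerced. Labels are generated (\code{obs1..}, \code{feat1..}) when absent.
#'
#' @param x numeric matrix or data frame of numeric columns.
#' @param min_rows minimum number of rows required (default 2).
#' @return a validated numeric matrix with unique dimnames.
#' @export
as_labeled_matrix <- function(x, min_rows = 2L) {
  if (is.data.frame(x)) {
    if (!all(vapply(x, is.numeric, logical(1))))
      stop("all columns must be numeric", call. = FALSE)
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("input must be a numeric matrix or data frame", call. = FALSE)
  if (nrow(x) < min_rows)
    stop("at least ", min_rows, " observations (rows) are required", call. = FALSE)
  if (ncol(x) < 1L)
    stop("at least one feature (column) is required", call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite entry at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("obs", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("feat", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate row labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate column labels: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  x
}

#' Column-centre a data matrix
#'
#' Subtracts each column's mean, yielding the centred matrix Y with
#' y_ij = x_ij - mean(x_j). Centring leaves per-column sample variances
#' unchanged. The original column means are kept in the
#' \code{"original_means"} attribute so the raw matrix can be reconstructed.
#'
#' @param x labelled numeric matrix (see [as_labeled_matrix()]).
#' @return centred matrix with attribute \code{original_means}.
#' @examples
#' y <- center_columns(matrix(c(1, 3, 2, 4), 2, 2))
#' colMeans(y)  # all zero
#' @export
center_columns <- function(x) {
  x <- as_labeled_matrix(x)
  mu <- colMeans(x)
  y <- sweep(x, 2L, mu, "-")
  attr(y, "original_means") <- mu
  y
}

#' Test whether a matrix is column-centred
#'
#' A column counts as centred when its mean is zero within \code{tol} times
#' the column's largest absolute value (or \code{tol} itself for an all-zero
#' column).
#'
#' @param y numeric matrix.
#' @param tol relative tolerance (default 1e-12).
#' @return logical.
#' @export
is_centered <- function(y, tol = 1e-12) {
  scale_ <- pmax(apply(abs(y), 2L, max), 1)
  all(abs(colMeans(y)) <= tol * scale_)
}

# Centre unless already centred; used by entry points that accept either a
# raw or a pre-centred matrix.
ensure_centered <- function(x) {
  x <- as_labeled_matrix(x)
  if (is_centered(x)) {
    if (is.null(attr(x, "original_means")))
      attr(x, "original_means") <- rep(0, ncol(x))
    x
  } else {
    center_columns(x)
  }
}

#' Min-max unitisation of each feature
#'
#' Rescales every column to the unit interval via (x - min) / (max - min),
#' the usual preprocessing when features are on incommensurate scales but a
#' correlation-matrix PCA is not wanted. Constant columns have no range and
#' are rejected.
#'
#' @param x labelled numeric matrix.
#' @return matrix with every column spanning exactly [0, 1].
#' @examples
#' unitise(cbind(a = c(1, 3, 5)))
#' @export
unitise <- function(x) {
  x <- as_labeled_matrix(x)
  rng <- apply(x, 2L, range)
  flat <- rng[2L, ] - rng[1L, ] <= 0
  if (any(flat))
    stop("constant column(s) cannot be unitised: ",
         paste(colnames(x)[flat], collapse = ", "), call. = FALSE)
  sweep(sweep(x, 2L, rng[1L, ], "-"), 2L, rng[2L, ] - rng[1L, ], "/")
}
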