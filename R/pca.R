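#' Fit a reference principal component analysis
#'
#' Fits PCA on a labelled data matrix by either of the two classical routes:
#' a thin SVD of the centred matrix Y = U D V' (the default, numerically the
#' stabler), or an eigendecomposition of the sample covariance matrix
#' S = Y'Y/(n-1). After sign canonicalisation the two routes return the same
#' model to machine precision: scores satisfy Z = Y V = U D, score variances
#' equal the eigenvalues, and singular values satisfy
#' ell_k = sqrt(n-1) sqrt(lambda_k).
#'
#' Centring is on by default and standardisation is not: features already on
#' a common scale should be analysed on the covariance matrix. Min-max
#' unitisation and correlation-matrix PCA are available as explicit options.
#'
#' @param x labelled numeric matrix or data frame, observations by features.
#' @param method decomposition route, \code{"svd"} (default) or
#'   \code{"eigen"}.
#' @param center subtract column means (default TRUE).
#' @param unitise min-max rescale each column to [0, 1] before centring.
#' @param standardise divide centred columns by their standard deviation
#'   (correlation-matrix PCA); off by default.
#' @param canonical_signs apply the largest-entry-positive sign convention to
#'   loadings (and co-flip scores). Set FALSE to keep the raw decomposition
#'   signs, as needed when emulating other implementations.
#' @return an object of class \code{"pca_fit"}: a list with components
#'   \code{loadings} (m x r matrix V), \code{eigenvalues} (lambda, length r),
#'   \code{singular_values} (ell), \code{scores} (n x r matrix Z),
#'   \code{u} (n x r left singular vectors), \code{score_sd} (sqrt(lambda)),
#'   \code{var_explained} (fractions summing to 1), \code{center}
#'   (subtracted means), \code{y} (the centred, possibly rescaled, matrix),
#'   \code{n}, \code{m}, \code{method}, \code{null_flags}.
#' @examples
#' fit <- fit_pca(pca_fixture("toy_table2")$matrix)
#' fit$eigenvalues            # 21.28, 0.81
#' summary(fit)
#' @export
fit_pca <- function(x, method = c("svd", "eigen"), center = TRUE,
                    unitise = FALSE, standardise = FALSE,
                    canonical_signs = TRUE) {
  method <- match.arg(method)
  x <- as_labeled_matrix(x)
  if (unitise) x <- unitise(x)
  if (center) {
    y <- center_columns(x)
  } else {
    y <- x
    attr(y, "original_means") <- rep(0, ncol(x))
  }
  scale_sd <- NULL
  if (standardise) {
    scale_sd <- apply(y, 2L, stats::sd)
    if (any(scale_sd <= 0))
      stop("zero-variance column(s) cannot be standardised: ",
           paste(colnames(y)[scale_sd <= 0], collapse = ", "), call. = FALSE)
    mu <- attr(y, "original_means")
    y <- sweep(y, 2L, scale_sd, "/")
    attr(y, "original_means") <- mu
  }
  n <- nrow(y); m <- ncol(y)
  if (m > n)
    warning("more features than observations: covariance matrix is singular")
  r <- min(n, m)

  if (method == "svd") {
    sv <- svd_thin(y, require_centered = center)
    if (!canonical_signs) {
      sv$u <- sweep(sv$u, 2L, sv$flips, "*")
      sv$v <- sweep(sv$v, 2L, sv$flips, "*")
      sv$flips <- rep(1, length(sv$flips))
    }
    v <- sv$v; d <- sv$d; u <- sv$u
    lambda <- eigen_from_singular(d, n)
  } else {
    s <- sample_covariance(y)
    e <- eigendecompose(s)
    if (!canonical_signs) {
      e$vectors <- sweep(e$vectors, 2L, e$flips, "*")
      e$flips <- rep(1, length(e$flips))
    }
    v <- e$vectors[, seq_len(r), drop = FALSE]
    lambda <- pmax(e$values[seq_len(r)], 0)
    d <- singular_from_eigen(lambda, n)
    u <- matrix(0, n, r, dimnames = list(rownames(y), colnames(v)))
    pos <- d > 0
    if (any(pos))
      u[, pos] <- (y %*% v[, pos, drop = FALSE]) %*%
        diag(1 / d[pos], sum(pos))
  }
  z <- y %*% v
  dimnames(z) <- list(rownames(y), colnames(v))
  total <- sum(lambda)
  structure(list(
    loadings = v,
    eigenvalues = lambda,
    singular_values = d,
    scores = z,
    u = u,
    score_sd = sqrt(lambda),
    var_explained = if (total > 0) lambda / total else rep(0, r),
    center = attr(y, "original_means"),
    scale_sd = scale_sd,
    y = y,
    n = n, m = m, r = r,
    method = method,
    null_flags = null_components(lambda),
    canonical_signs = canonical_signs
  ), class = "pca_fit")
}

#' Cumulative fraction of variance explained
#'
#' @param object a \code{pca_fit}.
#' @param k number of leading components, 1 <= k <= r.
#' @return sum of the k leading eigenvalues over the total; equals 1 at k = r.
#' @export
variance_explained <- function(object, k) {
  stopifnot(inherits(object, "pca_fit"))
  if (length(k) != 1L || k < 1 || k > object$r)
    stop("k must lie in 1..", object$r, call. = FALSE)
  total <- sum(object$eigenvalues)
  if (total <= 0) return(0)
  sum(object$eigenvalues[seq_len(k)]) / total
}

#' Sample variance of one score column
#'
#' Recomputed from the score column with divisor n - 1; by the defining
#' identity of PCA it must equal the k-th eigenvalue.
#'
#' @param object a \code{pca_fit}.
#' @param k component index.
#' @return scalar variance.
#' @export
score_variance <- function(object, k) {
  stopifnot(inherits(object, "pca_fit"))
  if (length(k) != 1L || k < 1 || k > object$r)
    stop("k must lie in 1..", object$r, call. = FALSE)
  stats::var(object$scores[, k])
}

#' @export
print.pca_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("Principal component analysis (%s route), n = %d, m = %d\n",
              x$method, x$n, x$m))
  cat("Eigenvalues (lambda):\n")
  print(round(x$eigenvalues, digits))
  cat("Singular values (ell):\n")
  print(round(x$singular_values, digits))
  cat("Proportion of variance:\n")
  print(round(x$var_explained, digits))
  invisible(x)
}

#' @export
summary.pca_fit <- function(object, ...) {
  tab <- rbind(`St. dev. of scores` = object$score_sd,
               `Eigenvalue` = object$eigenvalues,
               `Singular value` = object$singular_values,
               `Proportion of variance` = object$var_explained,
               `Cumulative proportion` = cumsum(object$var_explained))
  colnames(tab) <- colnames(object$loadings)
  structure(list(table = tab, method = object$method,
                 n = object$n, m = object$m),
            class = "summary.pca_fit")
}

#' @export
print.summary.pca_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("PCA (%s route), n = %d observations, m = %d features\n",
              x$method, x$n, x$m))
  print(round(x$table, digits))
  invisible(x)
}

#' @export
coef.pca_fit <- function(object, ...) object$loadings

#' Project new observations onto fitted components
#'
#' Applies the stored preprocessing (unitisation is not re-estimable and is
#' deliberately not supported for new data; centring and standardisation
#' reuse the training parameters) and right-multiplies by the loadings.
#'
#' @param object a \code{pca_fit}.
#' @param newdata matrix with the same features; defaults to training scores.
#' @param ... unused.
#' @return score matrix of the new observations.
#' @export
predict.pca_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  newdata <- as_labeled_matrix(newdata, min_rows = 1L)
  if (ncol(newdata) != object$m)
    stop("newdata must have ", object$m, " columns", call. = FALSE)
  y <- sweep(newdata, 2L, object$center, "-")
  if (!is.null(object$scale_sd)) y <- sweep(y, 2L, object$scale_sd, "/")
  y %*% object$loadings
}

#' Residuals of a truncated reconstruction
#'
#' @param object a \code{pca_fit}.
#' @param rank number of components used to reconstruct (default all).
#' @param ... unused.
#' @return matrix Y minus its rank-\code{rank} approximation.
#' @export
residuals.pca_fit <- function(object, rank = object$r, ...) {
  k <- seq_len(rank)
  object$y - object$scores[, k, drop = FALSE] %*%
    t(object$loadings[, k, drop = FALSE])
}

#' Scree-style plot of a fitted PCA
#'
#' @param x a \code{pca_fit}.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.pca_fit <- function(x, ...) {
  graphics::barplot(x$var_explained,
                    names.arg = colnames(x$loadings),
                    ylab = "Proportion of variance", ...)
  invisible(x)
}
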