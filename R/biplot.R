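#' The alpha-parametrised biplot factorisation Y = A B'
#'
#' Splits the thin SVD Y = U D V' into observation coordinates
#' A = U_k D_k^alpha and feature coordinates B = V_k D_k^(1-alpha), truncated
#' to the k leading singular values. At full rank A B' reconstructs Y exactly
#' for every alpha; at lower rank A B' is the best rank-k approximation of Y
#' (Eckart-Young). alpha = 0 gives the PC biplot (A = U, B = V D); alpha = 1
#' gives the scores-and-loadings overlay (A = Z, B = V).
#'
#' @param object a \code{pca_fit}, or a matrix (centred internally).
#' @param alpha scalar in [0, 1].
#' @param rank number of components retained, 1 <= rank <= r.
#' @return object of class \code{"biplot_coords"}: list with \code{A}
#'   (n x k), \code{B} (m x k), \code{alpha}, \code{rank}, \code{full_rank},
#'   \code{singular_values} (all r of them), \code{n},
#'   \code{reconstruction_error} (Frobenius norm of Y - A B').
#' @examples
#' fit <- fit_pca(pca_fixture("toy_table2")$matrix)
#' biplot_coords(fit, alpha = 0, rank = 2)
#' @export
biplot_coords <- function(object, alpha = 0, rank = 2L) {
  if (!inherits(object, "pca_fit")) object <- fit_pca(object)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  if (length(rank) != 1L || rank < 1 || rank > object$r)
    stop("rank must lie in 1..", object$r, call. = FALSE)
  k <- seq_len(rank)
  d <- object$singular_values[k]
  # 0^0 == 1 in R, so zero singular values are safe for alpha in {0, 1}
  a <- sweep(object$u[, k, drop = FALSE], 2L, d^alpha, "*")
  b <- sweep(object$loadings[, k, drop = FALSE], 2L, d^(1 - alpha), "*")
  recon <- a %*% t(b)
  structure(list(
    A = a, B = b, alpha = alpha, rank = as.integer(rank),
    full_rank = rank == object$r,
    singular_values = object$singular_values,
    n = object$n, m = object$m,
    reconstruction_error = sqrt(sum((object$y - recon)^2))
  ), class = "biplot_coords")
}

#' Principal component biplot coordinates (alpha = 0)
#'
#' The PC biplot: observation coordinates A = U = Z D^-1 and feature
#' coordinates B = V D. The equivalent form A = Z D^-1 is verified against
#' the fitted scores before returning, which requires all retained singular
#' values to be nonzero.
#'
#' @param object a \code{pca_fit} or matrix.
#' @param rank retained components (default 2).
#' @return \code{biplot_coords} with alpha = 0.
#' @export
pc_biplot <- function(object, rank = 2L) {
  if (!inherits(object, "pca_fit")) object <- fit_pca(object)
  k <- seq_len(rank)
  d <- object$singular_values[k]
  if (any(d <= 0))
    stop("zero singular value among the first ", rank,
         " components: A = Z D^-1 is undefined", call. = FALSE)
  coords <- biplot_coords(object, alpha = 0, rank = rank)
  alt <- sweep(object$scores[, k, drop = FALSE], 2L, 1 / d, "*")
  dev <- max(abs(coords$A - alt))
  if (dev > 1e-10 * max(abs(alt), 1))
    stop("internal inconsistency: U and Z D^-1 disagree by ", dev,
         call. = FALSE)
  coords
}

#' Scores-and-loadings biplot coordinates (alpha = 1)
#'
#' The common overlay of PCA scores (observations) and loadings (features).
#' Still a biplot, but a distinct geometry from the PC biplot: the feature
#' standard-deviation, cosine-correlation and Mahalanobis properties of the
#' alpha = 0 parametrisation are not guaranteed here.
#'
#' @inheritParams pc_biplot
#' @return \code{biplot_coords} with alpha = 1.
#' @export
scores_loadings_biplot <- function(object, rank = 2L) {
  if (!inherits(object, "pca_fit")) object <- fit_pca(object)
  biplot_coords(object, alpha = 1, rank = rank)
}

#' @export
print.biplot_coords <- function(x, digits = 4L, ...) {
  cat(sprintf("Biplot coordinates: alpha = %g, rank = %d%s\n", x$alpha,
              x$rank, if (x$full_rank) " (full rank)" else ""))
  cat("Observation coordinates A:\n")
  print(round(x$A, digits))
  cat("Feature coordinates B:\n")
  print(round(x$B, digits))
  cat(sprintf("Frobenius reconstruction error: %.3g\n",
              x$reconstruction_error))
  invisible(x)
}

#' Draw a biplot from computed coordinates
#'
#' Observations are drawn as labelled points on the primary axes and
#' features as arrows on secondary axes (top/right). The arrow scale is the
#' ratio of max-absolute extents of A and B; it affects the display only and
#' never the stored coordinates.
#'
#' @param x a \code{biplot_coords} with rank 2.
#' @param main plot title.
#' @param obs_col,arrow_col colours for observations and feature arrows.
#' @param ... passed to [graphics::plot()].
#' @return the scale factor applied to B, invisibly.
#' @export
plot.biplot_coords <- function(x, main = NULL, obs_col = "black",
                               arrow_col = "purple", ...) {
  if (x$rank != 2L)
    stop("biplot rendering requires exactly 2 retained components",
         call. = FALSE)
  a <- x$A; b <- x$B
  ext_a <- max(abs(a)); ext_b <- max(abs(b))
  sc <- if (ext_b > 0) ext_a / ext_b else 1
  bs <- b * sc
  lim <- range(c(a, bs)) * 1.15
  graphics::plot(a, xlim = lim, ylim = lim, pch = 19, col = obs_col,
                 xlab = colnames(a)[1L], ylab = colnames(a)[2L],
                 main = main, asp = 1, ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  graphics::text(a, labels = rownames(a), pos = 3, cex = 0.8, col = obs_col)
  graphics::arrows(0, 0, bs[, 1L], bs[, 2L], length = 0.08, col = arrow_col)
  graphics::text(bs, labels = rownames(b), pos = 4, cex = 0.8,
                 col = arrow_col)
  at <- pretty(lim / sc)
  graphics::axis(3, at = at * sc, labels = at, col.axis = arrow_col,
                 col = arrow_col)
  graphics::axis(4, at = at * sc, labels = at, col.axis = arrow_col,
                 col = arrow_col)
  invisible(sc)
}

#' Render a biplot to an image file
#'
#' @param coords a rank-2 \code{biplot_coords}.
#' @param path output file; extension selects the device (.png or .svg).
#' @param width,height device size in pixels (png) or inches (svg).
#' @param ... passed to [plot.biplot_coords()].
#' @return \code{path}, invisibly.
#' @export
render_biplot <- function(coords, path, width = 800, height = 800, ...) {
  stopifnot(inherits(coords, "biplot_coords"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height),
    svg = grDevices::svg(path, width = width / 100, height = height / 100),
    stop("unsupported image format: ", ext, call. = FALSE))
  on.exit(grDevices::dev.off())
  plot(coords, ...)
  invisible(path)
}

#' Biplot method for fitted PCA models
#'
#' @param x a \code{pca_fit}.
#' @param alpha biplot parametrisation (default 0, the PC biplot).
#' @param rank components retained (default 2).
#' @param ... passed to [plot.biplot_coords()].
#' @return the \code{biplot_coords}, invisibly.
#' @export
biplot.pca_fit <- function(x, alpha = 0, rank = 2L, ...) {
  coords <- biplot_coords(x, alpha = alpha, rank = rank)
  plot(coords, ...)
  invisible(coords)
}
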