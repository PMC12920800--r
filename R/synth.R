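#' Generate Gaussian data with a controlled population spectrum
#'
#' Draws n observations from a zero-mean multivariate normal whose
#' population covariance has the requested eigenvalues under a seeded random
#' orthogonal rotation: Sigma = Q diag(spectrum) Q'. Generation is
#' bit-for-bit reproducible given the two seeds. Used for identity testing
#' (the identities are distribution-free) and for eigenvalue-recovery
#' checks at large n.
#'
#' @param n number of observations; m > n is permitted (it exercises the
#'   singular-covariance paths) but flagged with a warning.
#' @param spectrum non-negative population eigenvalues, length m.
#' @param rotation_seed seed for the random orthogonal rotation Q.
#' @param noise_seed seed for the Gaussian draws.
#' @return labelled n x m matrix.
#' @examples
#' x <- synth_matrix(50, spectrum = c(4, 1), rotation_seed = 1, noise_seed = 2)
#' @export
synth_matrix <- function(n, spectrum, rotation_seed = 1L, noise_seed = 2L) {
  m <- length(spectrum)
  if (m < 1L || any(spectrum < 0) || any(!is.finite(spectrum)))
    stop("spectrum must be a vector of non-negative finite values",
         call. = FALSE)
  if (n < 2L) stop("n must be at least 2", call. = FALSE)
  if (m > n) warning("m > n: the sample covariance matrix will be singular")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rotation_seed)
  q <- qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
  set.seed(noise_seed)
  z <- matrix(stats::rnorm(n * m), n, m)
  x <- z %*% diag(sqrt(spectrum), m) %*% t(q)
  dimnames(x) <- list(paste0("obs", seq_len(n)), paste0("feat", seq_len(m)))
  x
}

#' Apply one documented corruption as a negative control
#'
#' Returns a copy of a fitted model or coordinate set with exactly one
#' deviation applied, mirroring the computational slips the identity grid is
#' designed to catch. Each grid check has at least one mode that flips it to
#' a failure while checks fed pristine inputs keep passing.
#'
#' Modes on a \code{pca_fit}:
#' \describe{
#'   \item{\code{divisor_n}}{eigenvalues rescaled by (n-1)/n, the divisor-n
#'     covariance convention; breaks the score-variance identity (I.D).}
#'   \item{\code{conflate_singular}}{singular values replaced by
#'     sqrt(lambda), the classic singular-value/eigenvalue conflation;
#'     breaks II.D.}
#'   \item{\code{psych_scaling}}{loading columns multiplied by
#'     sqrt(lambda_k), an implicit normalisation some implementations apply;
#'     breaks the feature-score correlation formula (VI.B).}
#' }
#' Modes on a \code{biplot_coords}:
#' \describe{
#'   \item{\code{flip_column}}{first column of A sign-flipped; III.A then
#'     reports \code{sign_flip}, not a failure.}
#'   \item{\code{scale_A}}{A multiplied by sqrt(n-1), an alternative
#'     observation scaling; fails III.A (and VII.A if fed to it).}
#'   \item{\code{scale_B}}{B multiplied by a scalar (2); fails V.A while
#'     VI.A still passes because cosines are scale-invariant.}
#'   \item{\code{scale_B_column}}{first column of B doubled; distorts angles
#'     and fails VI.A.}
#' }
#'
#' @param object a \code{pca_fit} or \code{biplot_coords}.
#' @param mode corruption mode, see above.
#' @return corrupted copy of \code{object}.
#' @export
corrupt <- function(object, mode) {
  model_modes <- c("divisor_n", "conflate_singular", "psych_scaling")
  coord_modes <- c("flip_column", "scale_A", "scale_B", "scale_B_column")
  if (!mode %in% c(model_modes, coord_modes))
    stop("unknown corruption mode: ", mode, "; known modes: ",
         paste(c(model_modes, coord_modes), collapse = ", "), call. = FALSE)
  if (inherits(object, "pca_fit")) {
    if (!mode %in% model_modes)
      stop("mode '", mode, "' applies to biplot_coords, not pca_fit",
           call. = FALSE)
    switch(mode,
      divisor_n = {
        object$eigenvalues <- object$eigenvalues * (object$n - 1) / object$n
      },
      conflate_singular = {
        object$singular_values <- sqrt(object$eigenvalues)
      },
      psych_scaling = {
        object$loadings <- sweep(object$loadings, 2L,
                                 sqrt(pmax(object$eigenvalues,
                                           .Machine$double.eps)), "*")
      })
    return(object)
  }
  if (inherits(object, "biplot_coords")) {
    if (!mode %in% coord_modes)
      stop("mode '", mode, "' applies to pca_fit, not biplot_coords",
           call. = FALSE)
    switch(mode,
      flip_column = { object$A[, 1L] <- -object$A[, 1L] },
      scale_A = { object$A <- object$A * sqrt(object$n - 1) },
      scale_B = { object$B <- object$B * 2 },
      scale_B_column = { object$B[, 1L] <- object$B[, 1L] * 2 })
    return(object)
  }
  stop("object must be a pca_fit or biplot_coords", call. = FALSE)
}
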