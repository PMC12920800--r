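#' Sample covariance matrix of a centred data matrix
#'
#' Computes S = Y'Y / divisor. The reference divisor is n - 1 (the unbiased
#' sample covariance); the divisor n is accepted so the conventions of
#' implementations that centre on it can be emulated.
#'
#' @param y centred numeric matrix (n x m).
#' @param divisor positive scalar, one of n - 1 (default) or n.
#' @return symmetric m x m matrix with attributes \code{divisor} and \code{n}.
#' @export
sample_covariance <- function(y, divisor = nrow(y) - 1L) {
  y <- as_labeled_matrix(y)
  n <- nrow(y)
  if (length(divisor) != 1L || !is.finite(divisor) || divisor <= 0)
    stop("divisor must be a positive scalar", call. = FALSE)
  if (!divisor %in% c(n - 1L, n))
    stop("divisor must be n - 1 or n (n = ", n, ")", call. = FALSE)
  if (!is_centered(y))
    stop("matrix is not column-centred; call center_columns() first",
         call. = FALSE)
  s <- crossprod(y) / divisor
  s <- (s + t(s)) / 2  # enforce exact symmetry against rounding
  attr(s, "divisor") <- divisor
  attr(s, "n") <- n
  s
}

#' Canonicalise eigen/singular-vector signs
#'
#' Each column of a vector matrix is flipped, when needed, so that its entry
#' of largest absolute value is positive; magnitude ties resolve to the
#' lowest row index. Decomposition routines return vectors with arbitrary
#' signs, so a fixed convention is needed before any cross-path comparison.
#' The flips are returned so score or left-vector matrices can be co-flipped.
#'
#' @param v numeric matrix whose columns are direction vectors.
#' @return list with elements \code{matrix} (sign-fixed copy) and
#'   \code{flips} (vector of +1/-1 per column).
#' @export
sign_canonicalise <- function(v) {
  v <- as.matrix(v)
  flips <- vapply(seq_len(ncol(v)), function(k) {
    col <- v[, k]
    i <- which.max(abs(col))  # first max: lowest row index wins ties
    s <- sign(col[i])
    if (s == 0) {
      warning("zero column ", k, " left unflipped")
      s <- 1
    }
    s
  }, numeric(1))
  list(matrix = sweep(v, 2L, flips, "*"), flips = flips)
}

#' Eigendecomposition of a covariance matrix
#'
#' Solves (S - lambda I) a = 0 for all eigenpairs, returning eigenvalues in
#' descending order and sign-canonicalised eigenvectors as columns. The sum
#' of the eigenvalues equals trace(S).
#'
#' @param s symmetric covariance matrix (e.g. from [sample_covariance()]).
#' @param tol asymmetry tolerance relative to the largest entry.
#' @return list with \code{values} (descending), \code{vectors}
#'   (orthonormal columns), \code{flips}.
#' @export
eigendecompose <- function(s, tol = 1e-12) {
  s <- as.matrix(s)
  scale_ <- max(abs(s), 1)
  if (!isTRUE(nrow(s) == ncol(s)) || max(abs(s - t(s))) > tol * scale_)
    stop("matrix is not symmetric within tolerance", call. = FALSE)
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)  # already sorted descending
  sc <- sign_canonicalise(e$vectors)
  vectors <- sc$matrix
  rownames(vectors) <- rownames(s)
  colnames(vectors) <- paste0("PC", seq_len(ncol(vectors)))
  list(values = e$values, vectors = vectors, flips = sc$flips)
}

#' Thin singular value decomposition of a centred matrix
#'
#' Computes Y = U D V' with r = min(n, m) retained columns, descending
#' non-negative singular values, and the package's sign convention applied
#' to V with U co-flipped so the product is unchanged.
#'
#' @param y centred numeric matrix.
#' @param require_centered validate centring (default TRUE); disable to
#'   decompose an arbitrary matrix.
#' @return list with \code{u} (n x r), \code{d} (length r), \code{v} (m x r),
#'   \code{flips}.
#' @export
svd_thin <- function(y, require_centered = TRUE) {
  y <- as_labeled_matrix(y)
  if (require_centered && !is_centered(y))
    stop("matrix is not column-centred; call center_columns() first",
         call. = FALSE)
  sv <- svd(y)
  sc <- sign_canonicalise(sv$v)
  v <- sc$matrix
  u <- sweep(sv$u, 2L, sc$flips, "*")
  rownames(u) <- rownames(y)
  rownames(v) <- colnames(y)
  colnames(u) <- colnames(v) <- paste0("PC", seq_along(sv$d))
  list(u = u, d = sv$d, v = v, flips = sc$flips)
}

#' Convert singular values to covariance eigenvalues
#'
#' The singular values of the centred matrix Y and the eigenvalues of its
#' sample covariance matrix are linked by ell_k = sqrt(n - 1) * sqrt(lambda_k),
#' i.e. lambda_k = ell_k^2 / (n - 1). Conflating the two is one of the most
#' common implementation slips the identity grid detects.
#'
#' @param ell non-negative singular values.
#' @param n number of observations (>= 2).
#' @return eigenvalues lambda of the sample covariance matrix.
#' @seealso [singular_from_eigen()] for the inverse map.
#' @export
eigen_from_singular <- function(ell, n) {
  if (any(ell < 0)) stop("singular values must be non-negative", call. = FALSE)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  ell^2 / (n - 1)
}

#' @rdname eigen_from_singular
#' @param lambda non-negative eigenvalues.
#' @export
singular_from_eigen <- function(lambda, n) {
  if (any(lambda < 0)) stop("eigenvalues must be non-negative", call. = FALSE)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  sqrt((n - 1) * lambda)
}

#' Brute-force principal direction for two features
#'
#' Maximises the projected variance a'Sa over unit vectors
#' a = (cos phi, sin phi) on a dense grid of angles. This is the defining
#' variance-maximisation program solved in closed form by the
#' eigendecomposition, retained as an independent numerical oracle for
#' two-feature problems.
#'
#' @param s 2 x 2 covariance matrix.
#' @param resolution number of grid points on the half-circle (default 1e6).
#' @return list with \code{direction} (unit vector), \code{value} (maximal
#'   variance), \code{angle} (radians in [0, pi)).
#' @export
principal_direction_grid <- function(s, resolution = 1e6) {
  s <- as.matrix(s)
  if (!all(dim(s) == 2L)) stop("grid search oracle requires m = 2", call. = FALSE)
  phi <- seq(0, pi, length.out = resolution)
  cp <- cos(phi); sp <- sin(phi)
  q <- s[1, 1] * cp^2 + 2 * s[1, 2] * cp * sp + s[2, 2] * sp^2
  i <- which.max(q)
  list(direction = c(cp[i], sp[i]), value = q[i], angle = phi[i])
}

# Components with lambda below 1e-12 * lambda_1 are numerically null; the
# Mahalanobis identity and Eq.-11 style inversions must not divide by them.
null_components <- function(lambda, rel_tol = 1e-12) {
  if (length(lambda) == 0L) return(logical(0))
  lambda < rel_tol * max(lambda, 0)
}
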