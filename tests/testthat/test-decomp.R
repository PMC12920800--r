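test_that("sample covariance honours the divisor and matches column variances", {
  y <- center_columns(toy$matrix)
  s <- sample_covariance(y, divisor = 5)
  expect_equal(round(unname(diag(s)), 2), toy$expected$sample_var)
  expect_equal(unname(diag(s)), unname(apply(y, 2, var)))

  y7 <- center_columns(ctsc$matrix)
  s7 <- sample_covariance(y7, divisor = 10)
  expect_abs_equal(diag(s7), ctsc$expected$sample_var)

  y2 <- matrix(c(-1, 1, -1, 1), 2, 2)
  expect_equal(unname(sample_covariance(y2, divisor = 1))[, ],
               matrix(2, 2, 2))

  expect_error(sample_covariance(y, divisor = 0), "positive")
  expect_error(sample_covariance(y, divisor = 3), "n - 1 or n")
  expect_error(sample_covariance(toy$matrix), "not column-centred")
})

test_that("eigendecomposition returns the descending, sign-fixed eigensystem", {
  y <- center_columns(toy$matrix)
  s <- sample_covariance(y)
  e <- eigendecompose(s)
  expect_equal(round(e$values, 2), toy$expected$eigenvalues)
  expect_abs_equal(e$vectors, toy$expected$abs_loadings)
  expect_equal(sum(e$values), sum(diag(s)), tolerance = 1e-10)
  expect_equal(unname(crossprod(e$vectors)), diag(2), tolerance = 1e-10)
  # largest-entry-positive convention
  expect_true(all(apply(e$vectors, 2, function(v) v[which.max(abs(v))] > 0)))

  expect_equal(eigendecompose(diag(3))$values, c(1, 1, 1))
  expect_error(eigendecompose(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("trace is conserved across random inputs", {
  for (i in 1:25) {
    x <- random_case(i)
    y <- center_columns(x)
    s <- sample_covariance(y)
    e <- eigendecompose(s)
    expect_equal(sum(e$values), sum(diag(s)), tolerance = 1e-10)
    expect_true(all(diff(e$values) <= 1e-12))
  }
})

test_that("thin SVD reconstructs the input with canonical signs", {
  y7 <- center_columns(ctsc$matrix)
  sv <- svd_thin(y7)
  expect_abs_equal(sv$d, ctsc$expected$singular_values)
  expect_abs_equal(sv$v[, 1], ctsc$expected$abs_loadings_pc1)
  recon <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_lt(max(abs(recon - y7)), 1e-10 * max(abs(y7)))
  expect_equal(unname(crossprod(sv$u)), diag(4), tolerance = 1e-10)
  expect_equal(unname(crossprod(sv$v)), diag(4), tolerance = 1e-10)

  d32 <- svd_thin(diag(c(3, 2)), require_centered = FALSE)
  expect_equal(d32$d, c(3, 2))
})

test_that("singular values and eigenvalues interconvert exactly", {
  expect_equal(round(eigen_from_singular(1.51, 11), 3), 0.228)
  expect_equal(eigen_from_singular(0, 5), 0)
  set.seed(7)
  ell <- sort(runif(6, 0, 10), decreasing = TRUE)
  expect_equal(singular_from_eigen(eigen_from_singular(ell, 42), 42), ell,
               tolerance = 1e-12)
  expect_error(eigen_from_singular(c(-1, 2), 5), "non-negative")
  expect_error(singular_from_eigen(c(1, 2), 1), "at least 2")
})

test_that("sign canonicalisation follows the largest-entry rule with ties to the first row", {
  out <- sign_canonicalise(cbind(c(-0.94, -0.34)))
  expect_equal(out$matrix[, 1], c(0.94, 0.34))
  expect_equal(out$flips, -1)
  out2 <- sign_canonicalise(cbind(c(0.94, 0.34)))
  expect_equal(out2$flips, 1)
  out3 <- sign_canonicalise(cbind(c(0.5, -0.5)))
  expect_equal(out3$matrix[, 1], c(0.5, -0.5))  # tie: row 1 already positive
  expect_warning(out4 <- sign_canonicalise(cbind(c(0, 0))), "zero column")
  expect_equal(out4$flips, 1)
})

test_that("grid search over the unit circle recovers the principal eigenpair", {
  y <- center_columns(toy$matrix)
  s <- sample_covariance(y)
  e <- eigendecompose(s)
  gs <- principal_direction_grid(s, resolution = 2e5)
  expect_equal(gs$value, e$values[1], tolerance = 1e-5)
  ang_eig <- atan2(e$vectors[2, 1], e$vectors[1, 1]) %% pi
  expect_lt(min(abs(gs$angle - ang_eig), pi - abs(gs$angle - ang_eig)), 1e-3)
  expect_error(principal_direction_grid(diag(3)), "m = 2")
})
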