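# Shared fixtures and generators for the test suite. All synthetic cases are
# seeded so failures reproduce.

toy <- pca_fixture("toy_table2")
ctsc <- pca_fixture("ctsc_table7")

# A random well-conditioned test matrix: n observations, m features, mildly
# separated spectrum. Seeds derive from the case index.
random_case <- function(i, n_range = c(5L, 200L), m_range = c(2L, 8L)) {
  set.seed(1000L + i)
  pick <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1L)
  n <- pick(n_range[1L], n_range[2L])
  m <- pick(m_range[1L], min(m_range[2L], n - 1L))
  spectrum <- sort(stats::rexp(m, rate = 0.5) + 0.05, decreasing = TRUE)
  synth_matrix(n, spectrum, rotation_seed = 2000L + i, noise_seed = 3000L + i)
}

expect_abs_equal <- function(object, expected, tol = 0.01) {
  expect_lt(max(abs(abs(object) - abs(expected))), tol + 1e-12)
}

# Scaled maximum deviation, the same measure the grid checks use.
rel_dev_acc <- function(a, b) {
  max(abs(a - b)) / max(abs(b), .Machine$double.eps)
}
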