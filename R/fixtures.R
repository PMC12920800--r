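#' Packaged worked-example fixtures
#'
#' Two small data sets used throughout the documentation and tests, stored
#' to the two printed decimals that define them.
#'
#' \describe{
#'   \item{\code{toy_table2}}{A fictitious 6 x 2 matrix (observations A-F,
#'     two features) small enough that every PCA and biplot quantity can be
#'     followed by hand.}
#'   \item{\code{ctsc_table7}}{A desensitised clinical-trial supply-chain
#'     excerpt: 11 protocols (A-K) by four features - stock-out events
#'     (STO), patients enrolled (ENR), number of clinics (CLI) and trial
#'     duration (DUR) - already unitised to [0, 1].}
#' }
#'
#' Each fixture carries a dictionary of the reference values its analysis
#' must reproduce (eigenvalues, singular values, loadings magnitudes, score
#' magnitudes, variance shares, cosines), rounded to two decimals as
#' published; comparisons against them should use an absolute tolerance of
#' 0.01.
#'
#' @param name \code{"toy_table2"} or \code{"ctsc_table7"}.
#' @return list with \code{name}, \code{matrix} (labelled numeric matrix)
#'   and \code{expected} (named list of reference values).
#' @examples
#' fx <- pca_fixture("toy_table2")
#' fit_pca(fx$matrix)$eigenvalues
#' @export
pca_fixture <- function(name = c("toy_table2", "ctsc_table7")) {
  name <- match.arg(name)
  if (name == "toy_table2") {
    x <- matrix(c(10, 6,
                  11, 4,
                  8, 5,
                  3, 3,
                  2, 2.8,
                  1, 1),
                ncol = 2L, byrow = TRUE,
                dimnames = list(LETTERS[1:6], c("Feat1", "Feat2")))
    expected <- list(
      centered_row_A = c(4.17, 2.37),
      sample_var = c(18.97, 3.13),
      eigenvalues = c(21.28, 0.81),
      abs_loadings = matrix(c(0.94, 0.34, 0.34, 0.94), 2L, 2L),
      abs_scores_pc1 = c(4.72, 4.99, 2.50, 2.88, 3.89, 5.44),
      abs_scores_pc2 = c(0.83, 1.39, 0.56, 0.36, 0.50, 0.85),
      score_var = c(21.29, 0.81),
      cos_feature_angle = 0.84,
      pc1_var_share = 0.96
    )
  } else {
    x <- matrix(c(
      0.12, 0.23, 0.10, 1.00,
      0.00, 0.00, 0.00, 0.23,
      0.65, 0.49, 0.24, 0.71,
      0.29, 0.48, 0.26, 0.71,
      0.00, 0.30, 0.32, 0.14,
      1.00, 1.00, 1.00, 0.16,
      0.35, 0.83, 0.26, 0.58,
      0.06, 0.05, 0.04, 0.41,
      0.00, 0.53, 0.26, 0.14,
      0.06, 0.30, 0.43, 0.14,
      0.00, 0.20, 0.30, 0.00),
      ncol = 4L, byrow = TRUE,
      dimnames = list(LETTERS[1:11], c("STO", "ENR", "CLI", "DUR")))
    expected <- list(
      col_means = c(0.23, 0.40, 0.29, 0.38),
      sample_var = c(0.11, 0.09, 0.07, 0.10),
      eigenvalues = c(0.23, 0.12, 0.02, 0.01),
      singular_values = c(1.51, 1.09, 0.46, 0.29),
      abs_loadings_pc1 = c(0.64, 0.60, 0.49, 0.01),
      abs_score_F_pc1 = 1.19,
      abs_U_row_F = c(0.79, 0.24),
      abs_B_row_STO = c(0.96, 0.22),
      abs_B_row_DUR = c(0.02, 1.01),
      b_norm_rank2 = c(STO = 0.99, ENR = 0.91, CLI = 0.81, DUR = 1.01),
      b_norm_full = c(STO = 1.03, ENR = 0.98, CLI = 0.85, DUR = 1.02),
      feature_sd = c(STO = 0.33, ENR = 0.31, CLI = 0.27, DUR = 0.32),
      corr_with_pcs = matrix(c(
        0.93, 0.21, -0.28, 0.11,
        0.93, 0.03, 0.36, 0.07,
        0.87, -0.40, -0.07, -0.27,
        0.02, 0.99, 0.03, -0.10),
        nrow = 4L, byrow = TRUE,
        dimnames = list(c("STO", "ENR", "CLI", "DUR"), NULL)),
      two_pc_var_share_min = 0.92,
      pair_table = data.frame(
        feature_a = c("STO", "STO", "STO", "ENR", "ENR", "CLI"),
        feature_b = c("ENR", "CLI", "DUR", "CLI", "DUR", "DUR"),
        cos_rank2 = c(0.98, 0.79, 0.24, 0.89, 0.05, -0.40),
        cos_full = c(0.78, 0.72, 0.20, 0.75, 0.05, -0.36),
        pearson_r = c(0.78, 0.72, 0.20, 0.75, 0.05, -0.36),
        p_value = c(0.0048, 0.0132, 0.5481, 0.0074, 0.8885, 0.2770),
        stringsAsFactors = FALSE)
    )
  }
  list(name = name, matrix = x, expected = expected)
}
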