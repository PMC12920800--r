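test_that("the self-audit is all-exact on both packaged fixtures", {
  for (fx in list(toy, ctsc)) {
    report <- run_grid(fx$matrix)
    statuses <- vapply(report$outcomes, `[[`, "", "status")
    expect_true(all(statuses == "exact"), info = fx$name)
    expect_true(grid_passed(report))
  }
})

test_that("score-variance check rejects the singular-value conflation", {
  fit <- fit_pca(toy$matrix)
  expect_equal(check_score_variance(fit)$status, "exact")
  broken <- fit
  broken$eigenvalues <- broken$singular_values  # common lambda/ell mix-up
  expect_equal(check_score_variance(broken)$status, "fail")
  # a zero-variance feature gives lambda = 0 = Var(z), still exact
  x <- cbind(random_case(1, n_range = c(10L, 10L), m_range = c(2L, 2L)),
             flat = 0)
  expect_equal(check_score_variance(fit_pca(x))$status, "exact")
})

test_that("singular/eigenvalue relation check catches the divisor-n slip", {
  fit7 <- fit_pca(ctsc$matrix)
  expect_equal(check_singular_eigen(fit7)$status, "exact")
  expect_abs_equal((fit7$singular_values / sqrt(10))^2,
                   ctsc$expected$eigenvalues)
  # sqrt(n) used where sqrt(n-1) belongs
  bad <- check_singular_eigen(fit7$singular_values / sqrt(11) * sqrt(10),
                              fit7$eigenvalues, n = 11)
  expect_equal(bad$status, "fail")
  # n = 2 degenerate case: ell = sqrt(lambda)
  y2 <- center_columns(matrix(c(1, 3, 2, 8), 2, 2))
  f2 <- fit_pca(y2, center = FALSE)
  expect_equal(f2$singular_values, sqrt(f2$eigenvalues), tolerance = 1e-12)
  expect_error(check_singular_eigen(c(1, 2), c(1, 2, 3), 5), "equal length")
})

test_that("observation-coordinate check distinguishes exact, sign-flip and failure", {
  fit <- fit_pca(toy$matrix)
  coords <- pc_biplot(fit, rank = 2)
  expect_equal(check_observation_coords(coords, fit)$status, "exact")
  expect_equal(check_observation_coords(corrupt(coords, "flip_column"),
                                        fit)$status, "sign_flip")
  # the alternative scaling A * sqrt(n-1) is a genuine failure
  expect_equal(check_observation_coords(corrupt(coords, "scale_A"),
                                        fit)$status, "fail")
  # |A| column 1 equals |z_1| / ell_1
  expect_abs_equal(coords$A[, 1],
                   toy$expected$abs_scores_pc1 / fit$singular_values[1])
})

test_that("feature-sd check is exact at full rank and an approximation below it", {
  fit7 <- fit_pca(ctsc$matrix)
  s <- sample_covariance(fit7$y)
  full <- check_feature_sd(pc_biplot(fit7, rank = 4), s)
  expect_equal(full$status, "exact")
  expect_abs_equal(sqrt(diag(s)), ctsc$expected$feature_sd)
  part <- check_feature_sd(pc_biplot(fit7, rank = 2), s)
  expect_equal(part$status, "skipped")
  expect_true(part$approximation)
  expect_match(part$detail, "rank-2 approximation")
  # the identity does not apply to scores-and-loadings coordinates
  a1 <- scores_loadings_biplot(fit7, rank = 4)
  expect_equal(check_feature_sd(a1, s)$status, "fail")
})

test_that("full-rank cosines equal correlations; rank-2 cosines are reported alongside", {
  fit <- fit_pca(toy$matrix)
  out <- check_cosine_correlation(pc_biplot(fit, rank = 2), fit$y)
  expect_equal(out$outcome$status, "exact")
  expect_equal(round(out$pairs$cos_full, 2), toy$expected$cos_feature_angle)
  expect_equal(out$pairs$cos_full, out$pairs$pearson_r, tolerance = 1e-10)

  fit7 <- fit_pca(ctsc$matrix)
  out7 <- check_cosine_correlation(pc_biplot(fit7, rank = 2), fit7$y)
  exp7 <- ctsc$expected$pair_table
  expect_abs_equal(out7$pairs$cos_rank, exp7$cos_rank2)
  expect_abs_equal(out7$pairs$cos_full, exp7$cos_full)
  expect_abs_equal(out7$pairs$pearson_r, exp7$pearson_r)
  # p-values of the strongly correlated pairs are stable under the
  # two-decimal rounding of the stored inputs; the mid-range ones inherit
  # amplified rounding (dp/dr is largest there) and reproduce to 2e-3
  strong <- abs(exp7$pearson_r) >= 0.7
  expect_lt(max(abs(out7$pairs$p_value - exp7$p_value)[strong]), 5e-4)
  expect_lt(max(abs(out7$pairs$p_value - exp7$p_value)), 2e-3)

  # orthogonal features: correlation zero implies cosine zero
  yo <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  fo <- fit_pca(yo, center = FALSE)
  oo <- check_cosine_correlation(pc_biplot(fo, rank = 2), fo$y)
  expect_equal(oo$pairs$cos_full, 0, tolerance = 1e-12)
})

test_that("feature-score correlations follow the loading formula", {
  fit7 <- fit_pca(ctsc$matrix)
  s <- sample_covariance(fit7$y)
  expect_equal(check_feature_score_corr(fit7, s)$status, "exact")
  emp <- cor(fit7$y, fit7$scores)
  expect_abs_equal(emp, ctsc$expected$corr_with_pcs)
  # corrupting the loadings psych-style breaks the formula
  expect_equal(check_feature_score_corr(corrupt(fit7, "psych_scaling"),
                                        s)$status, "fail")
})

test_that("Mahalanobis distances equal (n-1) times squared biplot distances", {
  fit <- fit_pca(toy$matrix)
  s <- sample_covariance(fit$y)
  out <- check_mahalanobis(pc_biplot(fit, rank = 2), fit$y, s)
  expect_equal(out$outcome$status, "exact")
  # brute-force oracle for the pair (A, B): explicit 2x2 cofactor inverse
  d <- fit$y["A", ] - fit$y["B", ]
  det_s <- s[1, 1] * s[2, 2] - s[1, 2]^2
  s_inv <- matrix(c(s[2, 2], -s[2, 1], -s[1, 2], s[1, 1]), 2, 2) / det_s
  lhs <- drop(t(d) %*% s_inv %*% d)
  pair <- out$pairs[out$pairs$obs_h == "A" & out$pairs$obs_i == "B", ]
  expect_equal(pair$mahalanobis_sq, lhs, tolerance = 1e-10)
  expect_equal(5 * pair$euclid_sq_U, lhs, tolerance = 1e-10)
  # h = i pairs are excluded by construction; distances are strictly positive
  expect_true(all(out$pairs$mahalanobis_sq > 0))

  fit7 <- fit_pca(ctsc$matrix)
  s7 <- sample_covariance(fit7$y)
  approx <- check_mahalanobis(pc_biplot(fit7, rank = 2), fit7$y, s7)
  expect_equal(approx$outcome$status, "skipped")
  expect_true(approx$outcome$approximation)
})

test_that("a singular covariance matrix skips the Mahalanobis check only", {
  x <- suppressWarnings(synth_matrix(3, spectrum = c(2, 1, 0.5, 0.2, 0.1),
                                     rotation_seed = 5, noise_seed = 6))
  report <- suppressWarnings(run_grid(x))
  expect_equal(report$outcomes$VII.A$status, "skipped")
  others <- vapply(report$outcomes[names(report$outcomes) != "VII.A"],
                   `[[`, "", "status")
  expect_true(all(others %in% c("exact", "sign_flip")))
})

test_that("approximation gaps shrink monotonically to zero as rank grows", {
  for (i in 1:5) {
    x <- random_case(i, n_range = c(12L, 30L), m_range = c(4L, 6L))
    fit <- fit_pca(x)
    s <- sample_covariance(fit$y)
    gaps_v <- gaps_c <- numeric(0)
    for (k in 2:fit$r) {
      coords <- pc_biplot(fit, rank = k)
      sd_b <- sqrt(rowSums(coords$B^2)) / sqrt(fit$n - 1)
      gaps_v <- c(gaps_v, max(abs(sd_b - sqrt(diag(s)))))
      cc <- check_cosine_correlation(coords, fit$y)
      gaps_c <- c(gaps_c, max(abs(cc$pairs$cos_rank - cc$pairs$pearson_r)))
    }
    # ||b_j|| grows monotonically with rank, so this gap is provably
    # non-increasing; the cosine gap converges to zero but its per-pair
    # maximum need not shrink at every single rank step
    expect_true(all(diff(gaps_v) <= 1e-10))
    expect_lt(gaps_v[length(gaps_v)], 1e-10)
    expect_lt(gaps_c[length(gaps_c)], 1e-8)
    expect_lte(gaps_c[length(gaps_c)], min(gaps_c) + 1e-10)
  }
})

test_that("each corruption mode flips its matched check and only that check", {
  fit <- fit_pca(toy$matrix)
  s <- sample_covariance(fit$y)
  run_all <- function(inputs) {
    c(I.D = check_score_variance(inputs$model)$status,
      II.D = check_singular_eigen(inputs$pair$ell, inputs$pair$lambda,
                                  n = fit$n)$status,
      III.A = check_observation_coords(inputs$coords_obs, fit)$status,
      V.A = check_feature_sd(inputs$coords_sd, s)$status,
      VI.A = check_cosine_correlation(inputs$coords_cos, fit$y)$outcome$status,
      VI.B = check_feature_score_corr(inputs$model_corr, s)$status,
      VII.A = check_mahalanobis(inputs$coords_maha, fit$y, s)$outcome$status)
  }
  pristine <- list(model = fit,
                   pair = list(ell = fit$singular_values,
                               lambda = fit$eigenvalues),
                   coords_obs = pc_biplot(fit, 2),
                   coords_sd = pc_biplot(fit, 2),
                   coords_cos = pc_biplot(fit, 2),
                   model_corr = fit,
                   coords_maha = pc_biplot(fit, 2))
  expect_true(all(run_all(pristine) == "exact"))

  cases <- list(
    list(slot = "model", mode = "divisor_n", check = "I.D"),
    list(slot = "model", mode = "conflate_singular", check = "II.D"),
    list(slot = "coords_obs", mode = "scale_A", check = "III.A"),
    list(slot = "coords_sd", mode = "scale_B", check = "V.A"),
    list(slot = "coords_cos", mode = "scale_B_column", check = "VI.A"),
    list(slot = "model_corr", mode = "psych_scaling", check = "VI.B"),
    list(slot = "coords_maha", mode = "scale_A", check = "VII.A"))
  for (case in cases) {
    inputs <- pristine
    bad <- corrupt(inputs[[case$slot]], case$mode)
    if (case$check == "II.D")
      inputs$pair <- list(ell = bad$singular_values, lambda = bad$eigenvalues)
    inputs[[case$slot]] <- bad
    statuses <- run_all(inputs)
    expect_equal(unname(statuses[case$check]), "fail", label = case$mode)
    expect_true(all(statuses[names(statuses) != case$check] == "exact"),
                info = case$mode)
  }

  # a pure sign flip is reported as such, not as a failure
  inputs <- pristine
  inputs$coords_obs <- corrupt(pristine$coords_obs, "flip_column")
  expect_equal(unname(run_all(inputs)["III.A"]), "sign_flip")
  # scaling B leaves the cosine check untouched (scale invariance)
  inputs <- pristine
  inputs$coords_cos <- corrupt(pristine$coords_cos, "scale_B")
  expect_equal(unname(run_all(inputs)["VI.A"]), "exact")
})

test_that("feature-angle propositions hold on random full-rank data", {
  for (i in 1:60) {
    x <- random_case(i, n_range = c(6L, 60L), m_range = c(2L, 6L))
    fit <- fit_pca(x)
    s <- sample_covariance(fit$y)
    coords <- pc_biplot(fit, rank = fit$r)
    cc <- check_cosine_correlation(coords, fit$y)
    expect_lt(max(abs(cc$pairs$cos_full - cc$pairs$pearson_r)), 1e-10)
    expect_equal(check_feature_score_corr(fit, s, tol = 1e-10)$status,
                 "exact")
    # the feature-score correlations are recoverable from B's rows alone
    b_corr <- sweep(coords$B / sqrt(fit$n - 1), 1, sqrt(diag(s)), "/")
    expect_equal(unname(b_corr), unname(cor(fit$y, fit$scores)),
                 tolerance = 1e-8)
  }
})
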