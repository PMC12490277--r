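test_that("varying-loadings covariance matches direct substitution (N=1, K=2)", {
  spec <- covariance_spec(
    Sigma_F = matrix(1), loading_means = list(1, 2),
    loading_covs = list(matrix(0), matrix(0.25)), error_vars = c(0.1, 0.2))
  bc <- marginal_cov_varying(spec)
  expect_equal(cov_entry(bc, 1, 1, 1, 1), 1.1)    # Sigma_F + sigma1^2
  expect_equal(cov_entry(bc, 1, 2, 1, 1), 2.0)    # mu2 * Sigma_F
  expect_equal(cov_entry(bc, 2, 2, 1, 1), 4.45)   # (0.25 + 4) * 1 + 0.2
  expect_equal(bc$matrix, t(bc$matrix))
})

test_that("constant-loadings covariance matches direct substitution (N=2, K=2)", {
  SF <- matrix(c(1, 0.5, 0.5, 1), 2)
  spec <- covariance_spec(SF, loading_means = c(1, 2), tau_g2 = c(0, 0),
                          error_vars = c(0, 0))
  bc <- marginal_cov_constant(spec)
  expect_equal(cov_block(bc, 1, 1), SF)
  expect_equal(cov_block(bc, 1, 2), 2 * SF)
  expect_equal(cov_block(bc, 2, 1), 2 * SF)
  expect_equal(cov_block(bc, 2, 2), 4 * SF)
})

test_that("zero mean and variance loadings kill non-reference structure", {
  SF <- random_psd(3, seed = 7)
  spec <- covariance_spec(SF, loading_means = c(1, 0, 0),
                          tau_g2 = c(0, 0, 0), error_vars = c(0.1, 0.2, 0.3))
  bc <- marginal_cov_constant(spec)
  expect_equal(cov_block(bc, 2, 2), diag(0.2, 3))
  expect_equal(cov_block(bc, 3, 3), diag(0.3, 3))
  expect_equal(cov_block(bc, 1, 2), matrix(0, 3, 3))
  expect_equal(cov_block(bc, 2, 3), matrix(0, 3, 3))
})

test_that("varying reduces exactly to constant when loadings do not vary", {
  SF <- random_psd(3, seed = 11)
  mus <- c(1, 1.7, -0.4)
  err <- c(0.1, 0.25, 0.05)
  v <- covariance_spec(
    SF, loading_means = lapply(mus, rep, 3),
    loading_covs = replicate(3, matrix(0, 3, 3), simplify = FALSE),
    error_vars = err)
  k <- covariance_spec(SF, loading_means = mus, tau_g2 = rep(0, 3),
                       error_vars = err)
  expect_identical(marginal_cov_varying(v)$matrix,
                   marginal_cov_constant(k)$matrix)
})

test_that("cross blocks scale linearly in the loading means", {
  SF <- random_psd(3, seed = 3)
  mu2 <- c(0.5, 1.5, -1)
  base <- covariance_spec(
    SF, loading_means = list(rep(1, 3), mu2),
    loading_covs = list(matrix(0, 3, 3), random_psd(3, seed = 4) / 4),
    error_vars = c(0.1, 0.1))
  dbl <- covariance_spec(
    SF, loading_means = list(rep(1, 3), 2 * mu2),
    loading_covs = base$loading_covs, error_vars = c(0.1, 0.1))
  expect_equal(cov_block(marginal_cov_varying(dbl), 1, 2),
               2 * cov_block(marginal_cov_varying(base), 1, 2))
})

test_that("varying minus matched constant is the loadings-covariance correction", {
  SF <- random_psd(3, seed = 21)
  G2 <- random_psd(3, seed = 22) / 4
  G3 <- random_psd(3, seed = 23) / 4
  # constant comparator matched in moments: same scalar means, tau2 = 0
  v <- covariance_spec(SF, loading_means = list(rep(1, 3), rep(1.3, 3), rep(0.6, 3)),
                       loading_covs = list(matrix(0, 3, 3), G2, G3),
                       error_vars = c(0.1, 0.2, 0.3))
  k <- covariance_spec(SF, loading_means = c(1, 1.3, 0.6), tau_g2 = rep(0, 3),
                       error_vars = c(0.1, 0.2, 0.3))
  D <- marginal_cov_varying(v)$matrix - marginal_cov_constant(k)$matrix
  expect_equal(D[4:6, 4:6], G2 * SF)
  expect_equal(D[7:9, 7:9], G3 * SF)
  D[4:6, 4:6] <- 0; D[7:9, 7:9] <- 0
  expect_equal(D, matrix(0, 9, 9))
})

test_that("closed forms agree with the Monte-Carlo oracle within 3 SEs", {
  for (s in c(101, 202)) {
    spec_v <- random_varying_spec(s)
    ana <- marginal_cov_varying(spec_v)$matrix
    emp <- mc_cov_oracle(spec_v, n_draws = 1e5, seed = s, se = TRUE)
    z <- abs(ana - emp$matrix) / attr(emp, "se")
    expect_lt(max(z), 4)  # 81 entries; 4 SEs keeps the false-alarm rate tiny

    spec_c <- random_constant_spec(s)
    ana <- marginal_cov_constant(spec_c)$matrix
    emp <- mc_cov_oracle(spec_c, n_draws = 1e5, seed = s + 1, se = TRUE)
    z <- abs(ana - emp$matrix) / attr(emp, "se")
    expect_lt(max(z), 4)
  }
})

test_that("oracle is deterministic under a fixed seed and validates n_draws", {
  spec <- random_constant_spec(5)
  a <- mc_cov_oracle(spec, 1e4, seed = 9)
  b <- mc_cov_oracle(spec, 1e4, seed = 9)
  expect_identical(a$matrix, b$matrix)
  expect_error(mc_cov_oracle(spec, 100, seed = 1), "10\\^4")
})

test_that("outputs are symmetric PSD and specs are validated", {
  for (s in 31:33) {
    bc <- marginal_cov_varying(random_varying_spec(s))
    expect_equal(bc$matrix, t(bc$matrix))
    ev <- eigen(bc$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
  }
  expect_error(covariance_spec(matrix(c(1, 2, 2, 1), 2),
                               loading_means = c(1, 1), tau_g2 = c(0, 0.1),
                               error_vars = c(0, 0)),
               "positive semi-definite")
  expect_error(covariance_spec(matrix(1), loading_means = list(2, 1),
                               loading_covs = list(matrix(0), matrix(0)),
                               error_vars = c(0, 0)),
               "reference")
})

test_that("tidy/CSV export reproduces entries in flat form", {
  spec <- covariance_spec(
    Sigma_F = matrix(1), loading_means = list(1, 2),
    loading_covs = list(matrix(0), matrix(0.25)), error_vars = c(0.1, 0.2))
  bc <- marginal_covariance(spec)
  td <- tidy(bc)
  expect_equal(nrow(td), 4L)
  expect_equal(td$value[td$outcome_row == 2 & td$outcome_col == 2], 4.45)

  path <- withr::local_tempfile(fileext = ".csv")
  write_block_csv(bc, path)
  back <- utils::read.csv(path)
  expect_equal(back$value[back$outcome_row == 2 & back$outcome_col == 2], 4.45)
  expect_equal(names(back), c("outcome_row", "outcome_col", "region_row",
                              "region_col", "value"))
})
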