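# Shared fixtures, built in code at test time.

path3 <- function() adjacency_graph(rbind(c(1, 2), c(2, 3)), 3)

# Desk-scale analogue of a 100-county / 5-year / 6-outcome study: 5 x 6
# queen lattice (N = 30), J = 5, K = 3, a factor trend growing 0 -> 1 on the
# log relative-risk scale, and the rarest outcome interval-censored.
desk_config <- function(graph = lattice_graph(5, 6), ...) {
  sim_config(graph, n_years = 5, n_outcomes = 3,
             mu = seq(0, 1, length.out = 5),
             baseline_rates = c(2e-3, 5e-4, 1.5e-4),
             censor_outcome = 3, censor_bounds = c(1, 5), ...)
}

# Randomized PSD matrix with unit-scale eigenvalues
random_psd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(0.1, n)
}

# Randomized covariance spec on a 3-region graph with K = 3
random_varying_spec <- function(seed) {
  set.seed(seed)
  covariance_spec(
    Sigma_F = random_psd(3),
    loading_means = list(rep(1, 3), rnorm(3, 1, 0.5), rnorm(3, 1, 0.5)),
    loading_covs = list(matrix(0, 3, 3), random_psd(3) / 4, random_psd(3) / 4),
    error_vars = runif(3, 0.05, 0.3))
}

random_constant_spec <- function(seed) {
  set.seed(seed)
  covariance_spec(
    Sigma_F = random_psd(3),
    loading_means = c(1, rnorm(2, 1, 0.5)),
    tau_g2 = c(0, runif(2, 0.05, 0.4)),
    error_vars = runif(3, 0.05, 0.3))
}
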