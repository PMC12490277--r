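#' Configure a synthetic syndemic dataset
#'
#' Defines the generative model for a complete synthetic dataset: a latent
#' factor field with ICAR spatial structure and AR(1) temporal dynamics
#' around year intercepts, mean-one ICAR loadings for every non-reference
#' outcome, and Poisson counts with population-by-baseline-rate offsets and
#' optional interval censoring of one outcome (small-cell suppression).
#'
#' @param graph An [adjacency_graph()]; must be connected.
#' @param n_years Number of years J (at least 2).
#' @param n_outcomes Number of outcomes K (at least 2); outcome 1 is the
#'   reference with loading fixed at 1.
#' @param mu Year intercepts \eqn{\mu_j} of the factor (length J, recycled).
#' @param eta AR(1) coefficient \eqn{\eta}, with `|eta| <= 1`.
#' @param tau_f2 ICAR variance of the factor field, `> 0`.
#' @param tau_g2 ICAR variance of the loading fields (shared across
#'   non-reference outcomes), `> 0`.
#' @param sigma2 Per-outcome error variances \eqn{\sigma_k^2} (length K,
#'   recycled), all `> 0`.
#' @param populations N x J matrix of populations `P_ij` (scalar or length-N
#'   input is recycled across years), all `> 0`.
#' @param baseline_rates Per-outcome baseline rates `r^(k)` (length K,
#'   recycled), all `> 0`; offsets are `E_ijk = P_ij * r^(k)`.
#' @param censor_outcome Index of the interval-censored outcome, or `NA` for
#'   none.
#' @param censor_bounds Inclusive integer censoring interval, default
#'   `c(1, 5)` (counts of 1-5 suppressed).
#' @param mean_ceiling Overflow guard: generation aborts if any Poisson mean
#'   `E * lambda` exceeds this (default 1e9).
#' @return A `sim_config` list.
#' @export
sim_config <- function(graph, n_years, n_outcomes,
                       mu = 0, eta = 0.5, tau_f2 = 0.3, tau_g2 = 0.3,
                       sigma2 = 0.1, populations = 2e4, baseline_rates = 2e-3,
                       censor_outcome = NA_integer_, censor_bounds = c(1L, 5L),
                       mean_ceiling = 1e9) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (graph$n_components != 1L) abort("simulation requires a connected graph.")
  n <- graph$n_regions
  J <- as.integer(n_years); K <- as.integer(n_outcomes)
  if (is.na(J) || J < 2L) abort("`n_years` must be >= 2.")
  if (is.na(K) || K < 2L) abort("`n_outcomes` must be >= 2.")
  mu <- rep_len(as.numeric(mu), J)
  if (!is.finite(eta) || abs(eta) > 1) abort("`eta` must satisfy |eta| <= 1.")
  if (tau_f2 <= 0 || tau_g2 <= 0) abort("ICAR variances must be > 0.")
  sigma2 <- rep_len(as.numeric(sigma2), K)
  if (any(sigma2 <= 0)) abort("`sigma2` must be > 0.")
  if (length(populations) == 1L || length(populations) == n) {
    populations <- matrix(rep_len(as.numeric(populations), n), n, J)
  }
  populations <- as.matrix(populations)
  if (!all(dim(populations) == c(n, J)) || any(populations <= 0)) {
    abort("`populations` must be positive, N x J (or scalar / length-N).")
  }
  baseline_rates <- rep_len(as.numeric(baseline_rates), K)
  if (any(baseline_rates <= 0)) abort("`baseline_rates` must be > 0.")
  if (!is.na(censor_outcome)) {
    censor_outcome <- as.integer(censor_outcome)
    if (censor_outcome < 1L || censor_outcome > K) abort("`censor_outcome` out of range.")
    censor_bounds <- as.integer(censor_bounds)
    if (length(censor_bounds) != 2L || anyNA(censor_bounds) ||
        censor_bounds[1L] > censor_bounds[2L] || censor_bounds[1L] < 0L) {
      abort("`censor_bounds` must be ordered nonnegative integers.")
    }
  }
  structure(list(graph = graph, n_regions = n, n_years = J, n_outcomes = K,
                 mu = mu, eta = eta, tau_f2 = tau_f2, tau_g2 = tau_g2,
                 sigma2 = sigma2, populations = populations,
                 baseline_rates = baseline_rates,
                 censor_outcome = censor_outcome,
                 censor_bounds = as.integer(censor_bounds),
                 mean_ceiling = mean_ceiling),
            class = "sim_config")
}

#' Simulate the latent factor field
#'
#' Year 1 is an ICAR field centred at \eqn{\mu_1}; year \eqn{j \ge 2} is an
#' ICAR field centred at \eqn{\tilde\mu_{ij} = \mu_j + \eta(f_{i,j-1} -
#' \mu_{j-1})}.  Each year's deviations are drawn jointly from the
#' sum-to-zero representative `N(0, tau_f2 * Q^+)` of the improper ICAR, so
#' the year intercepts remain identified.
#'
#' @param config A [sim_config()].
#' @return An N x J matrix of factor values `f_ij`.
#' @export
simulate_factors <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_regions; J <- config$n_years
  eig <- icar_eigen(config$graph)
  d <- icar_draw(config$graph, config$tau_f2, m = J, eig = eig)
  f <- matrix(0, n, J)
  f[, 1L] <- config$mu[1L] + d[, 1L]
  for (j in seq_len(J)[-1L]) {
    mu_tilde <- config$mu[j] + config$eta * (f[, j - 1L] - config$mu[j - 1L])
    f[, j] <- mu_tilde + d[, j]
  }
  dimnames(f) <- list(config$graph$labels, paste0("year", seq_len(J)))
  f
}

#' Simulate the loading fields
#'
#' The reference outcome's column is identically 1; each non-reference
#' column is an independent mean-one ICAR field (sum-to-zero deviations plus
#' 1) with shared variance `tau_g2`.
#'
#' @param config A [sim_config()].
#' @return An N x K matrix of loadings \eqn{\gamma_i^{(k)}}.
#' @export
simulate_loadings <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_regions; K <- config$n_outcomes
  eig <- icar_eigen(config$graph)
  gamma <- matrix(1, n, K)
  if (K > 1L) {
    gamma[, -1L] <- 1 + icar_draw(config$graph, config$tau_g2, m = K - 1L, eig = eig)
  }
  dimnames(gamma) <- list(config$graph$labels, paste0("outcome", seq_len(K)))
  gamma
}

#' Expected counts from populations and baseline counts
#'
#' Computes the per-outcome baseline rate as the overall rate in the
#' baseline year, \eqn{r^{(k)} = \sum_i Y^{(k)}_{i,\mathrm{base}} / \sum_i
#' P_{i,\mathrm{base}}}, and offsets \eqn{E_{ij}^{(k)} = P_{ij} r^{(k)}}, so
#' that \eqn{\exp(\log\lambda)} reads as relative risk against the
#' baseline-year average rate.
#'
#' @param populations N x J matrix of populations.
#' @param baseline_counts N x K matrix of baseline-year counts.
#' @param baseline_year Column of `populations` holding the baseline year
#'   (default 1).
#' @return A list with `rates` (length K) and `offsets` (N x J x K array).
#' @export
expected_counts <- function(populations, baseline_counts, baseline_year = 1L) {
  populations <- as.matrix(populations)
  baseline_counts <- as.matrix(baseline_counts)
  if (any(populations <= 0)) abort("populations must be positive.")
  if (nrow(baseline_counts) != nrow(populations)) {
    abort("`baseline_counts` must have one row per region.")
  }
  tot <- colSums(baseline_counts)
  if (any(tot <= 0)) {
    abort("zero total baseline count for at least one outcome: offset would be 0.")
  }
  rates <- tot / sum(populations[, baseline_year])
  n <- nrow(populations); J <- ncol(populations); K <- length(rates)
  offsets <- outer(populations, rates)
  dim(offsets) <- c(n, J, K)
  list(rates = as.numeric(rates), offsets = offsets)
}

#' Simulate counts given factors and loadings
#'
#' Draws the error layer \eqn{\varepsilon_{ij}^{(k)} \sim N(0, \sigma_k^2)},
#' forms \eqn{\log\lambda_{ij}^{(k)} = \gamma_i^{(k)} f_{ij} +
#' \varepsilon_{ij}^{(k)}}, draws \eqn{Y \sim
#' \mathrm{Poisson}(E\,\lambda)}, and replaces counts of the censored
#' outcome that fall inside the (inclusive) censoring interval by an
#' interval flag.
#'
#' @param config A [sim_config()].
#' @param factors N x J factor matrix (e.g. from [simulate_factors()]).
#' @param loadings N x K loading matrix (e.g. from [simulate_loadings()]).
#' @return A `sim_dataset`: list with `truth` (list of every latent quantity
#'   used: `f`, `gamma`, `loglambda`, `mu`, `eta`, `tau_f2`, `tau_g2`,
#'   `sigma2`) and `observations`, a long-format tibble with columns
#'   `region, year, outcome, count, censored, cens_low, cens_high,
#'   population, offset` (censored cells have `count = NA`).
#' @export
simulate_counts <- function(config, factors, loadings) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_regions; J <- config$n_years; K <- config$n_outcomes
  factors <- as.matrix(factors); loadings <- as.matrix(loadings)
  if (!all(dim(factors) == c(n, J))) abort("`factors` must be N x J.")
  if (!all(dim(loadings) == c(n, K))) abort("`loadings` must be N x K.")

  E <- outer(config$populations, config$baseline_rates)  # n x J x K
  eps <- array(rnorm(n * J * K, 0, rep(rep(sqrt(config$sigma2), each = n * J))),
               dim = c(n, J, K))
  gf <- array(apply(loadings, 2L, function(g) g * factors), dim = c(n, J, K))
  loglambda <- gf + eps
  pmean <- E * exp(loglambda)
  if (any(pmean > config$mean_ceiling)) {
    abort(sprintf("Poisson mean exceeds ceiling %.3g; check variances/rates.",
                  config$mean_ceiling))
  }
  counts <- array(rpois(n * J * K, pmean), dim = c(n, J, K))

  obs <- tidyr::expand_grid(outcome = seq_len(K), year = seq_len(J),
                            region = config$graph$labels)
  obs <- dplyr::select(obs, "region", "year", "outcome")
  obs$count <- as.integer(counts)  # array order: region fastest, outcome slowest
  obs$censored <- 0L
  obs$cens_low <- NA_integer_
  obs$cens_high <- NA_integer_
  obs$population <- as.numeric(config$populations[cbind(
    rep(seq_len(n), times = J * K), rep(rep(seq_len(J), each = n), times = K))])
  obs$offset <- as.numeric(E)
  if (!is.na(config$censor_outcome)) {
    b <- config$censor_bounds
    hit <- obs$outcome == config$censor_outcome &
      obs$count >= b[1L] & obs$count <= b[2L]
    obs$censored[hit] <- 1L
    obs$cens_low[hit] <- b[1L]
    obs$cens_high[hit] <- b[2L]
    obs$count[hit] <- NA_integer_
  }
  obs <- tibble::as_tibble(obs)

  structure(list(
    truth = list(f = factors, gamma = loadings, loglambda = loglambda,
                 mu = config$mu, eta = config$eta, tau_f2 = config$tau_f2,
                 tau_g2 = config$tau_g2, sigma2 = config$sigma2),
    observations = obs, config = config), class = "sim_dataset")
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_factors()], [simulate_loadings()],
#' [simulate_counts()] under one seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional RNG seed; if supplied, the dataset is reproducible
#'   bit-for-bit.
#' @return A `sim_dataset` (see [simulate_counts()]).
#' @examples
#' g <- lattice_graph(3, 3)
#' sim <- simulate_dataset(sim_config(g, n_years = 3, n_outcomes = 2), seed = 1)
#' sim$observations
#' @export
simulate_dataset <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- simulate_factors(config)
  gamma <- simulate_loadings(config)
  simulate_counts(config, f, gamma)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d regions x %d years x %d outcomes (%d cells, %d censored)\n",
              x$config$n_regions, x$config$n_years, x$config$n_outcomes,
              nrow(x$observations), sum(x$observations$censored)))
  invisible(x)
}
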