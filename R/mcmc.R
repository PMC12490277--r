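#' MCMC configuration
#'
#' Sampler settings for [fit_dsfm()].  Defaults mirror a production run
#' (10^6 iterations, half discarded as burn-in, thinning every 50th draw,
#' two chains); tests and examples use far smaller values.
#'
#' @param n_iter Total iterations per chain.
#' @param n_burnin Burn-in iterations discarded (`< n_iter`); proposal
#'   adaptation freezes at the end of burn-in.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of independent chains (two or more enables
#'   [gelman_rubin()]).
#' @param seed Integer seed; chain `c` runs under `seed + c - 1`.
#' @param loadings_mode `"varying"` (spatially varying mean-one ICAR
#'   loadings) or `"constant"` (one scalar loading per outcome with a
#'   `N(1, tau_g2)` prior).
#' @param likelihood If `FALSE`, the observation likelihood is switched off
#'   and the chain targets the prior (for prior-sampling validation only).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 1e6, n_burnin = 5e5, thin = 50,
                        n_chains = 2, seed = 1,
                        loadings_mode = c("varying", "constant"),
                        likelihood = TRUE) {
  loadings_mode <- match.arg(loadings_mode)
  n_iter <- as.integer(n_iter); n_burnin <- as.integer(n_burnin)
  thin <- as.integer(thin); n_chains <- as.integer(n_chains)
  if (n_burnin >= n_iter) abort("`n_burnin` must be < `n_iter`.")
  if (thin < 1L) abort("`thin` must be >= 1.")
  if (n_chains < 1L) abort("`n_chains` must be >= 1.")
  if (n_iter - n_burnin < thin) abort("no draws would be stored.")
  structure(list(n_iter = n_iter, n_burnin = n_burnin, thin = thin,
                 n_chains = n_chains, seed = as.integer(seed),
                 loadings_mode = loadings_mode, likelihood = likelihood),
            class = "mcmc_config")
}

#' Fit the dynamic spatial factor model
#'
#' Runs the Metropolis-within-Gibbs sampler targeting the joint posterior of
#' the hierarchy defined in [log_posterior()]: adaptive random-walk updates
#' for each latent log rate, conjugate Gaussian updates for the factor field
#' and the loadings, conjugate variance updates with rank-corrected ICAR
#' exponents, year intercepts by sum-to-zero centering, and a random-walk
#' update for the AR(1) coefficient constrained to its prior support.
#'
#' @param data A long-format observation data frame (see
#'   [observation_data()] for the schema) or an `observation_data` object.
#' @param graph The [adjacency_graph()] of the regions.
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param loadings_mode Optional override of `config$loadings_mode`.
#' @param ref_outcome Passed to [observation_data()] when `data` is a data
#'   frame.
#' @return A `dsfm_fit` object holding thinned draws of every model
#'   component per chain, acceptance rates, and the inputs.  Use [tidy()],
#'   [glance()], [summarize_posterior()], [gelman_rubin()],
#'   [scale_loadings()], [variance_explained()] and [log_relative_risk()]
#'   on it.
#' @examples
#' g <- lattice_graph(3, 3)
#' sim <- simulate_dataset(sim_config(g, n_years = 3, n_outcomes = 2), seed = 1)
#' fit <- fit_dsfm(sim$observations, g,
#'                 config = mcmc_config(n_iter = 400, n_burnin = 200, thin = 2,
#'                                      n_chains = 1))
#' glance(fit)
#' @export
fit_dsfm <- function(data, graph, priors = prior_spec(),
                     config = mcmc_config(), loadings_mode = NULL,
                     ref_outcome = NULL) {
  stopifnot(inherits(graph, "adjacency_graph"), inherits(priors, "prior_spec"),
            inherits(config, "mcmc_config"))
  if (!inherits(data, "observation_data")) {
    data <- observation_data(data, graph, ref_outcome = ref_outcome)
  }
  if (!is.null(loadings_mode)) {
    config$loadings_mode <- match.arg(loadings_mode, c("varying", "constant"))
  }
  constant_mode <- config$loadings_mode == "constant"
  n <- data$n_regions; J <- data$n_years; K <- data$n_outcomes

  init <- init_state(data, constant_mode)
  check <- log_posterior(
    c(init, list(mu = rep(0, J))), data, priors, graph)
  if (!is.finite(check)) {
    abort(paste0("non-finite log posterior at initialization (", check, "); ",
                 "check offsets, counts and censoring intervals."))
  }

  prior_ab <- if (priors$variance_prior == "invgamma") {
    c(priors$ig_shape, priors$ig_scale)
  } else {
    c(priors$gamma_shape, priors$gamma_rate)
  }
  adj <- unlist(graph$neighbors)
  adj_start <- c(0L, cumsum(lengths(graph$neighbors)))

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    chains[[ch]] <- run_chain_cpp(
      dims = c(n, J, K),
      counts = as.numeric(data$counts), status = as.integer(data$status),
      cens_low = as.numeric(data$cens_low), cens_high = as.numeric(data$cens_high),
      offsets = ifelse(is.na(as.numeric(data$offsets)), 1, as.numeric(data$offsets)),
      ref = data$ref_outcome,
      edge_a = graph$edges[, 1L], edge_b = graph$edges[, 2L],
      adj = adj, adj_start = adj_start,
      degrees = graph$degrees, n_components = graph$n_components,
      prior_a = prior_ab[1L], prior_s = prior_ab[2L],
      eta_lo = priors$eta_bounds[1L], eta_hi = priors$eta_bounds[2L],
      init = init,
      n_iter = config$n_iter, n_burnin = config$n_burnin, thin = config$thin,
      constant_mode = constant_mode, use_likelihood = config$likelihood)
  }

  structure(list(chains = chains, data = data, graph = graph,
                 priors = priors, config = config,
                 n_keep = (config$n_iter - config$n_burnin) %/% config$thin),
            class = "dsfm_fit")
}

init_state <- function(data, constant_mode) {
  n <- data$n_regions; J <- data$n_years; K <- data$n_outcomes
  y0 <- data$counts
  mid <- (data$cens_low + data$cens_high) / 2
  y0[data$status == 2L] <- mid[data$status == 2L]
  E0 <- data$offsets
  E0[is.na(E0)] <- 1
  ll0 <- log((y0 + 0.5) / E0)
  ll0[data$status == 0L] <- 0
  list(f = matrix(0, n, J),
       gamma = if (constant_mode) rep(1, K) else matrix(1, n, K),
       loglambda = ll0,
       sigma2 = rep(1, K), tau_f2 = 1, tau_g2 = 1, eta = 0)
}

#' @export
print.dsfm_fit <- function(x, ...) {
  cat(sprintf("<dsfm_fit> %s loadings; %d chain(s) x %d stored draws\n",
              x$config$loadings_mode, length(x$chains), x$n_keep))
  cat(sprintf("  %d regions x %d years x %d outcomes; acceptance: loglambda %.2f, eta %.2f\n",
              x$data$n_regions, x$data$n_years, x$data$n_outcomes,
              mean(purrr::map_dbl(x$chains, "accept_loglambda")),
              mean(purrr::map_dbl(x$chains, "accept_eta"))))
  invisible(x)
}

# Pooled draw matrix for a parameter group; columns named, rows are draws
# stacked across chains (or a list of per-chain matrices if pool = FALSE).
draw_matrix <- function(fit, par, pool = TRUE) {
  d <- fit$data
  nms <- switch(par,
    f = as.vector(outer(d$regions, d$years, function(r, y) paste0("f[", r, ",", y, "]"))),
    gamma = if (fit$config$loadings_mode == "constant") {
      paste0("gamma[", d$outcomes, "]")
    } else {
      as.vector(outer(d$regions, d$outcomes, function(r, k) paste0("gamma[", r, ",", k, "]")))
    },
    loglambda = {
      g <- expand.grid(region = d$regions, year = d$years, outcome = d$outcomes)
      paste0("loglambda[", g$region, ",", g$year, ",", g$outcome, "]")
    },
    sigma2 = paste0("sigma2[", d$outcomes, "]"),
    mu = paste0("mu[", d$years, "]"),
    tau_f2 = "tau_f2", tau_g2 = "tau_g2", eta = "eta",
    abort(sprintf("unknown parameter group '%s'.", par)))
  mats <- lapply(fit$chains, function(ch) {
    m <- ch[[par]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
    colnames(m) <- nms
    m
  })
  if (pool) do.call(rbind, mats) else mats
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF \eqn{\sqrt{((n-1)/n\,W + B/n)/W}} comparing within- and
#' between-chain variance; values near 1 indicate convergence (a common
#' working threshold is 1.1).  Parameters with zero within-chain variance
#' are reported as `NA` (undefined), not an error.
#'
#' @param x A `dsfm_fit` with at least two chains, or a numeric matrix with
#'   one column per chain.
#' @param pars For the fit method: character vector of parameter groups
#'   among `"sigma2", "tau_f2", "tau_g2", "eta", "mu", "gamma", "f",
#'   "loglambda"`.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `psrf` (matrix method:
#'   a single number).
#' @export
gelman_rubin <- function(x, ...) UseMethod("gelman_rubin")

#' @rdname gelman_rubin
#' @export
gelman_rubin.matrix <- function(x, ...) {
  m <- ncol(x); n <- nrow(x)
  if (m < 2L) abort("need >= 2 chains.")
  if (n < 10L) abort("need >= 10 stored draws per chain.")
  W <- mean(apply(x, 2L, var))
  B_over_n <- var(colMeans(x))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' @rdname gelman_rubin
#' @export
gelman_rubin.dsfm_fit <- function(x, pars = c("sigma2", "tau_f2", "tau_g2",
                                              "eta", "mu", "gamma"), ...) {
  if (length(x$chains) < 2L) abort("need >= 2 chains.")
  purrr::map_dfr(pars, function(p) {
    mats <- draw_matrix(x, p, pool = FALSE)
    psrf <- purrr::map_dbl(seq_len(ncol(mats[[1L]])), function(cc) {
      gelman_rubin.matrix(do.call(cbind, lapply(mats, function(m) m[, cc])))
    })
    tibble::tibble(parameter = colnames(mats[[1L]]), psrf = psrf)
  })
}
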