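#' Observation log-likelihood with interval censoring
#'
#' Poisson log-likelihood of one (or many) count cells with mean
#' \eqn{m = E\,e^{\log\lambda}}.  A censored cell contributes the log
#' probability that the count lies in the inclusive interval
#' `[cens_low, cens_high]`, \eqn{\log \sum_{y=a}^{b} \mathrm{Pois}(y; m)},
#' evaluated stably via log-sum-exp of log pmf terms (upper bound may be
#' `Inf`).  This is the small-cell-suppression likelihood: for suppressed
#' counts only the interval (here typically 1-5) is known.
#'
#' @param count Nonnegative integer count(s); `NA` for censored cells.
#' @param offset Expected count(s) `E > 0`.
#' @param loglambda Latent log relative risk(s).
#' @param cens_low,cens_high Inclusive interval bounds for censored cells
#'   (`NA` for observed cells).
#' @return Numeric vector of log-likelihood contributions.
#' @examples
#' obs_loglik(3, offset = 1, loglambda = log(2))      # dpois(3, 2, log = TRUE)
#' obs_loglik(NA, 1, 0, cens_low = 1, cens_high = 5)  # log P(1 <= Y <= 5), Y ~ Pois(1)
#' @export
obs_loglik <- function(count, offset, loglambda, cens_low = NA, cens_high = NA) {
  nn <- max(length(count), length(offset), length(loglambda),
            length(cens_low), length(cens_high))
  count <- rep_len(count, nn); offset <- rep_len(offset, nn)
  loglambda <- rep_len(loglambda, nn)
  cens_low <- rep_len(cens_low, nn); cens_high <- rep_len(cens_high, nn)
  if (any(offset <= 0)) abort("`offset` must be positive.")
  m <- offset * exp(loglambda)
  out <- numeric(nn)
  cens <- is.na(count)
  if (any(!cens)) {
    y <- count[!cens]
    if (any(y < 0)) abort("negative count.")
    out[!cens] <- dpois(y, m[!cens], log = TRUE)
  }
  for (idx in which(cens)) {
    a <- cens_low[idx]; b <- cens_high[idx]
    if (is.na(a) || is.na(b)) abort("censored cell without interval bounds.")
    if (a < 0) abort("negative count.")
    if (a > b) abort("censoring interval has a > b.")
    out[idx] <- pois_interval_logprob(a, b, m[idx])
  }
  out
}

pois_interval_logprob <- function(a, b, m) {
  if (is.infinite(b)) {
    if (a <= 0) return(0)
    return(ppois(a - 1, m, lower.tail = FALSE, log.p = TRUE))
  }
  lp <- dpois(a:b, m, log = TRUE)
  mx <- max(lp)
  mx + log(sum(exp(lp - mx)))
}

#' Prior specification
#'
#' Priors for the variance components, year intercepts and AR(1)
#' coefficient.  The default puts inverse-gamma(0.5, 0.5) priors on the
#' variances \eqn{\sigma_k^2, \tau_f^2, \tau_\gamma^2}, flat priors on the
#' year intercepts \eqn{\mu_j}, and a Uniform(-1, 1) prior on \eqn{\eta}
#' (the AR(1) support; the prior on \eqn{\eta} is a modelling choice of this
#' package and is configurable).  `variance_prior = "gamma_precision"`
#' switches to a Gamma(`gamma_shape`, `gamma_rate`) prior on the
#' *precisions* (default Gamma(5, 2)), the alternative used for prior
#' sensitivity runs.
#'
#' @param variance_prior `"invgamma"` (default) or `"gamma_precision"`.
#' @param ig_shape,ig_scale Inverse-gamma shape and scale (default 0.5, 0.5).
#' @param gamma_shape,gamma_rate Shape and rate of the Gamma prior on the
#'   precision (default 5, 2), used when `variance_prior =
#'   "gamma_precision"`.
#' @param eta_bounds Support of the uniform prior on `eta`.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(variance_prior = c("invgamma", "gamma_precision"),
                       ig_shape = 0.5, ig_scale = 0.5,
                       gamma_shape = 5, gamma_rate = 2,
                       eta_bounds = c(-1, 1)) {
  variance_prior <- match.arg(variance_prior)
  if (ig_shape <= 0 || ig_scale <= 0 || gamma_shape <= 0 || gamma_rate <= 0) {
    abort("prior shapes/scales must be positive.")
  }
  if (length(eta_bounds) != 2L || eta_bounds[1L] >= eta_bounds[2L]) {
    abort("`eta_bounds` must be an increasing pair.")
  }
  structure(list(variance_prior = variance_prior,
                 ig_shape = ig_shape, ig_scale = ig_scale,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 eta_bounds = as.numeric(eta_bounds)),
            class = "prior_spec")
}

log_prior_variance <- function(v, priors) {
  if (priors$variance_prior == "invgamma") {
    a <- priors$ig_shape; s <- priors$ig_scale
    sum(a * log(s) - lgamma(a) - (a + 1) * log(v) - s / v)
  } else {
    # Gamma(shape, rate) on the precision 1/v, with Jacobian 1/v^2
    sum(dgamma_log(1 / v, priors$gamma_shape, priors$gamma_rate) - 2 * log(v))
  }
}

dgamma_log <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) + (shape - 1) * log(x) - rate * x
}

#' Assemble validated observation data
#'
#' Validates and indexes a long-format observation table against an
#' adjacency graph, producing the arrays the likelihood and sampler consume.
#' Cells absent from `data` are treated as missing (no likelihood
#' contribution).
#'
#' @param data A data frame with columns `region, year, outcome, count,
#'   censored, cens_low, cens_high, population` and optionally `offset`.
#'   `region` must use the graph's labels; `censored` is 0/1; censored rows
#'   carry interval bounds and `count = NA`.
#' @param graph An [adjacency_graph()] whose labels define the region order.
#' @param offsets Optional N x J x K array of expected counts; if absent the
#'   `offset` column is used.
#' @param ref_outcome Reference outcome (label or index) whose loading is
#'   fixed at 1; default the first outcome level.
#' @return An `observation_data` list: `counts`, `censored`, `cens_low`,
#'   `cens_high`, `offsets` (N x J x K arrays; `status` codes 0 missing / 1
#'   observed / 2 censored), `populations` (N x J), `regions`, `years`,
#'   `outcomes`, `ref_outcome` (index).
#' @export
observation_data <- function(data, graph, offsets = NULL, ref_outcome = NULL) {
  stopifnot(inherits(graph, "adjacency_graph"))
  data <- as.data.frame(data)
  req <- c("region", "year", "outcome", "count", "censored", "population")
  miss <- setdiff(req, names(data))
  if (length(miss)) abort(paste0("missing required column(s): ",
                                 paste(miss, collapse = ", ")))
  if (!"cens_low" %in% names(data)) data$cens_low <- NA_integer_
  if (!"cens_high" %in% names(data)) data$cens_high <- NA_integer_

  region_idx <- match(as.character(data$region), graph$labels)
  if (anyNA(region_idx)) {
    bad <- which(is.na(region_idx))[1L]
    abort(sprintf("row %d: unknown region label '%s'.", bad, data$region[bad]))
  }
  years <- sort(unique(data$year))
  outcomes <- unique(as.character(data$outcome))
  year_idx <- match(data$year, years)
  out_idx <- match(as.character(data$outcome), outcomes)
  n <- graph$n_regions; J <- length(years); K <- length(outcomes)
  if (J < 2L) abort("need at least two years.")

  bad <- which(!is.na(data$count) & data$count < 0)
  if (length(bad)) abort(sprintf("row %d: negative count.", bad[1L]))
  bad <- which(data$censored == 1L &
                 (is.na(data$cens_low) | is.na(data$cens_high) |
                    data$cens_low > data$cens_high))
  if (length(bad)) abort(sprintf("row %d: censored cell needs ordered bounds.", bad[1L]))
  bad <- which(data$censored == 0L & is.na(data$count))
  if (length(bad)) abort(sprintf("row %d: uncensored cell with missing count.", bad[1L]))
  if (any(data$population <= 0)) abort("populations must be positive.")

  idx <- cbind(region_idx, year_idx, out_idx)
  if (anyDuplicated(idx)) abort("duplicated (region, year, outcome) cell.")

  arr <- function(init) array(init, dim = c(n, J, K))
  counts <- arr(NA_real_); censored <- arr(0); clo <- arr(NA_real_)
  chi <- arr(NA_real_); E <- arr(NA_real_); status <- arr(0L)
  counts[idx] <- data$count
  censored[idx] <- data$censored
  clo[idx] <- data$cens_low
  chi[idx] <- data$cens_high
  status[idx] <- ifelse(data$censored == 1L, 2L, 1L)

  populations <- matrix(NA_real_, n, J)
  populations[cbind(region_idx, year_idx)] <- data$population
  if (anyNA(populations)) {
    abort("every (region, year) needs a population in at least one outcome row.")
  }

  if (is.null(offsets)) {
    if (!"offset" %in% names(data)) abort("supply `offsets` or an `offset` column.")
    E[idx] <- data$offset
  } else {
    if (!all(dim(offsets) == c(n, J, K))) abort("`offsets` must be N x J x K.")
    E <- offsets
  }
  if (any(E[status > 0L] <= 0, na.rm = TRUE)) abort("offsets must be positive.")

  if (is.null(ref_outcome)) ref_outcome <- 1L
  if (is.character(ref_outcome)) {
    ref_outcome <- match(ref_outcome, outcomes)
    if (is.na(ref_outcome)) abort("`ref_outcome` not among outcome labels.")
  }
  ref_outcome <- as.integer(ref_outcome)
  if (ref_outcome < 1L || ref_outcome > K) abort("`ref_outcome` out of range.")

  structure(list(counts = counts, censored = censored, cens_low = clo,
                 cens_high = chi, offsets = E, status = status,
                 populations = populations, regions = graph$labels,
                 years = years, outcomes = outcomes,
                 ref_outcome = ref_outcome,
                 n_regions = n, n_years = J, n_outcomes = K),
            class = "observation_data")
}

#' @export
print.observation_data <- function(x, ...) {
  cat(sprintf(
    "<observation_data> %d regions x %d years x %d outcomes; %d observed, %d censored, %d missing\n",
    x$n_regions, x$n_years, x$n_outcomes, sum(x$status == 1L),
    sum(x$status == 2L), sum(x$status == 0L)))
  invisible(x)
}

#' Joint log posterior of one model state
#'
#' Sum of every log-density layer of the hierarchy: the (possibly
#' interval-censored) Poisson observation likelihood; the Gaussian error
#' layer of `loglambda` around \eqn{\gamma_i^{(k)} f_{ij}}; the year-wise
#' ICAR prior of the factor field (year 1 centred at \eqn{\mu_1}, later
#' years at \eqn{\tilde\mu_{ij} = \mu_j + \eta(f_{i,j-1} - \mu_{j-1})});
#' the mean-one ICAR prior of each non-reference loading column (or its
#' Gaussian analogue when loadings are scalar); the variance priors; and
#' the uniform prior on \eqn{\eta}.  Flat \eqn{\mu_j} priors contribute 0.
#' Additive constants of the improper ICAR layers are dropped.
#'
#' @param state List with elements `f` (N x J), `gamma` (N x K matrix, or
#'   length-K vector for spatially constant loadings), `loglambda`
#'   (N x J x K), `sigma2` (length K), `tau_f2`, `tau_g2`, `mu` (length J),
#'   `eta`.
#' @param data An [observation_data()].
#' @param priors A [prior_spec()].
#' @param graph The [adjacency_graph()].
#' @return A single finite numeric value (or `-Inf` outside the support).
#' @export
log_posterior <- function(state, data, priors, graph) {
  stopifnot(inherits(data, "observation_data"), inherits(priors, "prior_spec"),
            inherits(graph, "adjacency_graph"))
  n <- data$n_regions; J <- data$n_years; K <- data$n_outcomes
  f <- state$f
  gamma <- state$gamma
  constant_mode <- is.null(dim(gamma))
  gmat <- if (constant_mode) matrix(gamma, n, K, byrow = TRUE) else gamma
  if (any(abs(gmat[, data$ref_outcome] - 1) > 0)) {
    abort("reference loading column must be exactly 1.")
  }
  if (any(state$sigma2 <= 0) || state$tau_f2 <= 0 || state$tau_g2 <= 0) {
    return(-Inf)
  }
  if (state$eta < priors$eta_bounds[1L] || state$eta > priors$eta_bounds[2L]) {
    return(-Inf)
  }

  # observation layer
  ll <- 0
  obs <- data$status == 1L
  if (any(obs)) {
    ll <- ll + sum(dpois(data$counts[obs], data$offsets[obs] * exp(state$loglambda[obs]),
                         log = TRUE))
  }
  for (idx in which(data$status == 2L)) {
    ll <- ll + pois_interval_logprob(data$cens_low[idx], data$cens_high[idx],
                                     data$offsets[idx] * exp(state$loglambda[idx]))
  }

  # error layer
  gf <- array(apply(gmat, 2L, function(g) g * f), dim = c(n, J, K))
  sig <- rep(sqrt(state$sigma2), each = n * J)
  ll <- ll + sum(dnorm(as.vector(state$loglambda), as.vector(gf), sig, log = TRUE))

  # factor prior, year by year
  ll <- ll + log_prior_icar(f[, 1L], state$mu[1L], state$tau_f2, graph)
  for (j in seq_len(J)[-1L]) {
    mu_tilde <- state$mu[j] + state$eta * (f[, j - 1L] - state$mu[j - 1L])
    ll <- ll + log_prior_icar(f[, j], mu_tilde, state$tau_f2, graph)
  }

  # loadings prior
  for (k in setdiff(seq_len(K), data$ref_outcome)) {
    ll <- ll + if (constant_mode) {
      dnorm(gamma[k], 1, sqrt(state$tau_g2), log = TRUE)
    } else {
      log_prior_icar(gamma[, k], 1, state$tau_g2, graph)
    }
  }

  # variance and eta priors
  ll <- ll + log_prior_variance(state$sigma2, priors)
  ll <- ll + log_prior_variance(state$tau_f2, priors)
  ll <- ll + log_prior_variance(state$tau_g2, priors)
  ll <- ll - log(diff(priors$eta_bounds))
  ll
}
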