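#' Posterior summary table
#'
#' Pooled-across-chains posterior mean and central 95% credible interval
#' (2.5 and 97.5 percentiles) for selected parameter groups, with a
#' formatted `"mean (lo, hi)"` string.
#'
#' @param fit A `dsfm_fit`.
#' @param pars Character vector of parameter groups (see [gelman_rubin()]).
#' @param digits Digits for the formatted string (default 3).
#' @return A tibble with columns `parameter, mean, lower, upper, formatted`
#'   and a `degenerate` flag marking constant-draw (zero-width) intervals,
#'   such as the pinned reference loading.
#' @export
summarize_posterior <- function(fit, pars = c("gamma", "sigma2", "tau_f2",
                                              "tau_g2", "eta", "mu"),
                                digits = 3) {
  stopifnot(inherits(fit, "dsfm_fit"))
  purrr::map_dfr(pars, function(p) {
    m <- draw_matrix(fit, p)
    if (nrow(m) < 40L) abort("need at least 40 pooled draws for 2.5% quantiles.")
    summarize_draws(m, digits)
  })
}

# Degenerate (constant-draw) intervals, e.g. the pinned reference loading,
# are flagged in a column rather than warned about.
summarize_draws <- function(m, digits = 3) {
  qs <- apply(m, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  mu <- colMeans(m)
  fmt <- paste0("%.", digits, "f")
  mu <- unname(mu); qs <- unname(qs)
  tibble::tibble(
    parameter = colnames(m), mean = mu, lower = qs[1L, ], upper = qs[2L, ],
    formatted = sprintf(paste0(fmt, " (", fmt, ", ", fmt, ")"),
                        mu, qs[1L, ], qs[2L, ]),
    degenerate = qs[1L, ] == qs[2L, ])
}

#' @export
tidy.dsfm_fit <- function(x, pars = c("gamma", "sigma2", "tau_f2", "tau_g2",
                                      "eta", "mu"), ...) {
  dplyr::select(summarize_posterior(x, pars), -"formatted", -"degenerate")
}

#' @export
glance.dsfm_fit <- function(x, ...) {
  psrf_max <- if (length(x$chains) >= 2L) {
    max(gelman_rubin.dsfm_fit(x)$psrf, na.rm = TRUE)
  } else NA_real_
  tibble::tibble(
    n_chains = length(x$chains), n_draws = x$n_keep,
    loadings_mode = x$config$loadings_mode,
    accept_loglambda = mean(purrr::map_dbl(x$chains, "accept_loglambda")),
    accept_eta = mean(purrr::map_dbl(x$chains, "accept_eta")),
    psrf_max = psrf_max)
}

#' Scaled loadings
#'
#' Divides each loading by the sum of the K outcome loadings at the same
#' region, so that 1/K is the equal-contribution baseline (0.167 for six
#' outcomes): values above 1/K mark outcomes in stronger agreement with the
#' latent factor at that region.  For a fitted model the scaling is applied
#' per posterior draw and then averaged, propagating uncertainty through the
#' nonlinear transform; regions where the loading sum is numerically zero
#' are flagged undefined rather than dropped.
#'
#' @param x A `dsfm_fit` (varying loadings), or a numeric matrix/data frame
#'   of raw loadings with one row per region and one column per outcome.
#' @param tol Loading sums with `|sum| < tol` are flagged undefined.
#' @param ... Unused.
#' @return A tibble with columns `region, outcome, scaled` (and `lower,
#'   upper` for the fit method) plus a logical `undefined` column.
#' @examples
#' scale_loadings(matrix(1, 2, 6))  # every entry 1/6
#' @export
scale_loadings <- function(x, ...) UseMethod("scale_loadings")

#' @export
scale_loadings.default <- function(x, tol = 1e-6, ...) {
  m <- as.matrix(x)
  if (ncol(m) < 2L) abort("need K >= 2 outcomes.")
  s <- rowSums(m)
  undefined <- abs(s) < tol
  scaled <- m / s
  scaled[undefined, ] <- NA_real_
  out <- tibble::tibble(
    region = rep(seq_len(nrow(m)), times = ncol(m)),
    outcome = rep(colnames(m) %||% seq_len(ncol(m)), each = nrow(m)),
    scaled = as.vector(scaled),
    undefined = rep(undefined, times = ncol(m)))
  out
}

#' @export
scale_loadings.dsfm_fit <- function(x, tol = 1e-6, ...) {
  if (x$config$loadings_mode != "varying") {
    abort("per-region scaled loadings need a spatially varying fit.")
  }
  d <- x$data; n <- d$n_regions; K <- d$n_outcomes
  draws <- draw_matrix(x, "gamma")  # S x (n K), region fastest
  S <- nrow(draws)
  arr <- array(draws, dim = c(S, n, K))
  sums <- apply(arr, c(1L, 2L), sum)              # S x n
  undef <- abs(sums) < tol
  scaled <- arr / array(sums, dim = c(S, n, K))
  scaled[array(undef, dim = c(S, n, K))] <- NA_real_
  agg <- apply(scaled, c(2L, 3L), function(v) {
    c(mean(v, na.rm = TRUE), quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
  })  # 3 x n x K
  tibble::tibble(
    region = rep(d$regions, times = K),
    outcome = rep(d$outcomes, each = n),
    scaled = as.vector(agg[1L, , ]),
    lower = as.vector(agg[2L, , ]),
    upper = as.vector(agg[3L, , ]),
    undefined = rep(colMeans(undef) > 0.5, times = K))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variance explained by the factor
#'
#' For each region and outcome, the share of the log-rate variance over time
#' explained by the factor term:
#' \deqn{\frac{\mathrm{Var}_j(\hat\gamma_i^{(k)} \hat f_{ij})}
#'       {\mathrm{Var}_j(\hat\gamma_i^{(k)} \hat f_{ij}) + \hat\sigma_k^2},}
#' computed from posterior means, with the empirical variance taken over the
#' J years.  Values above 0.50 mark region-outcome pairs where the shared
#' factor dominates the independent error.
#'
#' @param fit A `dsfm_fit`.
#' @return A tibble with columns `region, outcome, ratio, above_half`.
#' @export
variance_explained <- function(fit) {
  stopifnot(inherits(fit, "dsfm_fit"))
  d <- fit$data; n <- d$n_regions; J <- d$n_years; K <- d$n_outcomes
  if (J < 2L) abort("time variance undefined for J < 2.")
  f_hat <- matrix(colMeans(draw_matrix(fit, "f")), n, J)
  gdraws <- colMeans(draw_matrix(fit, "gamma"))
  g_hat <- if (fit$config$loadings_mode == "constant") {
    matrix(gdraws, n, K, byrow = TRUE)
  } else {
    matrix(gdraws, n, K)
  }
  s_hat <- colMeans(draw_matrix(fit, "sigma2"))
  ratio <- matrix(0, n, K)
  for (k in seq_len(K)) {
    v <- apply(g_hat[, k] * f_hat, 1L, var)
    ratio[, k] <- v / (v + s_hat[k])
  }
  tibble::tibble(region = rep(d$regions, times = K),
                 outcome = rep(d$outcomes, each = n),
                 ratio = as.vector(ratio),
                 above_half = as.vector(ratio) >= 0.5)
}

#' Posterior log relative risk
#'
#' Posterior mean and 95% interval of the latent log relative risk
#' \eqn{\log\lambda_{ij}^{(k)}} for every region, year and outcome.  Zero
#' corresponds to the baseline-year state-average rate used to build the
#' offsets.
#'
#' @param fit A `dsfm_fit`.
#' @return A tibble with columns `region, year, outcome, log_rr, lower,
#'   upper`.
#' @export
log_relative_risk <- function(fit) {
  stopifnot(inherits(fit, "dsfm_fit"))
  d <- fit$data
  m <- draw_matrix(fit, "loglambda")
  qs <- apply(m, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  grid <- expand.grid(region = d$regions, year = d$years, outcome = d$outcomes,
                      stringsAsFactors = FALSE)
  tibble::tibble(region = grid$region, year = grid$year, outcome = grid$outcome,
                 log_rr = unname(colMeans(m)), lower = unname(qs[1L, ]),
                 upper = unname(qs[2L, ]))
}
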