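#' Specify the marginal covariance inputs of a one-factor spatial model
#'
#' Collects the ingredients of the closed-form marginal covariance of the
#' stacked outcome vector \eqn{Y = (Y^{(1)}_{1:N}, \ldots, Y^{(K)}_{1:N})}
#' under the Gaussian linear one-factor model
#' \eqn{Y_i^{(k)} = \gamma_i^{(k)} f_i + \varepsilon_i^{(k)}}, where the
#' factor vector has spatial covariance \eqn{\Sigma^F}, the loadings of each
#' non-reference outcome are Gaussian with mean \eqn{\mu^{(k)}} and either a
#' spatial covariance \eqn{\Sigma^{\Gamma(k)}} (spatially varying) or a
#' scalar variance \eqn{\tau_{\gamma(k)}^2} (spatially constant), and the
#' errors are independent with variances \eqn{\sigma_{(k)}^2}.  Outcome 1 is
#' the reference: its loading is fixed at 1 everywhere.
#'
#' @param Sigma_F N x N symmetric positive semi-definite factor covariance.
#' @param loading_means For the spatially varying form, a list of `K` mean
#'   vectors of length N (element 1 must be all ones); for the constant form,
#'   a numeric vector of `K` scalars (element 1 must be 1).
#' @param loading_covs Spatially varying form only: list of `K` N x N PSD
#'   matrices (element 1 must be the zero matrix).
#' @param tau_g2 Constant form only: numeric vector of `K` loading variances
#'   (element 1 must be 0).
#' @param error_vars Numeric vector of `K` error variances, each `>= 0`.
#' @return A `covariance_spec` with `form` `"varying"` or `"constant"`.
#' @examples
#' spec <- covariance_spec(
#'   Sigma_F = matrix(1), loading_means = list(1, 2),
#'   loading_covs = list(matrix(0), matrix(0.25)), error_vars = c(0.1, 0.2))
#' marginal_covariance(spec)
#' @export
covariance_spec <- function(Sigma_F, loading_means, loading_covs = NULL,
                            tau_g2 = NULL, error_vars) {
  Sigma_F <- as.matrix(Sigma_F)
  n <- nrow(Sigma_F)
  check_psd(Sigma_F, "Sigma_F")
  if (is.null(loading_covs) == is.null(tau_g2)) {
    abort("supply exactly one of `loading_covs` (varying) or `tau_g2` (constant).")
  }
  form <- if (is.null(tau_g2)) "varying" else "constant"
  K <- length(loading_means)
  if (K < 2L) abort("need at least two outcomes (reference plus one).")
  if (length(error_vars) != K || any(error_vars < 0)) {
    abort("`error_vars` must be K nonnegative variances.")
  }

  if (form == "varying") {
    if (!is.list(loading_means)) abort("varying form: `loading_means` must be a list of vectors.")
    loading_means <- lapply(loading_means, function(m) rep_len(as.numeric(m), n))
    if (any(loading_means[[1L]] != 1)) {
      abort("reference outcome loading mean must be identically 1.")
    }
    if (length(loading_covs) != K) abort("`loading_covs` must have one matrix per outcome.")
    loading_covs <- lapply(loading_covs, function(S) {
      S <- as.matrix(S)
      if (!all(dim(S) == n)) abort("loading covariance dimension mismatch.")
      check_psd(S, "loading_covs")
      S
    })
    if (any(loading_covs[[1L]] != 0)) {
      abort("reference outcome loading covariance must be zero.")
    }
  } else {
    loading_means <- as.numeric(loading_means)
    if (loading_means[1L] != 1) abort("reference outcome loading must be 1.")
    tau_g2 <- as.numeric(tau_g2)
    if (length(tau_g2) != K || any(tau_g2 < 0)) {
      abort("`tau_g2` must be K nonnegative variances.")
    }
    if (tau_g2[1L] != 0) abort("reference outcome loading variance must be 0.")
  }

  structure(list(Sigma_F = Sigma_F, loading_means = loading_means,
                 loading_covs = loading_covs, tau_g2 = tau_g2,
                 error_vars = as.numeric(error_vars),
                 n_regions = n, n_outcomes = K, form = form),
            class = "covariance_spec")
}

check_psd <- function(S, name, tol = 1e-8) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    abort(sprintf("`%s` is not positive semi-definite (min eigenvalue %.3g).",
                  name, min(ev)))
  }
  invisible(S)
}

#' Closed-form marginal covariance of the stacked outcome vector
#'
#' Builds the K x K grid of N x N covariance blocks of
#' \eqn{Y = (Y^{(1)}, \ldots, Y^{(K)})} after marginalising over the factor
#' and the loadings.  With spatially varying loadings the diagonal block of
#' outcome \eqn{k \ge 2} is
#' \eqn{[\Sigma^{\Gamma(k)} + \mu^{(k)}\mu^{(k)\top}] \odot \Sigma^F +
#' \Sigma^{\varepsilon(k)}}, so the spatial covariance of an outcome carries
#' the spatial covariance of its loadings as well as that of the factor;
#' with constant loadings it collapses to
#' \eqn{(\tau_{\gamma(k)}^2 + \mu^{(k)2})\,\Sigma^F +
#' \Sigma^{\varepsilon(k)}}, proportional to the factor covariance.  Cross
#' blocks are \eqn{\mu_i^{(k)}\mu_j^{(k')}\Sigma^F_{ij}} (with
#' \eqn{\mu^{(1)} \equiv 1}).
#'
#' `marginal_cov_varying()` and `marginal_cov_constant()` require the
#' matching spec form; `marginal_covariance()` dispatches on it.
#'
#' @param spec A [covariance_spec()].
#' @return A `block_covariance`: the full `(N K) x (N K)` matrix with
#'   accessors [cov_block()] and [cov_entry()], and a [tidy()] method giving
#'   the flat `(outcome_row, outcome_col, region_row, region_col, value)`
#'   table.
#' @examples
#' g <- covariance_spec(matrix(c(1, .5, .5, 1), 2), loading_means = c(1, 2),
#'                      tau_g2 = c(0, 0), error_vars = c(0, 0))
#' cov_block(marginal_covariance(g), 2, 2)  # 4 * Sigma_F
#' @export
marginal_covariance <- function(spec) {
  stopifnot(inherits(spec, "covariance_spec"))
  if (spec$form == "varying") marginal_cov_varying(spec) else marginal_cov_constant(spec)
}

#' @rdname marginal_covariance
#' @export
marginal_cov_varying <- function(spec) {
  stopifnot(inherits(spec, "covariance_spec"))
  if (spec$form != "varying") abort("spec is not in spatially varying form.")
  n <- spec$n_regions; K <- spec$n_outcomes
  blocks_from(spec, n, K,
              mu = spec$loading_means,
              gcov = spec$loading_covs)
}

#' @rdname marginal_covariance
#' @export
marginal_cov_constant <- function(spec) {
  stopifnot(inherits(spec, "covariance_spec"))
  if (spec$form != "constant") abort("spec is not in spatially constant form.")
  n <- spec$n_regions; K <- spec$n_outcomes
  ones <- matrix(1, n, n)
  blocks_from(spec, n, K,
              mu = lapply(spec$loading_means, function(m) rep(m, n)),
              gcov = lapply(spec$tau_g2, function(t2) t2 * ones))
}

# Shared block assembly: block (k,k') = [ delta_kk' Sigma_Gamma(k)
#   + mu_k mu_k'^T ] (.) Sigma_F + delta_kk' sigma_k^2 I.
blocks_from <- function(spec, n, K, mu, gcov) {
  full <- matrix(0, n * K, n * K)
  for (k1 in seq_len(K)) for (k2 in k1:K) {
    B <- outer(mu[[k1]], mu[[k2]]) * spec$Sigma_F
    if (k1 == k2) {
      B <- B + gcov[[k1]] * spec$Sigma_F + diag(spec$error_vars[k1], n)
    }
    r <- (k1 - 1L) * n + seq_len(n); c <- (k2 - 1L) * n + seq_len(n)
    full[r, c] <- B
    if (k1 != k2) full[c, r] <- t(B)
  }
  new_block_covariance(full, n, K)
}

new_block_covariance <- function(full, n, K) {
  structure(list(matrix = full, n_regions = n, n_outcomes = K),
            class = "block_covariance")
}

#' @export
print.block_covariance <- function(x, ...) {
  cat(sprintf("<block_covariance> %d outcomes x %d regions (%d x %d matrix)\n",
              x$n_outcomes, x$n_regions, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Extract a covariance block or entry
#'
#' @param bc A `block_covariance`.
#' @param k1,k2 Outcome indices.
#' @param i,j Region indices.
#' @return `cov_block()`: the N x N block `Cov(Y^(k1), Y^(k2))`;
#'   `cov_entry()`: the scalar `Cov(Y_i^(k1), Y_j^(k2))`.
#' @export
cov_block <- function(bc, k1, k2) {
  stopifnot(inherits(bc, "block_covariance"))
  n <- bc$n_regions
  bc$matrix[(k1 - 1L) * n + seq_len(n), (k2 - 1L) * n + seq_len(n), drop = FALSE]
}

#' @rdname cov_block
#' @export
cov_entry <- function(bc, k1, k2, i, j) {
  stopifnot(inherits(bc, "block_covariance"))
  n <- bc$n_regions
  bc$matrix[(k1 - 1L) * n + i, (k2 - 1L) * n + j]
}

#' @export
tidy.block_covariance <- function(x, ...) {
  n <- x$n_regions; K <- x$n_outcomes
  grid <- tidyr::expand_grid(outcome_row = seq_len(K), region_row = seq_len(n),
                             outcome_col = seq_len(K), region_col = seq_len(n))
  grid$value <- as.vector(t(x$matrix))  # row-major walk matches expand_grid order
  dplyr::select(grid, "outcome_row", "outcome_col", "region_row", "region_col",
                "value")
}

#' Write a block covariance to a flat CSV
#'
#' One row per entry with columns `outcome_row, outcome_col, region_row,
#' region_col, value`.
#'
#' @param bc A `block_covariance`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_block_csv <- function(bc, path) {
  utils::write.csv(tidy.block_covariance(bc), path, row.names = FALSE)
  invisible(path)
}

#' Monte-Carlo oracle for the marginal covariance
#'
#' Brute-force check of the closed-form covariance: repeatedly draws
#' \eqn{F \sim N(0, \Sigma^F)}, loadings from their Gaussian model
#' (reference loading fixed at 1) and independent errors, forms
#' \eqn{Y_i^{(k)} = \gamma_i^{(k)} f_i + \varepsilon_i^{(k)}}, and returns
#' the empirical cross-covariance.
#'
#' @param spec A [covariance_spec()] in either form.
#' @param n_draws Number of Monte-Carlo replicates (at least 1e4).
#' @param seed RNG seed (draws are reproducible for a fixed seed).
#' @param se If `TRUE`, attach the entrywise Monte-Carlo standard errors as
#'   attribute `"se"` (matrix of the same shape).
#' @return A `block_covariance` of empirical covariances.
#' @export
mc_cov_oracle <- function(spec, n_draws, seed = 1L, se = FALSE) {
  stopifnot(inherits(spec, "covariance_spec"))
  n_draws <- as.integer(n_draws)
  if (n_draws < 1e4) abort("`n_draws` must be at least 10^4.")
  n <- spec$n_regions; K <- spec$n_outcomes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  Fs <- matrix(rnorm(n_draws * n), n_draws, n) %*% mat_sqrt(spec$Sigma_F)
  Y <- matrix(0, n_draws, n * K)
  for (k in seq_len(K)) {
    if (k == 1L) {
      G <- matrix(1, n_draws, n)
    } else if (spec$form == "varying") {
      G <- matrix(rnorm(n_draws * n), n_draws, n) %*% mat_sqrt(spec$loading_covs[[k]])
      G <- sweep(G, 2L, spec$loading_means[[k]], "+")
    } else {
      G <- matrix(rnorm(n_draws, spec$loading_means[k], sqrt(spec$tau_g2[k])),
                  n_draws, n)
    }
    eps <- matrix(rnorm(n_draws * n, 0, sqrt(spec$error_vars[k])), n_draws, n)
    Y[, (k - 1L) * n + seq_len(n)] <- G * Fs + eps
  }
  out <- new_block_covariance(stats::cov(Y), n, K)
  if (se) {
    Yc <- sweep(Y, 2L, colMeans(Y))
    m <- ncol(Y)
    sem <- matrix(0, m, m)
    for (a in seq_len(m)) for (b in a:m) {
      p <- Yc[, a] * Yc[, b]
      sem[a, b] <- sem[b, a] <- sd(p) / sqrt(n_draws)
    }
    attr(out, "se") <- sem
  }
  out
}

mat_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
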