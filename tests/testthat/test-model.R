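test_that("Poisson log-likelihood matches closed-form pmf arithmetic", {
  # y = 3, m = 2: -2 + 3 log 2 - log 6
  expect_equal(obs_loglik(3, offset = 1, loglambda = log(2)),
               -2 + 3 * log(2) - log(6))
  # y = 0, m = 5
  expect_equal(obs_loglik(0, offset = 1, loglambda = log(5)), -5)
  # offset folds into the mean: m = E * exp(loglambda)
  expect_equal(obs_loglik(4, offset = 10, loglambda = log(0.2)),
               dpois(4, 2, log = TRUE))
})

test_that("interval likelihood equals direct pmf summation", {
  # [1,5] at m = 1: e^-1 (1 + 1/2 + 1/6 + 1/24 + 1/120)
  expect_equal(obs_loglik(NA, 1, 0, cens_low = 1, cens_high = 5),
               log(exp(-1) * (1 + 1 / 2 + 1 / 6 + 1 / 24 + 1 / 120)))
  # identity against naive summation for 100 random means
  set.seed(4)
  m <- exp(runif(100, log(0.05), log(50)))
  got <- obs_loglik(rep(NA, 100), offset = m, loglambda = 0,
                    cens_low = 1, cens_high = 5)
  naive <- log(vapply(m, function(mm) sum(dpois(1:5, mm)), 0))
  expect_equal(got, naive, tolerance = 1e-13)
})

test_that("interval likelihood is monotone in the interval and handles [0, Inf)", {
  m <- 3.7
  narrow <- obs_loglik(NA, m, 0, cens_low = 2, cens_high = 4)
  wide <- obs_loglik(NA, m, 0, cens_low = 1, cens_high = 6)
  expect_gt(wide, narrow)
  expect_equal(obs_loglik(NA, m, 0, cens_low = 0, cens_high = Inf), 0)
  # open-above interval via survival function
  expect_equal(obs_loglik(NA, m, 0, cens_low = 2, cens_high = Inf),
               ppois(1, m, lower.tail = FALSE, log.p = TRUE))
})

test_that("likelihood rejects invalid cells", {
  expect_error(obs_loglik(-1, 1, 0), "negative")
  expect_error(obs_loglik(NA, 1, 0, cens_low = 5, cens_high = 1), "a > b")
  expect_error(obs_loglik(2, -1, 0), "positive")
  expect_error(obs_loglik(NA, 1, 0), "bounds")
})

test_that("log_posterior equals the independently coded sum of its parts", {
  g <- lattice_graph(2, 2)
  cfg <- sim_config(g, n_years = 3, n_outcomes = 2,
                    mu = c(0, 0.3, 0.5), censor_outcome = 2,
                    censor_bounds = c(1, 5), baseline_rates = c(2e-3, 2e-4))
  sim <- simulate_dataset(cfg, seed = 8)
  data <- observation_data(sim$observations, g)
  priors <- prior_spec()

  set.seed(9)
  n <- 4; J <- 3; K <- 2
  state <- list(f = matrix(rnorm(n * J), n, J),
                gamma = cbind(1, rnorm(n, 1, 0.4)),
                loglambda = array(rnorm(n * J * K, 0, 0.5), c(n, J, K)),
                sigma2 = c(0.2, 0.3), tau_f2 = 0.4, tau_g2 = 0.25,
                mu = c(0.1, 0.2, 0.3), eta = 0.4)

  # independent recomputation, term by term, with base R only
  lp <- 0
  for (k in 1:K) for (j in 1:J) for (i in 1:n) {
    y <- data$counts[i, j, k]; E <- data$offsets[i, j, k]
    m <- E * exp(state$loglambda[i, j, k])
    lp <- lp + if (data$status[i, j, k] == 2L) {
      log(sum(dpois(1:5, m)))
    } else if (data$status[i, j, k] == 1L) {
      dpois(y, m, log = TRUE)
    } else 0
    lp <- lp + dnorm(state$loglambda[i, j, k],
                     state$gamma[i, k] * state$f[i, j],
                     sqrt(state$sigma2[k]), log = TRUE)
  }
  pair_ss <- function(d) sum((d[g$edges[, 1]] - d[g$edges[, 2]])^2)
  rank <- 4 - 1
  icar <- function(d, t2) -rank / 2 * log(t2) - pair_ss(d) / (2 * t2)
  lp <- lp + icar(state$f[, 1] - state$mu[1], state$tau_f2)
  for (j in 2:J) {
    mu_t <- state$mu[j] + state$eta * (state$f[, j - 1] - state$mu[j - 1])
    lp <- lp + icar(state$f[, j] - mu_t, state$tau_f2)
  }
  lp <- lp + icar(state$gamma[, 2] - 1, state$tau_g2)
  ig <- function(v) 0.5 * log(0.5) - lgamma(0.5) - 1.5 * log(v) - 0.5 / v
  lp <- lp + sum(ig(state$sigma2)) + ig(state$tau_f2) + ig(state$tau_g2)
  lp <- lp - log(2)  # uniform(-1, 1) eta prior

  expect_equal(log_posterior(state, data, priors, g), lp)
})

test_that("log_posterior responds to its layers as expected", {
  g <- lattice_graph(2, 2)
  cfg <- sim_config(g, n_years = 2, n_outcomes = 2)
  sim <- simulate_dataset(cfg, seed = 2)
  data <- observation_data(sim$observations, g)
  priors <- prior_spec()
  state <- list(f = matrix(0.2, 4, 2), gamma = cbind(1, rep(1, 4)),
                loglambda = array(0.2, c(4, 2, 2)),
                sigma2 = c(0.1, 0.1), tau_f2 = 0.3, tau_g2 = 0.3,
                mu = c(0, 0), eta = 0.2)
  base <- log_posterior(state, data, priors, g)
  expect_true(is.finite(base))

  # widening one epsilon residual strictly decreases the error layer
  worse <- state
  worse$loglambda[1, 1, 1] <- worse$loglambda[1, 1, 1] + 2
  delta_obs <- sum(obs_loglik(data$counts[1, 1, 1], data$offsets[1, 1, 1],
                              worse$loglambda[1, 1, 1])) -
    sum(obs_loglik(data$counts[1, 1, 1], data$offsets[1, 1, 1],
                   state$loglambda[1, 1, 1]))
  expect_lt(log_posterior(worse, data, priors, g) - base - delta_obs, 0)

  # out-of-support states have -Inf posterior
  bad <- state; bad$eta <- 1.5
  expect_identical(log_posterior(bad, data, priors, g), -Inf)
  bad <- state; bad$sigma2 <- c(-0.1, 0.1)
  expect_identical(log_posterior(bad, data, priors, g), -Inf)

  # reference column must stay pinned
  bad <- state; bad$gamma[2, 1] <- 1.01
  expect_error(log_posterior(bad, data, priors, g), "reference")
})

test_that("gamma-precision prior option changes only the variance layer", {
  g <- lattice_graph(2, 2)
  cfg <- sim_config(g, n_years = 2, n_outcomes = 2)
  sim <- simulate_dataset(cfg, seed = 3)
  data <- observation_data(sim$observations, g)
  state <- list(f = matrix(0.1, 4, 2), gamma = cbind(1, rep(1.1, 4)),
                loglambda = array(0.1, c(4, 2, 2)),
                sigma2 = c(0.2, 0.4), tau_f2 = 0.3, tau_g2 = 0.3,
                mu = c(0, 0), eta = 0)
  d <- log_posterior(state, data, prior_spec("gamma_precision"), g) -
    log_posterior(state, data, prior_spec(), g)
  # difference equals the difference of the two variance-prior densities
  ig <- function(v) 0.5 * log(0.5) - lgamma(0.5) - 1.5 * log(v) - 0.5 / v
  gp <- function(v) dgamma(1 / v, 5, rate = 2, log = TRUE) - 2 * log(v)
  vs <- c(state$sigma2, state$tau_f2, state$tau_g2)
  expect_equal(d, sum(gp(vs)) - sum(ig(vs)))
})

test_that("observation_data validates schema and aligns indices", {
  g <- adjacency_graph(rbind(c(1, 2)), 2, labels = c("A", "B"))
  df <- tidyr::expand_grid(region = c("A", "B"), year = 2017:2018, outcome = "y1")
  df$count <- c(5, 7, 4, 6); df$censored <- 0L
  df$population <- 1000; df$offset <- 5
  od <- observation_data(df, g)
  expect_equal(od$counts["A" == g$labels, , 1], c(5, 7))
  expect_error(observation_data(dplyr::mutate(df, count = c(-1, 1, 1, 1)), g),
               "negative count")
  expect_error(observation_data(dplyr::mutate(df, region = c("Z", "B", "A", "B")), g),
               "unknown region")
  expect_error(observation_data(dplyr::select(df, -"count"), g), "missing required")
  expect_error(observation_data(df, g, ref_outcome = "nope"), "not among")
})
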