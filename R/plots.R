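#' Plot methods
#'
#' `autoplot.dsfm_fit()` draws the posterior mean factor trajectory of every
#' region over time with the cross-region median highlighted, the usual way
#' to read how the latent syndemic burden evolves and which regions deviate.
#' `autoplot.block_covariance()` draws the stacked covariance matrix as a
#' tile heatmap with outcome block boundaries.  `plot_trace()` draws
#' per-chain trace plots for a parameter group.
#'
#' @param object A `dsfm_fit` or `block_covariance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name dsfm-plots
NULL

#' @rdname dsfm-plots
#' @export
autoplot.dsfm_fit <- function(object, ...) {
  d <- object$data
  f_hat <- matrix(colMeans(draw_matrix(object, "f")), d$n_regions, d$n_years)
  df <- tibble::tibble(region = rep(d$regions, times = d$n_years),
                       year = rep(d$years, each = d$n_regions),
                       f = as.vector(f_hat))
  med <- dplyr::summarise(dplyr::group_by(df, .data$year),
                          f = stats::median(.data$f), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$f, group = .data$region)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(data = med, ggplot2::aes(group = 1), linewidth = 1.2,
                       colour = "firebrick") +
    ggplot2::labs(x = "year", y = "posterior mean factor",
                  title = "Latent factor trajectories (median in red)") +
    ggplot2::theme_minimal()
}

#' @rdname dsfm-plots
#' @export
autoplot.block_covariance <- function(object, ...) {
  df <- tidy.block_covariance(object)
  n <- object$n_regions
  df$row <- (df$outcome_row - 1L) * n + df$region_row
  df$col <- (df$outcome_col - 1L) * n + df$region_col
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::geom_hline(yintercept = n * seq_len(object$n_outcomes - 1L) + 0.5,
                        linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = n * seq_len(object$n_outcomes - 1L) + 0.5,
                        linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cov",
                  title = "Marginal covariance of the stacked outcome vector") +
    ggplot2::theme_minimal()
}

#' @rdname dsfm-plots
#' @param fit A `dsfm_fit`.
#' @param par Parameter group name (see [gelman_rubin()]).
#' @param max_series Cap on the number of scalar series drawn.
#' @export
plot_trace <- function(fit, par = "sigma2", max_series = 12L) {
  stopifnot(inherits(fit, "dsfm_fit"))
  mats <- draw_matrix(fit, par, pool = FALSE)
  keep <- seq_len(min(ncol(mats[[1L]]), max_series))
  df <- purrr::map_dfr(seq_along(mats), function(ch) {
    m <- mats[[ch]][, keep, drop = FALSE]
    tibble::tibble(chain = factor(ch),
                   iteration = rep(seq_len(nrow(m)), times = ncol(m)),
                   parameter = rep(colnames(m), each = nrow(m)),
                   value = as.vector(m))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "stored draw", y = NULL) +
    ggplot2::theme_minimal()
}
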