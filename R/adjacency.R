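#' Build an areal adjacency graph
#'
#' Constructs the symmetric neighbourhood structure \eqn{w_{il}} used by every
#' ICAR prior in the package.  Two regions are neighbours (\eqn{w_{il} = 1})
#' iff the unordered pair appears in `edges`; duplicated and reversed pairs
#' are collapsed.  Isolated regions are rejected because the ICAR full
#' conditional divides by the neighbour total \eqn{w_{i+}}.
#'
#' @param edges A two-column matrix or data frame of region index pairs
#'   (1-based), or a list of length-2 vectors.  Order within a pair is
#'   irrelevant.
#' @param n_regions Number of areal units.
#' @param labels Optional character vector of region labels (defaults to
#'   `"R1"..."Rn"`).
#'
#' @return An object of class `adjacency_graph`: a list with elements
#'   `n_regions`, `edges` (two-column integer matrix, `i < l`, one row per
#'   unordered pair), `degrees` (\eqn{w_{i+}}), `neighbors` (list of integer
#'   vectors), `labels`, `n_components` and `membership`.
#' @examples
#' g <- adjacency_graph(rbind(c(1, 2), c(2, 3)), n_regions = 3)
#' g$degrees  # 1 2 1
#' @export
adjacency_graph <- function(edges, n_regions, labels = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.list(edges) && !is.matrix(edges)) edges <- do.call(rbind, edges)
  if (!is.matrix(edges) || ncol(edges) != 2L || nrow(edges) < 1L) {
    abort("`edges` must be a non-empty two-column matrix of region index pairs.")
  }
  storage.mode(edges) <- "integer"
  n_regions <- as.integer(n_regions)
  if (is.na(n_regions) || n_regions < 2L) {
    abort("`n_regions` must be an integer >= 2.")
  }
  if (anyNA(edges) || any(edges < 1L) || any(edges > n_regions)) {
    abort("edge indices must lie in [1, n_regions].")
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- which(edges[, 1L] == edges[, 2L])[1L]
    abort(sprintf("self-loop at region %d (edge row %d): w_ii must be 0.",
                  edges[bad, 1L], bad))
  }
  # canonical order + dedup: w_il is binary, so multiplicity is ignored
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]

  degrees <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n_regions)
  if (any(degrees == 0L)) {
    abort(sprintf(
      "isolated region(s) %s: the ICAR conditional is undefined at w_i+ = 0.",
      paste(which(degrees == 0L), collapse = ", ")))
  }

  if (is.null(labels)) labels <- paste0("R", seq_len(n_regions))
  labels <- as.character(labels)
  if (length(labels) != n_regions || anyDuplicated(labels)) {
    abort("`labels` must be `n_regions` unique strings.")
  }

  neighbors <- vector("list", n_regions)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; l <- edges[r, 2L]
    neighbors[[i]] <- c(neighbors[[i]], l)
    neighbors[[l]] <- c(neighbors[[l]], i)
  }
  neighbors <- lapply(neighbors, sort)

  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, n_regions - igraph::vcount(ig)))
  comp <- igraph::components(ig)
  if (comp$no > 1L) {
    warn(sprintf("adjacency graph has %d connected components.", comp$no))
  }

  structure(
    list(n_regions = n_regions, edges = edges, degrees = as.integer(degrees),
         neighbors = neighbors, labels = labels,
         n_components = comp$no, membership = as.integer(comp$membership)),
    class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d regions, %d edges, %d component(s)\n",
              x$n_regions, nrow(x$edges), x$n_components))
  cat(sprintf("  degrees w_i+: min %d, median %g, max %d\n",
              min(x$degrees), stats::median(x$degrees), max(x$degrees)))
  invisible(x)
}

#' Regular lattice adjacency
#'
#' Generates a `rows` by `cols` grid graph under rook (shared edge) or queen
#' (shared edge or corner) contiguity.  Queen contiguity matches point-touch
#' county adjacency, where two areas are neighbours if their boundaries share
#' at least one point.
#'
#' @param rows,cols Grid dimensions; `rows * cols >= 2`.
#' @param rule `"queen"` (default) or `"rook"`.
#' @return An [adjacency_graph()] on `rows * cols` regions, labelled
#'   `"r<i>c<j>"` in row-major order.
#' @examples
#' lattice_graph(2, 2, "rook")$degrees   # all 2 (a 4-cycle)
#' lattice_graph(2, 2, "queen")$degrees  # all 3 (complete graph on 4)
#' @export
lattice_graph <- function(rows, cols, rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L || rows * cols < 2L) {
    abort("`rows * cols` must be at least 2.")
  }
  idx <- function(r, c) (r - 1L) * cols + c
  steps <- list(c(0L, 1L), c(1L, 0L))
  if (rule == "queen") steps <- c(steps, list(c(1L, 1L), c(1L, -1L)))
  out <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    for (s in steps) {
      r2 <- r + s[1L]; c2 <- c + s[2L]
      if (r2 >= 1L && r2 <= rows && c2 >= 1L && c2 <= cols) {
        out[[length(out) + 1L]] <- c(idx(r, c), idx(r2, c2))
      }
    }
  }
  labels <- as.vector(t(outer(seq_len(rows), seq_len(cols),
                              function(r, c) paste0("r", r, "c", c))))
  adjacency_graph(do.call(rbind, out), rows * cols, labels = labels)
}

#' ICAR full conditional of one region
#'
#' Mean and variance of the intrinsic CAR full conditional for region `i`:
#' the conditional mean is the region's prior mean plus the average deviation
#' of its neighbours from theirs, and the conditional variance is
#' \eqn{\tau^2 / w_{i+}}.
#'
#' @param values Numeric vector of current field values (length `n_regions`).
#' @param prior_means Numeric vector of prior means, recycled if scalar.
#' @param tau2 ICAR variance parameter \eqn{\tau^2 > 0}.
#' @param graph An [adjacency_graph()].
#' @param i Region index.
#' @return A list with elements `mean` and `variance`.
#' @examples
#' g <- adjacency_graph(rbind(c(1, 2), c(2, 3)), 3)
#' icar_conditional(c(1.2, 0, 0.8), prior_means = 1, tau2 = 0.5, g, i = 2)
#' @export
icar_conditional <- function(values, prior_means, tau2, graph, i) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- graph$n_regions
  values <- as.numeric(values)
  prior_means <- rep_len(as.numeric(prior_means), n)
  if (length(values) != n) abort("`values` must have one entry per region.")
  if (!is.numeric(tau2) || length(tau2) != 1L || !is.finite(tau2) || tau2 <= 0) {
    abort("`tau2` must be a positive scalar.")
  }
  i <- as.integer(i)
  if (i < 1L || i > n) abort("region index out of range.")
  nb <- graph$neighbors[[i]]
  w <- graph$degrees[i]
  list(mean = prior_means[i] + mean(values[nb] - prior_means[nb]),
       variance = tau2 / w)
}

#' ICAR joint log density (pairwise-difference form)
#'
#' Unnormalised log density of the intrinsic CAR field whose full
#' conditionals are [icar_conditional()]:
#' \deqn{-\frac{N - c}{2}\log\tau^2 -
#'       \frac{1}{2\tau^2}\sum_{i<l} w_{il}(d_i - d_l)^2,}
#' with \eqn{d = } `values - prior_means` and \eqn{c} the number of connected
#' components (the standard rank correction for the improper ICAR).  Additive
#' constants are dropped.
#'
#' @inheritParams icar_conditional
#' @return A single numeric value.
#' @export
log_prior_icar <- function(values, prior_means, tau2, graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- graph$n_regions
  values <- as.numeric(values)
  prior_means <- rep_len(as.numeric(prior_means), n)
  if (length(values) != n) abort("`values` must have one entry per region.")
  if (!is.numeric(tau2) || length(tau2) != 1L || !is.finite(tau2) || tau2 <= 0) {
    abort("`tau2` must be a positive scalar.")
  }
  d <- values - prior_means
  ss <- sum((d[graph$edges[, 1L]] - d[graph$edges[, 2L]])^2)
  rank <- n - graph$n_components
  -rank / 2 * log(tau2) - ss / (2 * tau2)
}

#' ICAR marginal covariance (rank-corrected pseudo-inverse)
#'
#' Covariance of the sum-to-zero representative of the intrinsic CAR field:
#' \eqn{\tau^2 Q^{+}} with \eqn{Q = D - W} the ICAR precision (degree matrix
#' minus adjacency) and \eqn{Q^{+}} its Moore-Penrose pseudo-inverse.  Draws
#' from `N(0, tau2 * Q^+)` lie in the per-component sum-to-zero subspace.
#'
#' @inheritParams icar_conditional
#' @return An `n_regions` by `n_regions` symmetric PSD matrix.
#' @export
icar_covariance <- function(graph, tau2) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (tau2 <= 0) abort("`tau2` must be positive.")
  Q <- icar_precision(graph)
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  V <- e$vectors[, pos, drop = FALSE]
  tau2 * V %*% (t(V) / e$values[pos])
}

icar_precision <- function(graph) {
  n <- graph$n_regions
  Q <- diag(as.numeric(graph$degrees), n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges[r, 1L]; l <- graph$edges[r, 2L]
    Q[i, l] <- Q[i, l] - 1
    Q[l, i] <- Q[l, i] - 1
  }
  Q
}

# Draw m independent fields from the sum-to-zero ICAR N(0, tau2 * Q^+),
# returned as an n x m matrix.  Eigen-decomposition is cached by the caller
# where it matters.
icar_draw <- function(graph, tau2, m = 1L, eig = NULL) {
  if (is.null(eig)) eig <- icar_eigen(graph)
  z <- matrix(rnorm(ncol(eig$V) * m), ncol(eig$V), m)
  eig$V %*% (z / sqrt(eig$values)) * sqrt(tau2)
}

icar_eigen <- function(graph) {
  e <- eigen(icar_precision(graph), symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  list(V = e$vectors[, pos, drop = FALSE], values = e$values[pos])
}
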