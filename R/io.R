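#' Read and write long-format observation tables
#'
#' The observation CSV schema has columns `region, year, outcome, count,
#' censored, cens_low, cens_high, population, offset`; censored rows carry
#' interval bounds and an empty count.  `write_observations()` accepts the
#' `observations` tibble of a [simulate_dataset()] result or any data frame
#' in the schema.
#'
#' @param x A data frame in the observation schema (or a `sim_dataset`).
#' @param path File path.
#' @return `read_observations()`: a tibble; `write_observations()`: `path`
#'   invisibly.
#' @export
write_observations <- function(x, path) {
  if (inherits(x, "sim_dataset")) x <- x$observations
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(region = "character"))
  tibble::as_tibble(df)
}

#' Read and write adjacency as an edge-list CSV
#'
#' Two label columns (`from, to`), one row per unordered neighbour pair.
#' Region order (hence index order) is taken from `labels` if given,
#' otherwise from first appearance in the file.
#'
#' @param graph An [adjacency_graph()].
#' @param path File path.
#' @param labels Optional full label vector fixing the region order (needed
#'   if some region appears only late in the file).
#' @return `read_adjacency_csv()`: an [adjacency_graph()];
#'   `write_adjacency_csv()`: `path` invisibly.
#' @export
write_adjacency_csv <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  utils::write.csv(
    data.frame(from = graph$labels[graph$edges[, 1L]],
               to = graph$labels[graph$edges[, 2L]]),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_csv
#' @export
read_adjacency_csv <- function(path, labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) abort("edge-list CSV needs two label columns.")
  if (is.null(labels)) labels <- unique(c(rbind(df[[1L]], df[[2L]])))
  edges <- cbind(match(df[[1L]], labels), match(df[[2L]], labels))
  if (anyNA(edges)) abort("edge label not in `labels`.")
  adjacency_graph(edges, length(labels), labels = labels)
}

#' Read and write GAL neighbour files
#'
#' Plain-text spatial weights in GAL format: a header line with the number
#' of regions, then for each region a line `label degree` followed by a
#' line listing its neighbours' labels.
#'
#' @param graph An [adjacency_graph()].
#' @param path File path.
#' @return `read_gal()`: an [adjacency_graph()]; `write_gal()`: `path`
#'   invisibly.
#' @export
write_gal <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  lines <- character(1L + 2L * graph$n_regions)
  lines[1L] <- as.character(graph$n_regions)
  for (i in seq_len(graph$n_regions)) {
    lines[2L * i] <- paste(graph$labels[i], graph$degrees[i])
    lines[2L * i + 1L] <- paste(graph$labels[graph$neighbors[[i]]], collapse = " ")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gal
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- if (length(head_tok) >= 2L && head_tok[1L] == "0") {
    as.integer(head_tok[2L])
  } else {
    as.integer(head_tok[1L])
  }
  if (is.na(n) || length(lines) < 1L + 2L * n) abort("malformed GAL file.")
  labels <- character(n)
  nb_lab <- vector("list", n)
  for (i in seq_len(n)) {
    hdr <- strsplit(trimws(lines[2L * i]), "\\s+")[[1L]]
    labels[i] <- hdr[1L]
    deg <- as.integer(hdr[2L])
    nb_lab[[i]] <- if (deg > 0L) strsplit(trimws(lines[2L * i + 1L]), "\\s+")[[1L]] else character()
    if (length(nb_lab[[i]]) != deg) abort(sprintf("GAL degree mismatch for '%s'.", labels[i]))
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, match(nb_lab[[i]], labels))
  }))
  if (anyNA(edges)) abort("GAL neighbour label not declared.")
  adjacency_graph(edges, n, labels = labels)
}

#' Load a dataset from disk
#'
#' Reads an observation CSV and an adjacency file (GAL if the extension is
#' `.gal`, otherwise edge-list CSV) and returns index-aligned structures.
#' Region order is taken from the adjacency file.
#'
#' @param data_path Observation CSV path.
#' @param adjacency_path GAL or edge-list CSV path.
#' @param ref_outcome Reference outcome label or index (default: first).
#' @return A list with elements `data` ([observation_data()]) and `graph`
#'   ([adjacency_graph()]).
#' @export
load_dataset <- function(data_path, adjacency_path, ref_outcome = NULL) {
  graph <- if (grepl("\\.gal$", adjacency_path, ignore.case = TRUE)) {
    read_gal(adjacency_path)
  } else {
    read_adjacency_csv(adjacency_path)
  }
  obs <- read_observations(data_path)
  list(data = observation_data(obs, graph, ref_outcome = ref_outcome),
       graph = graph)
}

#' Export a synthetic dataset to disk
#'
#' Writes the long-format observation CSV, the true-state CSV (for recovery
#' scoring: true factor, loadings and log rates per cell) and the adjacency
#' GAL file.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if missing).
#' @param stem File name stem, default `"synthetic"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, stem = "synthetic") {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(observations = file.path(dir, paste0(stem, "_observations.csv")),
             truth = file.path(dir, paste0(stem, "_truth.csv")),
             gal = file.path(dir, paste0(stem, ".gal")))
  write_observations(sim$observations, paths[["observations"]])
  cfg <- sim$config
  truth <- tidyr::expand_grid(outcome = seq_len(cfg$n_outcomes),
                              year = seq_len(cfg$n_years),
                              region = cfg$graph$labels)
  truth <- dplyr::select(truth, "region", "year", "outcome")
  truth$f <- rep(as.vector(sim$truth$f), times = cfg$n_outcomes)
  truth$gamma <- as.vector(sim$truth$gamma[, rep(seq_len(cfg$n_outcomes),
                                                 each = cfg$n_years)])
  truth$loglambda <- as.vector(sim$truth$loglambda)
  utils::write.csv(truth, paths[["truth"]], row.names = FALSE)
  write_gal(cfg$graph, paths[["gal"]])
  invisible(paths)
}
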