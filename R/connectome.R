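#' Construct a connectome object
#'
#' A connectome couples the Epileptor network: `weights` is the symmetric,
#' non-negative, zero-diagonal structural coupling matrix `W`, and
#' `tract_lengths` holds white-matter fiber lengths in millimetres from which
#' interaction delays are derived as `length / speed`. The default conduction
#' speed of 60 mm per model time unit corresponds to 3000 mm/s once a model
#' time unit is identified with 0.02 s.
#'
#' @param weights square numeric matrix of non-negative coupling weights.
#' @param tract_lengths square numeric matrix of fiber lengths in mm; defaults
#'   to all-zero (no delays).
#' @param ez_nodes integer vector of epileptogenic-zone node indices (1-based).
#' @param labels optional character vector of node names.
#' @param speed conduction speed in mm per model time unit.
#' @param time_unit_seconds wall-clock seconds per model time unit.
#' @param normalize if `TRUE`, apply [normalize_weights()] to `weights`.
#' @param symmetrize if `TRUE`, replace asymmetric inputs by `(M + t(M))/2`
#'   instead of rejecting them.
#' @param tol symmetry tolerance.
#' @return An object of class `connectome`.
#' @seealso [load_connectome()], [synth_connectome()], [synth_fixtures()]
#' @export
connectome <- function(weights, tract_lengths = NULL, ez_nodes = integer(),
                       labels = NULL, speed = 60, time_unit_seconds = 0.02,
                       normalize = FALSE, symmetrize = FALSE, tol = 1e-12) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be a square matrix")
  if (is.null(tract_lengths)) tract_lengths <- matrix(0, n, n)
  tract_lengths <- as.matrix(tract_lengths)
  if (!all(dim(tract_lengths) == c(n, n)))
    stop("tract_lengths must match the dimensions of weights (", n, "x", n, ")")
  if (!all(is.finite(weights)) || !all(is.finite(tract_lengths)))
    stop("weights and tract lengths must be finite")
  if (any(weights < 0)) stop("negative coupling weights are not allowed")
  if (any(tract_lengths < 0)) stop("negative tract lengths are not allowed")

  weights <- .check_symmetric(weights, "weights", symmetrize, tol)
  tract_lengths <- .check_symmetric(tract_lengths, "tract_lengths", symmetrize, tol)
  # diffusive coupling has no self-term; the Jacobian row sums must not
  # include a self-weight either
  diag(weights) <- 0

  ez_nodes <- as.integer(ez_nodes)
  if (anyDuplicated(ez_nodes)) stop("ez_nodes must be distinct")
  if (length(ez_nodes) && (min(ez_nodes) < 1 || max(ez_nodes) > n))
    stop("ez_nodes out of range 1..", n)
  if (!is.null(labels) && length(labels) != n)
    stop("labels must have one entry per node")
  if (speed <= 0) stop("speed must be positive")

  if (normalize) weights <- normalize_weights(weights)

  structure(list(n_nodes = n, weights = weights, tract_lengths = tract_lengths,
                 delays = compute_delays(tract_lengths, speed),
                 ez_nodes = ez_nodes, labels = labels, speed = speed,
                 time_unit_seconds = time_unit_seconds,
                 normalized = normalize || .is_normalized(weights)),
            class = "connectome")
}

.check_symmetric <- function(M, what, symmetrize, tol) {
  d <- max(abs(M - t(M)))
  if (d > tol) {
    if (symmetrize) return((M + t(M)) / 2)
    stop(what, " is asymmetric (max |M - t(M)| = ", format(d),
         "); pass symmetrize = TRUE to average with the transpose")
  }
  M
}

.is_normalized <- function(W) {
  m <- max(W)
  m == 0 || (m <= 1 + 1e-12 && abs(m - 1) < 1e-9)
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Connectome: %d nodes, %d edges (density %.3f)%s\n",
              x$n_nodes, nz, nz / choose(x$n_nodes, 2),
              if (x$normalized) ", weights normalized to [0,1]" else ""))
  cat(sprintf("  tract lengths: max %.1f mm; max delay %.3f time units (%.4f s)\n",
              max(x$tract_lengths), max(x$delays),
              max(x$delays) * x$time_unit_seconds))
  if (length(x$ez_nodes))
    cat("  EZ nodes:", paste(x$ez_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Load a connectome from plain-text matrix files
#'
#' Reads whitespace- or comma-delimited square numeric matrices (one file for
#' the coupling weights, optionally one for tract lengths in mm) and returns a
#' validated [connectome]. Weights are kept raw (pre-normalization); apply
#' [normalize_weights()] or pass `normalize = TRUE`.
#'
#' @param weights_path path to the weight-matrix text file.
#' @param lengths_path optional path to the tract-length matrix file (mm).
#' @param ez_nodes integer vector of EZ node indices (1-based).
#' @param ... further arguments passed to [connectome()] (e.g. `normalize`,
#'   `symmetrize`, `speed`).
#' @return A `connectome` object.
#' @export
load_connectome <- function(weights_path, lengths_path = NULL,
                            ez_nodes = integer(), ...) {
  W <- .read_matrix(weights_path)
  L <- if (!is.null(lengths_path)) .read_matrix(lengths_path) else NULL
  if (!is.null(L) && !all(dim(L) == dim(W)))
    stop("weight and length matrices have mismatched dimensions: ",
         paste(dim(W), collapse = "x"), " vs ", paste(dim(L), collapse = "x"))
  connectome(W, L, ez_nodes = ez_nodes, ...)
}

.read_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  M <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(M) <- NULL
  if (!is.numeric(M)) stop("non-numeric entries in ", path)
  if (nrow(M) != ncol(M))
    stop("matrix in ", path, " is not square (", nrow(M), "x", ncol(M), ")")
  M
}

#' Write a connectome back to text-matrix files
#'
#' Emits the same plain-text dialect [load_connectome()] reads, so that a
#' write/read round trip reproduces the matrices exactly.
#'
#' @param x a `connectome`.
#' @param weights_path,lengths_path output file paths (`lengths_path` may be
#'   `NULL` to skip lengths).
#' @return Invisibly, the input connectome.
#' @export
write_connectome <- function(x, weights_path, lengths_path = NULL) {
  stopifnot(inherits(x, "connectome"))
  .write_matrix(x$weights, weights_path)
  if (!is.null(lengths_path)) .write_matrix(x$tract_lengths, lengths_path)
  invisible(x)
}

.write_matrix <- function(M, path) {
  lines <- apply(M, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(lines, path)
}

#' Truncate and normalize coupling weights
#'
#' Attenuates tractography artifacts by clipping all entries above the given
#' percentile (computed over all `n^2` entries, zero diagonal included, with
#' the usual linear-interpolation quantile convention) to that threshold, and
#' then divides by the threshold so that all weights lie in `[0, 1]`.
#'
#' @param weights non-negative square matrix.
#' @param percentile clipping percentile (default 95).
#' @return Matrix of the same shape with entries in `[0, 1]` and maximum 1.
#' @examples
#' W <- matrix(c(0, 2, 2, 0), 2)
#' normalize_weights(W)  # constant off-diagonal -> all ones off the diagonal
#' @export
normalize_weights <- function(weights, percentile = 95) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("weights must be non-negative")
  t <- stats::quantile(as.vector(weights), percentile / 100, names = FALSE,
                       type = 7)
  if (t <= 0)
    stop("degenerate input: the ", percentile,
         "th percentile of the weights is not positive")
  pmin(weights, t) / t
}

#' Interaction delays from tract lengths
#'
#' Converts fiber lengths to interaction delays in model time units,
#' `delay = length / speed`. With the default speed of 60 mm per time unit
#' and 0.02 s per time unit, the longest observed fiber length of 200 mm
#' yields a delay of 10/3 time units, i.e. about 0.067 s.
#'
#' @param tract_lengths non-negative matrix (or vector) of lengths in mm.
#' @param speed conduction speed in mm per model time unit (default 60).
#' @return Delays in model time units, same shape as `tract_lengths`.
#' @export
compute_delays <- function(tract_lengths, speed = 60) {
  if (speed <= 0) stop("speed must be positive")
  if (any(tract_lengths < 0)) stop("tract lengths must be non-negative")
  tract_lengths / speed
}

#' Graph-theoretic node metrics relative to an EZ node
#'
#' Computes, for every node, the shortest path length to the given EZ node,
#' betweenness centrality, (weighted) local clustering coefficient and
#' eigenvector centrality of the weighted graph. Shortest paths use an edge
#' cost derived from the coupling weight: stronger links are shorter. The
#' transform is configurable: `"inverse"` uses `1/W`, `"neglog"` uses
#' `-log(W)` (requires normalized weights `<= 1`), `"hops"` ignores weights.
#'
#' @param x a `connectome`.
#' @param ez EZ node index (1-based); defaults to the first entry of
#'   `x$ez_nodes`.
#' @param cost edge-cost transform for shortest paths.
#' @return A `data.frame` with one row per node: `node`,
#'   `shortest_path_length_to_ez`, `betweenness_centrality`,
#'   `clustering_coefficient`, `eigenvector_centrality`. Disconnected nodes
#'   have infinite path length.
#' @export
graph_metrics <- function(x, ez = NULL,
                          cost = c("inverse", "neglog", "hops")) {
  stopifnot(inherits(x, "connectome"))
  cost <- match.arg(cost)
  if (is.null(ez)) {
    if (!length(x$ez_nodes)) stop("no EZ node given and connectome has none")
    ez <- x$ez_nodes[1]
  }
  if (ez < 1 || ez > x$n_nodes) stop("ez index out of range 1..", x$n_nodes)

  g <- igraph::graph_from_adjacency_matrix(x$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wts <- igraph::E(g)$weight
  costs <- switch(cost,
                  inverse = 1 / wts,
                  neglog = {
                    if (any(wts > 1 + 1e-12))
                      stop("neglog cost requires normalized weights <= 1")
                    -log(pmin(wts, 1))
                  },
                  hops = rep(1, length(wts)))
  d <- as.vector(igraph::distances(g, v = ez, weights = costs))
  btw <- igraph::betweenness(g, weights = costs, normalized = FALSE)
  cc <- igraph::transitivity(g, type = "barrat", isolates = "zero")
  evc <- igraph::eigen_centrality(g, weights = wts)$vector
  data.frame(node = seq_len(x$n_nodes),
             shortest_path_length_to_ez = d,
             betweenness_centrality = as.vector(btw),
             clustering_coefficient = as.vector(cc),
             eigenvector_centrality = as.vector(evc))
}
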