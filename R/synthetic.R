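# Synthetic connectomes emulating the statistical structure of
# tractography-derived patient matrices: symmetric heavy-tailed weights
# normalized after 95th-percentile truncation, and tract lengths taken from
# the geometry of random node positions so that delay structure correlates
# with topology.

#' Generate a synthetic tractography-like connectome
#'
#' Places `n_nodes` uniformly in a cubic volume, connects a random fraction
#' `density` of node pairs with log-normal (heavy-tailed) weights, takes
#' tract lengths as the Euclidean inter-node distances (capped at
#' `length_cap`), and passes the weights through [normalize_weights()]. The
#' result is symmetric, zero-diagonal, with weights in `[0, 1]` — the same
#' invariants as a preprocessed patient connectome. Fully reproducible from
#' `seed`.
#'
#' @param n_nodes number of nodes.
#' @param density fraction of off-diagonal pairs connected, in `(0, 1]`.
#' @param meanlog,sdlog log-normal parameters of the raw (pre-normalization)
#'   weights; the defaults give strongly right-skewed weights as seen in
#'   streamline counts.
#' @param box_mm side of the cubic placement volume in mm.
#' @param length_cap maximum tract length in mm.
#' @param ez_nodes EZ node indices (default: node 1).
#' @param seed RNG seed (`NULL`: leave the RNG alone).
#' @param percentile truncation percentile for [normalize_weights()].
#' @return A normalized [connectome]. If the generated graph is
#'   disconnected, a warning reports the number of components (disconnected
#'   fixtures remain usable).
#' @export
synth_connectome <- function(n_nodes, density = 0.3, meanlog = 0, sdlog = 1,
                             box_mm = 150, length_cap = 200,
                             ez_nodes = 1L, seed = NULL, percentile = 95) {
  stopifnot(n_nodes >= 2, density > 0, density <= 1)
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(stats::runif(3 * n_nodes, 0, box_mm), ncol = 3)
  L <- pmin(as.matrix(stats::dist(pos)), length_cap)
  dimnames(L) <- NULL

  np <- n_nodes * (n_nodes - 1) / 2
  on <- stats::runif(np) < density
  wv <- numeric(np)
  wv[on] <- stats::rlnorm(sum(on), meanlog, sdlog)
  W <- matrix(0, n_nodes, n_nodes)
  W[upper.tri(W)] <- wv
  W <- W + t(W)
  if (all(W == 0)) stop("density too low: generated graph has no edges")
  if (stats::quantile(as.vector(W), percentile / 100, names = FALSE) > 0) {
    W <- normalize_weights(W, percentile)
  } else {
    # graph sparser than (100 - percentile)%: the truncation percentile is
    # zero, so scale by the maximum instead (no truncation)
    W <- W / max(W)
  }

  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  nc <- igraph::count_components(g)
  if (nc > 1)
    warning("generated graph is disconnected (", nc, " components)")

  out <- connectome(W, L, ez_nodes = ez_nodes)
  out$positions <- pos
  out
}

#' Small deterministic network fixtures
#'
#' Canonical test topologies for the seizure-spread machinery:
#' \describe{
#'   \item{`two_node`}{a single symmetric link; EZ at node 1. The smallest
#'     network on which all three phases (no seizure, no spread, spread)
#'     appear as `(x0, w)` vary.}
#'   \item{`chain`}{nearest-neighbour links of equal weight; EZ at one end,
#'     so recruitment should propagate down the chain.}
#'   \item{`star_hub`}{EZ at the hub, leaves attached with strictly
#'     decreasing weights — the predicted recruitment order is the leaf
#'     weight order, which makes it the canonical rank-prediction fixture.}
#' }
#' Tract lengths are uniform at `length_mm` for every edge.
#'
#' @param kind fixture topology.
#' @param n number of nodes (`>= 2`; `two_node` forces `n = 2`).
#' @param weight edge weight for `two_node`/`chain`; for `star_hub`, the
#'   strongest leaf weight (leaf `k` of `n - 1` gets
#'   `weight * (1 - (k - 1) / (n - 1))`).
#' @param length_mm tract length assigned to every edge.
#' @param seed unused for these deterministic fixtures; accepted for
#'   interface symmetry.
#' @return A [connectome] with `ez_nodes = 1`.
#' @export
synth_fixtures <- function(kind = c("two_node", "chain", "star_hub"), n = 2,
                           weight = 1, length_mm = 60, seed = NULL) {
  kind <- match.arg(kind)
  if (n < 2) stop("need at least 2 nodes")
  if (kind == "two_node") n <- 2L
  W <- matrix(0, n, n)
  L <- matrix(0, n, n)
  if (kind == "two_node") {
    W[1, 2] <- W[2, 1] <- weight
  } else if (kind == "chain") {
    for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- weight
  } else { # star_hub: EZ hub at node 1, graded leaves
    lw <- weight * (1 - (seq_len(n - 1) - 1) / (n - 1))
    W[1, 2:n] <- W[2:n, 1] <- lw
  }
  L[W > 0] <- length_mm
  connectome(W, L, ez_nodes = 1L)
}
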