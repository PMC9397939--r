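#' Piecewise Epileptor nonlinearities
#'
#' `f1` couples the fast subsystem into the spike-wave subsystem: for
#' `x1 < 0` it is the cubic `x1^3 - 3 x1^2`; on the `x1 >= 0` branch it reads
#' `(x2 - 0.6 (z - 4)^2) x1`, so the permittivity variable `z` enters only
#' there. `f2` is a rectified linear drive, `0` for `x2 < -0.25` and
#' `6 (x2 + 0.25)` otherwise. Both are continuous at the switch points; the
#' switch points themselves take the `>=` branch.
#'
#' @param x1,x2,z state variables (vectorized).
#' @return Numeric vector.
#' @keywords internal
f1_epileptor <- function(x1, x2, z) {
  ifelse(x1 < 0, x1^3 - 3 * x1^2, (x2 - 0.6 * (z - 4)^2) * x1)
}

#' @rdname f1_epileptor
#' @keywords internal
f2_epileptor <- function(x2) {
  ifelse(x2 < -0.25, 0, 6 * (x2 + 0.25))
}

.state_cols_full <- c("x1", "y1", "z", "x2", "y2", "g")
.state_cols_reduced <- c("x", "z")

.as_state <- function(state, nv) {
  state <- as.matrix(state)
  if (is.null(dim(state)) || ncol(state) != nv)
    state <- matrix(state, ncol = nv)
  if (!all(is.finite(state))) stop("non-finite state")
  state
}

.coupling_term <- function(x1, W, delayed_x1 = NULL,
                           ext_w = NULL, ext_x = NULL) {
  n <- length(x1)
  if (is.null(delayed_x1)) {
    # zero delays: sum_j W_ij (x1_j - x1_i)
    cpl <- as.vector(W %*% x1) - rowSums(W) * x1
  } else {
    cpl <- rowSums(W * (delayed_x1 - matrix(x1, n, n))) # delayed_x1[i,j] = x1_j(t - tau_ij)
  }
  if (!is.null(ext_w)) cpl <- cpl + ext_w * (ext_x - x1)
  cpl
}

#' Deterministic drift of the full 6D-per-node Epileptor network
#'
#' Evaluates the deterministic right-hand side of the full Epileptor network:
#' per node the six variables `(x1, y1, z, x2, y2, g)` with the slow
#' permittivity variable `z` mediating diffusive coupling
#' `-w * sum_j W_ij [x1_j(t - tau_ij) - x1_i]`, and the low-pass filtered
#' drive `g` integrated as `g' = x1 - gamma * g`. Stochastic inputs are the
#' simulator's responsibility; this is the drift only.
#'
#' @param state numeric `n x 6` matrix, columns `(x1, y1, z, x2, y2, g)`.
#' @param params an [epileptor_params] object.
#' @param connectome a [connectome] (or `NULL` for isolated nodes).
#' @param x0 per-node excitability vector; defaults to the homogeneous
#'   surround value in `params`.
#' @param delayed_x1 optional `n x n` matrix supplying `x1_j(t - tau_ij)` in
#'   entry `(i, j)`; when `NULL` the current `x1` is used (zero delays).
#' @param ext_w,ext_x optional constant external drive: `ext_w` is a
#'   per-node weight vector and `ext_x` the frozen source level, adding
#'   `ext_w_i (ext_x - x1_i)` to each node's coupling sum. Used when an EZ
#'   node is replaced by its mean ictal drive.
#' @return `n x 6` matrix of time derivatives.
#' @export
drift_full <- function(state, params, connectome = NULL, x0 = NULL,
                       delayed_x1 = NULL, ext_w = NULL, ext_x = NULL) {
  state <- .as_state(state, 6)
  n <- nrow(state)
  x1 <- state[, 1]; y1 <- state[, 2]; z <- state[, 3]
  x2 <- state[, 4]; y2 <- state[, 5]; g <- state[, 6]
  if (is.null(x0)) x0 <- rep(params$x0_surround, n)
  W <- if (is.null(connectome)) matrix(0, n, n) else connectome$weights
  cpl <- .coupling_term(x1, W, delayed_x1, ext_w, ext_x)
  cbind(y1 - f1_epileptor(x1, x2, z) - z + params$I1,
        (1 - 5 * x1^2 - y1) / params$tau1,
        (4 * (x1 - x0) - z - params$w * cpl) / params$tau0,
        -y2 + x2 - x2^3 + params$I2 + 0.002 * g - 0.3 * (z - 3.5),
        (-y2 + f2_epileptor(x2)) / params$tau2,
        x1 - params$gamma * g)
}

#' Deterministic drift of the 2D reduced Epileptor network
#'
#' The two-variable reduction keeps one fast variable `x` per node, with
#' `x' = -x^3 - 2 x^2 + 1 - z + I1`, and the slow permittivity variable `z`
#' with the same diffusive coupling as the full model.
#'
#' @inheritParams drift_full
#' @param state numeric `n x 2` matrix, columns `(x, z)`.
#' @param delayed_x optional `n x n` matrix of delayed `x` values.
#' @return `n x 2` matrix of time derivatives.
#' @export
drift_reduced <- function(state, params, connectome = NULL, x0 = NULL,
                          delayed_x = NULL, ext_w = NULL, ext_x = NULL) {
  state <- .as_state(state, 2)
  n <- nrow(state)
  x <- state[, 1]; z <- state[, 2]
  if (is.null(x0)) x0 <- rep(params$x0_surround, n)
  W <- if (is.null(connectome)) matrix(0, n, n) else connectome$weights
  cpl <- .coupling_term(x, W, delayed_x, ext_w, ext_x)
  cbind(-x^3 - 2 * x^2 + 1 - z + params$I1,
        (4 * (x - x0) - z - params$w * cpl) / params$tau0)
}

#' Observable of the full Epileptor model
#'
#' The simulated field activity of a node is observed as the difference
#' `x2 - x1` between the slow and fast oscillatory variables.
#'
#' @param state an `n x 6` state matrix, or a `steps x (6 n)` stacked
#'   trajectory in block order `(x1, y1, z, x2, y2, g)`.
#' @param n_nodes number of nodes (required for stacked trajectories).
#' @return Per-node observable: a vector for a single state, a
#'   `steps x n` matrix for a stacked trajectory.
#' @export
observe <- function(state, n_nodes = NULL) {
  state <- as.matrix(state)
  if (is.null(n_nodes) && ncol(state) == 6) {
    return(state[, 4] - state[, 1])
  }
  if (is.null(n_nodes)) stop("n_nodes required for stacked trajectories")
  if (ncol(state) == 2 * n_nodes)
    stop("observable x2 - x1 is not defined for the reduced model")
  if (ncol(state) != 6 * n_nodes)
    stop("state has ", ncol(state), " columns; expected ", 6 * n_nodes)
  state[, 3 * n_nodes + seq_len(n_nodes), drop = FALSE] -
    state[, seq_len(n_nodes), drop = FALSE]
}
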