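#' Epileptor network model of focal seizure spread
#'
#' The main user-facing constructor: binds a structural [connectome] to the
#' Epileptor dynamics under given control parameters (surround excitability
#' `x0`, global coupling `w`, noise level `sigma`) and a choice of active
#' epileptogenic-zone node. The resulting object supports the usual
#' modelling verbs:
#' \itemize{
#'   \item [predict.epileptor_model()] — two-Jacobian linear-stability
#'     prediction of the spread phase and of the node-recruitment order;
#'   \item [simulate.epileptor_model()] — stochastic seizure realizations,
#'     coarse-grained to spread outcomes;
#'   \item [summary.epileptor_model()], [coef.epileptor_model()],
#'     [plot.epileptor_model()].
#' }
#'
#' @param connectome a normalized [connectome].
#' @param x0 homogeneous surround excitability (non-epileptic; the usual
#'   range is `[-2.3, -2.09]`).
#' @param w global coupling strength.
#' @param sigma additive noise standard deviation.
#' @param active_ez active EZ node (default: the connectome's first EZ node).
#' @param model `"full"` (6D per node) or `"reduced"` (2D per node).
#' @param protocol a [seizure_protocol] used by `simulate()`.
#' @param ... further arguments passed to [epileptor_params()].
#' @return An object of class `epileptor_model`.
#' @examples
#' \donttest{
#' net <- synth_fixtures("two_node")
#' m <- epileptor_model(net, x0 = -2.2, w = 0.3)
#' predict(m)$predicted_phase
#' }
#' @export
epileptor_model <- function(connectome, x0 = -2.2, w = 1, sigma = 0.05,
                            active_ez = NULL, model = c("full", "reduced"),
                            protocol = seizure_protocol(), ...) {
  model <- match.arg(model)
  stopifnot(inherits(connectome, "connectome"))
  if (is.null(active_ez)) {
    if (!length(connectome$ez_nodes)) stop("no active EZ node specified")
    active_ez <- connectome$ez_nodes[1]
  }
  params <- epileptor_params(x0_surround = x0, w = w, sigma = sigma, ...)
  structure(list(connectome = connectome, params = params,
                 active_ez = active_ez, model = model, protocol = protocol),
            class = "epileptor_model")
}

#' @export
print.epileptor_model <- function(x, ...) {
  cat(sprintf("Epileptor network model (%s): %d nodes, active EZ = %d\n",
              x$model, x$connectome$n_nodes, x$active_ez))
  cat(sprintf("  x0_surround = %g, w = %g, sigma = %g\n",
              x$params$x0_surround, x$params$w, x$params$sigma))
  invisible(x)
}

#' @export
coef.epileptor_model <- function(object, ...) {
  p <- object$params
  c(x0_surround = p$x0_surround, x0_ez = p$x0_ez, w = p$w, sigma = p$sigma,
    I1 = p$I1, I2 = p$I2, gamma = p$gamma,
    tau0 = p$tau0, tau1 = p$tau1, tau2 = p$tau2)
}

#' Stability-based prediction for an Epileptor network model
#'
#' Runs the two-Jacobian analysis (see [classify_phase()]) and returns the
#' stability report: leading eigenvalues, predicted phase and, when spread
#' is predicted, the eigenvector-based recruitment ranks.
#'
#' @param object an [epileptor_model].
#' @param ... passed to [classify_phase()].
#' @return A `stability_report`.
#' @export
predict.epileptor_model <- function(object, ...) {
  classify_phase(object$connectome, object$params, object$active_ez,
                 model = object$model, ...)
}

#' Simulate seizures from an Epileptor network model
#'
#' Runs `nsim` stochastic realizations of the seizure protocol and
#' coarse-grains each into a `spread_outcome`. Realization `k` uses seed
#' `seed + k - 1`, recorded in the outcome for exact replay.
#'
#' @param object an [epileptor_model].
#' @param nsim number of realizations.
#' @param seed base RNG seed.
#' @param record trajectory recording mode (see [seizure_protocol()]).
#' @param ... ignored.
#' @return A list of `spread_outcome` objects (invisible class
#'   `spread_outcome_list`), with the trajectories attached as attribute
#'   `"trajectory"` on each element when `record != "none"`.
#' @export
simulate.epileptor_model <- function(object, nsim = 1, seed = 1L,
                                     record = "none", ...) {
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    pr <- object$protocol
    pr$seed <- seed + k - 1L
    pr$active_ez <- object$active_ez
    pr$record <- record
    traj <- simulate_seizure_protocol(object$connectome, object$params, pr,
                                      object$model)
    sp <- extract_spread(traj)
    if (record != "none") attr(sp, "trajectory") <- traj
    out[[k]] <- sp
  }
  structure(out, class = "spread_outcome_list")
}

#' @export
print.spread_outcome_list <- function(x, ...) {
  sizes <- vapply(x, `[[`, 0L, "spread_size")
  cat(sprintf("%d seizure realization(s); spread sizes: %s\n", length(x),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Summarize an Epileptor network model
#'
#' Combines the stability prediction with (optionally) a small batch of
#' simulated realizations.
#'
#' @param object an [epileptor_model].
#' @param nsim realizations to simulate for the empirical side (0 to skip).
#' @param seed base seed for those realizations.
#' @param ... ignored.
#' @return A list with the `stability_report` and, if `nsim > 0`, the
#'   simulated spread sizes and empirical phase.
#' @export
summary.epileptor_model <- function(object, nsim = 0, seed = 1L, ...) {
  rep <- predict(object)
  out <- list(model = object, report = rep)
  if (nsim > 0) {
    sims <- simulate(object, nsim = nsim, seed = seed)
    sizes <- vapply(sims, `[[`, 0L, "spread_size")
    phases <- vapply(sims, `[[`, "", "phase")
    emp <- if (all(phases == "no_seizure")) "no_seizure"
           else if (any(phases == "spread")) "spread"
           else "no_spread"
    out$spread_sizes <- sizes
    out$empirical_phase <- emp
  }
  class(out) <- "summary.epileptor_model"
  out
}

#' @export
print.summary.epileptor_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  predicted phase: %s (lambda_R = %.2e, lambda_tilde_R = %.2e)\n",
              x$report$predicted_phase, x$report$lambda_R,
              x$report$lambda_tilde_R))
  if (!is.null(x$spread_sizes))
    cat(sprintf("  empirical phase over %d realization(s): %s; spread sizes %s\n",
                length(x$spread_sizes), x$empirical_phase,
                paste(x$spread_sizes, collapse = ", ")))
  invisible(x)
}

#' Plot a simulated seizure
#'
#' Simulates one realization (recording the observable) and draws the
#' per-node field observable `x2 - x1` as stacked traces, with recruitment
#' onsets marked.
#'
#' @param x an [epileptor_model].
#' @param seed RNG seed for the plotted realization.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the plotted `epileptor_trajectory`.
#' @export
plot.epileptor_model <- function(x, seed = 1L, ...) {
  pr <- x$protocol
  pr$seed <- seed; pr$active_ez <- x$active_ez
  pr$record <- "full"; pr$record_stride <- max(1L, pr$record_stride)
  traj <- simulate_seizure_protocol(x$connectome, x$params, pr, x$model)
  n <- traj$n_nodes
  if (x$model == "full") {
    obs <- observe(traj$states, n_nodes = n)
  } else {
    obs <- traj$states[, seq_len(n), drop = FALSE]
  }
  off <- 6 * (seq_len(n) - 1)
  tt <- traj$times * x$connectome$time_unit_seconds
  graphics::matplot(tt, sweep(obs, 2, off, "+"), type = "l", lty = 1,
                    xlab = "time [s]", ylab = "observable x2 - x1 (offset per node)",
                    ...)
  on <- traj$onset_step * traj$dt * x$connectome$time_unit_seconds
  ok <- !is.na(on)
  if (any(ok)) graphics::points(on[ok], off[ok], pch = 17)
  invisible(traj)
}
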