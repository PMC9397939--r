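#' Seizure protocol settings
#'
#' Bundles the integration and protocol controls for one simulated seizure:
#' an integration step of `dt = 0.05` model time units, a 20,000-step settle
#' period with all nodes at the surround excitability, activation of the
#' selected EZ node (`x0 -> x0_ez`), and up to `max_steps` further steps.
#' After a node's seizure terminates it is uncoupled from the network for the
#' rest of the run (postictal refractory state); if it is the active EZ node
#' its excitability also reverts to the surround value.
#'
#' @param dt integration step in model time units.
#' @param settle_steps steps integrated before EZ activation to let
#'   transients decay.
#' @param max_steps steps integrated after activation.
#' @param active_ez index of the EZ node switched to `x0_ez`; defaults to the
#'   connectome's first EZ node.
#' @param threshold optional list with `thr_on`/`thr_off` overriding the
#'   auto-calibrated seizure detection thresholds on the detection variable
#'   (`g` for the full model).
#' @param seed RNG seed for the stochastic run (`NULL`: leave the RNG alone).
#' @param record `"g"` records the detection variable, `"full"` all state
#'   variables, `"none"` only the event log (cheapest; used by sweeps).
#' @param record_stride recording stride in steps.
#' @param blowup_bound integration-divergence guard on `max |state|`.
#' @return An object of class `seizure_protocol`.
#' @export
seizure_protocol <- function(dt = 0.05, settle_steps = 20000L,
                             max_steps = 200000L, active_ez = NULL,
                             threshold = NULL, seed = NULL,
                             record = c("g", "full", "none"),
                             record_stride = 1L, blowup_bound = 1e6) {
  record <- match.arg(record)
  stopifnot(dt > 0, settle_steps >= 0, max_steps > 0, record_stride >= 1)
  structure(list(dt = dt, settle_steps = as.integer(settle_steps),
                 max_steps = as.integer(max_steps), active_ez = active_ez,
                 threshold = threshold, seed = seed, record = record,
                 record_stride = as.integer(record_stride),
                 blowup_bound = blowup_bound),
            class = "seizure_protocol")
}

#' Simulate one seizure on an Epileptor network
#'
#' Integrates the stochastic delay-coupled Epileptor network with the
#' predictor-corrector Heun scheme. Noise is additive (so the scheme is
#' unbiased for the Ito system), injected only into the fast-subsystem
#' equations (`x2`, `y2`; `x` for the reduced model) as i.i.d. Gaussian
#' increments with variance `sigma^2 * dt`. Delayed coupling values
#' `x1_j(t - tau_ij)` are served from a ring buffer with delays rounded to
#' the nearest integer step and history pre-filled with the initial state.
#'
#' The run starts exactly at the single-node stable fixed point of the
#' surround excitability, tiled across nodes. After `settle_steps`, the
#' active EZ node's excitability switches to `x0_ez`. Seizure onset/offset in
#' every node is detected online by threshold crossings of the smooth
#' low-pass variable `g` (hysteresis on the downward crossing); on offset the
#' node is uncoupled for the remainder of the run.
#'
#' Identical seeds yield bit-identical trajectories; `sigma = 0` runs consume
#' no random numbers.
#'
#' @param connectome a normalized [connectome].
#' @param params an [epileptor_params]; `params$w` and `params$sigma` are the
#'   control parameters of the run.
#' @param protocol a [seizure_protocol].
#' @param model `"full"` (6 variables per node) or `"reduced"` (2).
#' @return An object of class `epileptor_trajectory`: recorded `times`, the
#'   detection-variable matrix `g` (steps x nodes, if recorded), optionally
#'   the full `states` matrix (block order `x1, y1, z, x2, y2, g`), the event
#'   log (`onset_step`, `offset_step`, uncoupling), thresholds, and run
#'   metadata.
#' @export
simulate_seizure_protocol <- function(connectome, params,
                                      protocol = seizure_protocol(),
                                      model = c("full", "reduced")) {
  model <- match.arg(model)
  stopifnot(inherits(connectome, "connectome"),
            inherits(params, "epileptor_params"),
            inherits(protocol, "seizure_protocol"))
  if (!connectome$normalized)
    warning("connectome weights do not appear to be normalized to [0,1]")
  n <- connectome$n_nodes

  active_ez <- protocol$active_ez
  if (is.null(active_ez)) {
    if (!length(connectome$ez_nodes)) stop("no active EZ node specified")
    active_ez <- connectome$ez_nodes[1]
  }
  if (length(connectome$ez_nodes) && !(active_ez %in% connectome$ez_nodes))
    stop("active_ez (", active_ez, ") is not one of the connectome's EZ nodes")

  thr <- protocol$threshold
  if (is.null(thr)) thr <- calibrate_threshold(params, model, protocol$dt)

  fps <- find_fixed_points_single(params, params$x0_surround, model)
  stable <- Filter(function(f) f$stable, fps)
  if (!length(stable))
    stop("surround excitability ", params$x0_surround,
         " has no stable fixed point; the surround must be non-epileptic")
  state0 <- matrix(rep(stable[[1]]$state, each = n), nrow = n)

  delay_steps <- matrix(as.integer(round(connectome$delays / protocol$dt)),
                        n, n)
  n_steps <- protocol$settle_steps + protocol$max_steps
  record_mode <- switch(protocol$record, none = 0L, g = 1L, full = 2L)

  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  res <- .heun_sim(state0, if (model == "full") 1L else 2L,
                   as.integer(n_steps), protocol$dt,
                   rep(params$x0_surround, n), params$w, connectome$weights,
                   delay_steps, params$sigma, .par_list(params),
                   protocol$settle_steps, active_ez - 1L, params$x0_ez,
                   thr$thr_on, thr$thr_off,
                   record_mode, protocol$record_stride, protocol$blowup_bound)

  structure(list(times = if (record_mode > 0) res$times else numeric(),
                 g = if (record_mode > 0) res$det else NULL,
                 states = if (record_mode == 2) res$states else NULL,
                 final_state = res$final_state,
                 onset_step = as.integer(res$onset_step),
                 offset_step = as.integer(res$offset_step),
                 coupled_at_end = as.logical(res$coupled),
                 dt = protocol$dt, n_nodes = n, model = model,
                 activation_step = protocol$settle_steps,
                 n_steps = n_steps, threshold = thr,
                 active_ez = active_ez, params = params, protocol = protocol,
                 record_stride = protocol$record_stride,
                 seed = protocol$seed),
            class = "epileptor_trajectory")
}

#' @export
print.epileptor_trajectory <- function(x, ...) {
  cat(sprintf("Epileptor %s-model trajectory: %d nodes, %d steps (dt = %g)\n",
              x$model, x$n_nodes, x$n_steps, x$dt))
  cat(sprintf("  EZ node %d activated at step %d; %d node(s) seized\n",
              x$active_ez, x$activation_step, sum(!is.na(x$onset_step))))
  invisible(x)
}

#' Coarse-grain a trajectory into a seizure-spread outcome
#'
#' Assigns each node a binary recruitment state: a node is recruited when its
#' detection variable `g` crosses the onset threshold upward after EZ
#' activation; its seizure terminates at the subsequent downward crossing of
#' the (lower) hysteresis threshold. The collective order parameter is the
#' spread size, the number of recruited nodes including the active EZ, and
#' its phase label is `no_seizure` (nothing seized), `no_spread` (only the
#' active EZ seized) or `spread`.
#'
#' Crossing times are recomputed from the recorded `g` series when available
#' (to stride resolution), otherwise taken from the integrator's event log.
#'
#' @param trajectory an `epileptor_trajectory`.
#' @param threshold optional list with `thr_on`/`thr_off` overriding the
#'   trajectory's thresholds.
#' @param active_ez active EZ node; defaults to the trajectory's.
#' @return An object of class `spread_outcome`: `recruited` (0/1 per node),
#'   `onset_times`/`offset_times` in model time units since the start of the
#'   run (`NA` where undefined), `spread_size`, `spread_fraction`, `phase`,
#'   and the recruitment order.
#' @export
extract_spread <- function(trajectory, threshold = NULL, active_ez = NULL) {
  stopifnot(inherits(trajectory, "epileptor_trajectory"))
  thr <- if (is.null(threshold)) trajectory$threshold else threshold
  if (is.null(active_ez)) active_ez <- trajectory$active_ez
  n <- trajectory$n_nodes
  act <- trajectory$activation_step

  if (!is.null(trajectory$g)) {
    g <- trajectory$g
    stride <- trajectory$record_stride
    i_act <- act %/% stride + 1L # first recorded row at/after activation
    if (all(g[i_act, ] >= thr$thr_on))
      stop("calibration error: onset threshold (", format(thr$thr_on),
           ") lies below the resting detection variable of every node")
    onset <- offset <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      post <- g[(i_act + 1L):nrow(g), i]
      io <- which(post >= thr$thr_on)[1]
      if (!is.na(io)) {
        onset[i] <- (i_act + io - 1L) * stride # steps since run start
        ioff <- which(post[io:length(post)] <= thr$thr_off)[1]
        if (!is.na(ioff)) offset[i] <- (i_act + io + ioff - 2L) * stride
      }
    }
  } else {
    onset <- trajectory$onset_step
    offset <- trajectory$offset_step
  }

  recruited <- as.integer(!is.na(onset))
  spread_size <- sum(recruited)
  phase <- if (spread_size == 0) "no_seizure"
           else if (spread_size == 1 && recruited[active_ez] == 1) "no_spread"
           else "spread"
  onset_times <- onset * trajectory$dt
  ord <- order(onset_times, seq_len(n), na.last = NA)

  structure(list(recruited = recruited,
                 onset_times = onset_times,
                 offset_times = offset * trajectory$dt,
                 spread_size = spread_size,
                 spread_fraction = spread_size / n,
                 phase = phase,
                 recruitment_order = ord,
                 active_ez = active_ez, n_nodes = n,
                 seed = trajectory$seed),
            class = "spread_outcome")
}

#' @export
print.spread_outcome <- function(x, ...) {
  cat(sprintf("Seizure spread outcome: phase '%s', spread size %d/%d\n",
              x$phase, x$spread_size, x$n_nodes))
  if (length(x$recruitment_order))
    cat("  recruitment order:",
        paste(utils::head(x$recruitment_order, 12), collapse = ", "),
        if (length(x$recruitment_order) > 12) "..." else "", "\n")
  invisible(x)
}
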