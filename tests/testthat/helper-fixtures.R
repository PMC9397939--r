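# shared fixtures and small numerical helpers

default_params <- function(...) epileptor_params(...)

# central finite-difference Jacobian of a vector field
fd_jacobian <- function(fn, x, h = 1e-6) {
  m <- length(fn(x))
  J <- matrix(0, m, length(x))
  for (j in seq_along(x)) {
    e <- rep(0, length(x)); e[j] <- h
    J[, j] <- (fn(x + e) - fn(x - e)) / (2 * h)
  }
  J
}

# drift of an assembled stability-variant system as a function of the
# stacked state vector (used as the oracle for the analytic Jacobians)
variant_drift <- function(connectome, params, variant, active_ez, model,
                          x_bar = NULL) {
  n <- connectome$n_nodes
  if (variant == "with_ez") {
    x0 <- rep(params$x0_surround, n)
    x0[active_ez] <- params$x0_ez
    W <- connectome$weights
    ext_w <- NULL; ext_x <- NULL
  } else {
    keep <- setdiff(seq_len(n), active_ez)
    x0 <- rep(params$x0_surround, n - 1)
    W <- connectome$weights[keep, keep, drop = FALSE]
    ext_w <- connectome$weights[keep, active_ez]
    ext_x <- x_bar
  }
  conn <- list(weights = W)
  if (model == "full") {
    function(v) as.vector(drift_full(matrix(v, ncol = 6), params, conn,
                                     x0 = x0, ext_w = ext_w, ext_x = ext_x))
  } else {
    function(v) as.vector(drift_reduced(matrix(v, ncol = 2), params, conn,
                                        x0 = x0, ext_w = ext_w, ext_x = ext_x))
  }
}

# small synthetic nets used across test files (fixed seeds)
net3 <- function() synth_connectome(3, density = 1, seed = 11)
net10 <- function() synth_connectome(10, density = 0.5, seed = 42)

# a protocol sized for tests: full settle, shorter post-activation window
test_protocol <- function(...) {
  seizure_protocol(settle_steps = 20000L, max_steps = 100000L, ...)
}

# hand-constructed trajectory object for extract_spread unit tests
fake_trajectory <- function(g, dt = 0.05, activation_step = 2L,
                            thr_on = 0.5, thr_off = 0.4, active_ez = 1L) {
  structure(list(times = (seq_len(nrow(g)) - 1) * dt, g = g, states = NULL,
                 onset_step = rep(NA_integer_, ncol(g)),
                 offset_step = rep(NA_integer_, ncol(g)),
                 dt = dt, n_nodes = ncol(g), model = "full",
                 activation_step = activation_step, n_steps = nrow(g) - 1L,
                 threshold = list(thr_on = thr_on, thr_off = thr_off),
                 active_ez = active_ez, record_stride = 1L, seed = NULL),
            class = "epileptor_trajectory")
}

# minimal spread_outcome builder for pipeline unit tests
fake_outcome <- function(onsets, active_ez = 1L) {
  n <- length(onsets)
  recruited <- as.integer(!is.na(onsets))
  structure(list(recruited = recruited, onset_times = onsets,
                 offset_times = rep(NA_real_, n),
                 spread_size = sum(recruited),
                 spread_fraction = mean(recruited),
                 phase = if (sum(recruited) == 0) "no_seizure"
                         else if (sum(recruited) == 1) "no_spread" else "spread",
                 recruitment_order = order(onsets, na.last = NA),
                 active_ez = active_ez, n_nodes = n, seed = NULL),
            class = "spread_outcome")
}
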