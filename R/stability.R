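# Linear stability analysis of Epileptor networks: fixed points, analytic
# Jacobians, two-Jacobian phase classification and eigenvector-based
# recruitment ranking. Delays are set to zero throughout: inter-node
# interaction runs through the slow permittivity variable, so axonal delays
# play no role in the location or stability of equilibria.

# ---- root finding ---------------------------------------------------------

# damped Newton with analytic Jacobian; pracma::fsolve only as a rescue when
# Newton stalls above the fixed-point residual contract (1e-9)
.newton <- function(fun, jac, x, tol = 1e-11, maxit = 60, rescue = TRUE) {
  f <- fun(x)
  r <- max(abs(f))
  nonmono <- 0
  for (it in seq_len(maxit)) {
    if (r < tol) break
    step <- tryCatch(solve(jac(x), -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (h in 1:12) { # step-halving line search
      xn <- x + lambda * step
      fn <- fun(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < r) { improved <- TRUE; break }
      lambda <- lambda / 2
    }
    if (!improved) {
      # the piecewise branches can defeat a monotone line search right at a
      # switch plane; a few full (non-monotone) semismooth steps cross it
      xn <- x + step
      fn <- fun(xn)
      nonmono <- nonmono + 1
      if (!all(is.finite(fn)) || nonmono > 5) break
    }
    x <- xn; f <- fn; r <- max(abs(f))
  }
  if (rescue && r > 1e-9) {
    sol <- tryCatch(pracma::fsolve(fun, x, J = jac), error = function(e) NULL)
    if (!is.null(sol)) {
      ff <- fun(sol$x)
      if (all(is.finite(ff)) && max(abs(ff)) < r) { x <- sol$x; r <- max(abs(ff)) }
    }
  }
  list(x = x, residual = r)
}

# ---- network system assembly ---------------------------------------------

# Effective coupled system for a stability variant. For "with_ez" the active
# EZ node keeps x0 = x0_ez inside the network; for "ez_removed" the EZ row
# and column are deleted and the EZ's influence enters as the constant drive
# ext_w_i * (x_bar - x1_i) in each formerly connected node's z equation.
.network_system <- function(connectome, params, variant, active_ez,
                            model = "full", x_bar = NULL) {
  n <- connectome$n_nodes
  if (is.null(active_ez)) {
    if (!length(connectome$ez_nodes)) stop("no active EZ node specified")
    active_ez <- connectome$ez_nodes[1]
  }
  stopifnot(active_ez >= 1, active_ez <= n)
  if (variant == "with_ez") {
    x0 <- rep(params$x0_surround, n)
    x0[active_ez] <- params$x0_ez
    list(W = connectome$weights, x0 = x0, ext_w = NULL, ext_x = NULL,
         nodes = seq_len(n), active_ez = active_ez, m = n)
  } else if (variant == "ez_removed") {
    if (is.null(x_bar)) x_bar <- ez_mean_drive(params, model = model)
    keep <- setdiff(seq_len(n), active_ez)
    list(W = connectome$weights[keep, keep, drop = FALSE],
         x0 = rep(params$x0_surround, n - 1),
         ext_w = connectome$weights[keep, active_ez], ext_x = x_bar,
         nodes = keep, active_ez = active_ez, m = n - 1)
  } else stop("unknown variant: ", variant)
}

# lean drift on stacked vectors for the Newton loops; must agree with
# drift_full / drift_reduced (property-tested)
.sys_drift <- function(sys, params, model) {
  m <- sys$m
  W <- sys$W
  rs <- rowSums(W)
  ext_w <- sys$ext_w; ext_x <- sys$ext_x
  x0 <- sys$x0
  w <- params$w
  I1 <- params$I1; I2 <- params$I2; gam <- params$gamma
  t0 <- params$tau0; t1 <- params$tau1; t2 <- params$tau2
  if (model == "full") {
    function(v) {
      x1 <- v[1:m]; y1 <- v[m + 1:m]; z <- v[2 * m + 1:m]
      x2 <- v[3 * m + 1:m]; y2 <- v[4 * m + 1:m]; g <- v[5 * m + 1:m]
      cpl <- as.vector(W %*% x1) - rs * x1
      if (!is.null(ext_w)) cpl <- cpl + ext_w * (ext_x - x1)
      lo <- x1 < 0
      f1 <- (x2 - 0.6 * (z - 4)^2) * x1
      f1[lo] <- x1[lo]^3 - 3 * x1[lo]^2
      f2 <- 6 * (x2 + 0.25)
      f2[x2 < -0.25] <- 0
      c(y1 - f1 - z + I1,
        (1 - 5 * x1^2 - y1) / t1,
        (4 * (x1 - x0) - z - w * cpl) / t0,
        -y2 + x2 - x2^3 + I2 + 0.002 * g - 0.3 * (z - 3.5),
        (-y2 + f2) / t2,
        x1 - gam * g)
    }
  } else {
    function(v) {
      x <- v[1:m]; z <- v[m + 1:m]
      cpl <- as.vector(W %*% x) - rs * x
      if (!is.null(ext_w)) cpl <- cpl + ext_w * (ext_x - x)
      c(-x^3 - 2 * x^2 + 1 - z + I1,
        (4 * (x - x0) - z - w * cpl) / t0)
    }
  }
}

# ---- analytic Jacobians ---------------------------------------------------

# Jacobian of the network drift in block order (x1, y1, z, x2, y2, g) for the
# full model or (x, z) for the reduced model, each block m x m, evaluated at
# `state` (m x nv). Delays are zero. `ext_w` adds the constant-drive weights
# to the z-row diagonal sums.
.network_jacobian <- function(state, params, W, ext_w = NULL,
                              model = c("full", "reduced")) {
  model <- match.arg(model)
  m <- nrow(state)
  id <- seq_len(m)
  rs <- rowSums(W)
  if (!is.null(ext_w)) rs <- rs + ext_w
  # z-rows w.r.t. the coupling variable (Kronecker-delta structure)
  Jzx <- -params$w * W / params$tau0
  Jzx[cbind(id, id)] <- (4 + params$w * rs) / params$tau0
  if (model == "reduced") {
    x <- state[, 1]
    J <- matrix(0, 2 * m, 2 * m)
    J[cbind(id, id)] <- -3 * x^2 - 4 * x
    J[cbind(id, m + id)] <- -1
    J[m + id, id] <- Jzx
    J[cbind(m + id, m + id)] <- -1 / params$tau0
    return(J)
  }
  x1 <- state[, 1]; z <- state[, 3]; x2 <- state[, 4]
  lo <- x1 < 0 # f1 branch per node; the switch point takes the ">=" branch
  df1_dx1 <- x2 - 0.6 * (z - 4)^2
  df1_dx1[lo] <- 3 * x1[lo]^2 - 6 * x1[lo]
  df1_dz <- -1.2 * (z - 4) * x1
  df1_dz[lo] <- 0
  df1_dx2 <- x1
  df1_dx2[lo] <- 0
  df2_dx2 <- rep(6, m)
  df2_dx2[x2 < -0.25] <- 0
  b <- function(k) (k - 1L) * m + id # block offsets: x1,y1,z,x2,y2,g
  J <- matrix(0, 6 * m, 6 * m)
  J[cbind(b(1), b(1))] <- -df1_dx1
  J[cbind(b(1), b(2))] <- 1
  J[cbind(b(1), b(3))] <- -df1_dz - 1
  J[cbind(b(1), b(4))] <- -df1_dx2
  J[cbind(b(2), b(1))] <- -10 * x1 / params$tau1
  J[cbind(b(2), b(2))] <- -1 / params$tau1
  J[b(3), b(1)] <- Jzx
  J[cbind(b(3), b(3))] <- -1 / params$tau0
  J[cbind(b(4), b(3))] <- -0.3
  J[cbind(b(4), b(4))] <- 1 - 3 * x2^2
  J[cbind(b(4), b(5))] <- -1
  J[cbind(b(4), b(6))] <- 0.002
  J[cbind(b(5), b(4))] <- df2_dx2 / params$tau2
  J[cbind(b(5), b(5))] <- -1 / params$tau2
  J[cbind(b(6), b(1))] <- 1
  J[cbind(b(6), b(6))] <- -params$gamma
  J
}

#' Assemble the analytic Jacobian of an Epileptor network at a fixed point
#'
#' Builds the `6m x 6m` (full model) or `2m x 2m` (reduced model) Jacobian of
#' the deterministic network drift, evaluated at a fixed point, with delays
#' set to zero. Two variants are available: `"with_ez"` keeps the active EZ
#' node in the network (`m = n`); `"ez_removed"` deletes the EZ node's rows
#' and columns (`m = n - 1`) and accounts for the constant mean-ictal drive
#' through the surviving nodes' coupling row sums.
#'
#' Piecewise derivatives are taken on the branch containing the fixed point;
#' a fixed point lying exactly on a switch point uses the `>=` branch (with a
#' warning).
#'
#' @param fixed_point `m x 6` (or `m x 2`) state matrix, e.g. from
#'   [find_network_fixed_point()].
#' @param connectome a normalized [connectome].
#' @param params an [epileptor_params].
#' @param variant `"with_ez"` or `"ez_removed"`.
#' @param active_ez active EZ node index (defaults to the connectome's first).
#' @param model `"full"` or `"reduced"`.
#' @param x_bar mean ictal drive of the EZ for the `"ez_removed"` variant;
#'   computed via [ez_mean_drive()] when `NULL`. Only its coupling weights
#'   enter the Jacobian; the value itself shifts the fixed point.
#' @return The Jacobian matrix, block-ordered `(x1, y1, z, x2, y2, g)` resp.
#'   `(x, z)` with one `m`-block per variable.
#' @export
build_jacobian <- function(fixed_point, connectome, params,
                           variant = c("with_ez", "ez_removed"),
                           active_ez = NULL, model = c("full", "reduced"),
                           x_bar = NULL) {
  variant <- match.arg(variant)
  model <- match.arg(model)
  if (variant == "ez_removed" && is.null(x_bar))
    x_bar <- ez_mean_drive(params, model = model)
  sys <- .network_system(connectome, params, variant, active_ez, model, x_bar)
  nv <- if (model == "full") 6 else 2
  fixed_point <- .as_state(fixed_point, nv)
  if (nrow(fixed_point) != sys$m)
    stop("fixed point has ", nrow(fixed_point), " nodes; expected ", sys$m)
  if (model == "full" && any(fixed_point[, 1] == 0 | fixed_point[, 4] == -0.25))
    warning("fixed point lies exactly on a nonsmooth switch; using the '>=' branch")
  .network_jacobian(fixed_point, params, sys$W, sys$ext_w, model)
}

# ---- single-node fixed points --------------------------------------------

#' Fixed points of an isolated Epileptor node
#'
#' Multi-start damped-Newton root search on the deterministic single-node
#' system (full 6D Epileptor or 2D reduction) at excitability `x0`. Roots are
#' deduplicated at `1e-6` and classified stable/unstable by the sign of the
#' largest real part of the node Jacobian's eigenvalues. At non-epileptic
#' excitability the full model has three fixed points, exactly one of them
#' stable; above the critical excitability the stable one is lost.
#'
#' @param params an [epileptor_params] (its `w` is ignored: the node is
#'   isolated).
#' @param x0 node excitability.
#' @param model `"full"` or `"reduced"`.
#' @param branch `"resting"` (default) seeds the search near the resting
#'   state (`x1 < 0`), the convention under which the full model has three
#'   fixed points; `"all"` also seeds the ictal branch (`x1 >= 0`), which
#'   harbours one additional strongly unstable equilibrium.
#' @return A list with one element per fixed point: `state` (`1 x nv`
#'   matrix), `stable` (logical), `lambda` (leading real part), `residual`.
#'   Sorted by the first state component.
#' @export
find_fixed_points_single <- function(params, x0 = params$x0_surround,
                                     model = c("full", "reduced"),
                                     branch = c("resting", "all")) {
  model <- match.arg(model)
  branch <- match.arg(branch)
  p0 <- params; p0$w <- 0
  conn1 <- list(weights = matrix(0, 1, 1))
  sys <- list(W = conn1$weights, x0 = x0, ext_w = NULL, ext_x = NULL, m = 1)
  fn <- .sys_drift(sys, p0, model)
  jf <- function(v) .network_jacobian(matrix(v, ncol = if (model == "full") 6 else 2),
                                      p0, sys$W, NULL, model)
  starts <- .single_node_starts(p0, x0, model, branch)
  roots <- list()
  for (s in starts) {
    sol <- .newton(fn, jf, s)
    if (sol$residual > 1e-9) next
    if (model == "full" && branch == "resting" && sol$x[1] >= 0) next
    if (!length(roots) ||
        all(vapply(roots, function(r) max(abs(r$x - sol$x)) > 1e-6, TRUE)))
      roots[[length(roots) + 1]] <- sol
  }
  if (!length(roots))
    stop("no fixed point found from any of ", length(starts), " starts")
  out <- lapply(roots, function(r) {
    st <- matrix(r$x, nrow = 1)
    ev <- eigen(jf(r$x), only.values = TRUE)$values
    lam <- max(Re(ev))
    list(state = st, stable = lam < 0, lambda = lam, residual = r$residual)
  })
  out[order(vapply(out, function(f) f$state[1, 1], 0))]
}

.single_node_starts <- function(params, x0, model, branch = "all") {
  if (model == "reduced") {
    # cubic x^3 + 2x^2 + 4x - (4 x0 + 1 + I1) = 0 seeds plus a coarse grid
    rts <- polyroot(c(-(4 * x0 + 1 + params$I1), 4, 2, 1))
    xs <- unique(c(Re(rts[abs(Im(rts)) < 1e-8]), seq(-2.5, 1.5, by = 0.5)))
    return(lapply(xs, function(x) c(x, 4 * (x - x0))))
  }
  x1_grid <- if (branch == "resting") seq(-2.5, -0.25, by = 0.25)
             else seq(-2.5, 1.25, by = 0.25)
  starts <- list()
  for (x1 in x1_grid) {
    for (x2 in c(-1.5, -0.5, 0.25)) {
      starts[[length(starts) + 1]] <-
        c(x1, 1 - 5 * x1^2, 4 * (x1 - x0), x2, f2_epileptor(x2),
          x1 / params$gamma)
    }
  }
  starts
}

#' Critical excitability of an isolated node
#'
#' Bisection on `x0` for the excitability at which an isolated node's stable
#' (non-epileptic) fixed point is lost or destabilized. A node with `x0`
#' above this value is epileptogenic. For the full Epileptor with standard
#' constants the critical value is approximately -2.061.
#'
#' @param params an [epileptor_params].
#' @param model `"full"` or `"reduced"`.
#' @param bracket interval `(lo, hi)` with a stable fixed point at `lo` and
#'   none at `hi`.
#' @param tol bisection tolerance on `x0`.
#' @return The critical excitability (scalar).
#' @export
critical_excitability_single <- function(params, model = c("full", "reduced"),
                                         bracket = c(-2.3, -1.6), tol = 1e-4) {
  model <- match.arg(model)
  stable_at <- function(x0) {
    fps <- tryCatch(find_fixed_points_single(params, x0, model),
                    error = function(e) list())
    any(vapply(fps, `[[`, TRUE, "stable"))
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (!stable_at(lo) || stable_at(hi))
    stop("bracketing failure: need a stable fixed point at ", lo,
         " and none at ", hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stable_at(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ---- EZ mean ictal drive --------------------------------------------------

.drive_cache <- new.env(parent = emptyenv())

# reference isolated-EZ deterministic run: seizure thresholds on the
# detection variable (g resp. x) and the mean of x1 over the first seizure
.ez_reference_run <- function(params, model = "full", dt = 0.05,
                              max_steps = 400000L) {
  key <- paste(model, dt, max_steps,
               paste(format(c(params$x0_ez, params$x0_surround, params$I1,
                              params$I2, params$gamma, params$tau0,
                              params$tau1, params$tau2), digits = 15),
                     collapse = ","), sep = "|")
  if (!is.null(.drive_cache[[key]])) return(.drive_cache[[key]])
  p0 <- params; p0$w <- 0; p0$sigma <- 0
  fps <- find_fixed_points_single(p0, p0$x0_surround, model)
  stable <- Filter(function(f) f$stable, fps)
  if (!length(stable))
    stop("no stable fixed point at the surround excitability x0 = ",
         p0$x0_surround)
  s0 <- stable[[1]]$state
  nv <- ncol(s0)
  res <- .heun_sim(s0, if (model == "full") 1L else 2L, as.integer(max_steps),
                   dt, p0$x0_ez, 0, matrix(0, 1, 1),
                   matrix(0L, 1, 1), 0, .par_list(p0),
                   -1L, -1L, p0$x0_ez, NA_real_, NA_real_,
                   2L, 1L, 1e6)
  det <- res$det[, 1]
  baseline <- det[1]
  plateau <- max(det)
  if (plateau - baseline < 1e-3)
    stop("no seizure detected within ", max_steps,
         " steps of the isolated-EZ reference run")
  thr_on <- baseline + 0.5 * (plateau - baseline)
  thr_off <- baseline + 0.45 * (plateau - baseline) # 90% of the rise to onset
  onset <- which(det >= thr_on)[1]
  offi <- which(det[onset:length(det)] <= thr_off)[1]
  if (is.na(onset) || is.na(offi))
    stop("reference seizure did not complete within ", max_steps, " steps")
  offset <- onset + offi - 1L
  x1 <- res$states[, 1]
  out <- list(thr_on = thr_on, thr_off = thr_off, baseline = baseline,
              plateau = plateau, onset_step = onset - 1L,
              offset_step = offset - 1L,
              x_bar = mean(x1[onset:offset]), dt = dt)
  .drive_cache[[key]] <- out
  out
}

#' Mean ictal drive of an isolated EZ node
#'
#' Simulates one isolated, deterministic node at the EZ excitability
#' (`x0_ez`, default -1.6), detects the first full seizure by threshold
#' crossings of the smooth detection variable (`g` for the full model), and
#' returns the time average of the fast variable `x1` over that seizure. This
#' is the constant input used when the EZ node is replaced by an external
#' drive in the second Jacobian variant.
#'
#' @param params an [epileptor_params].
#' @param model `"full"` or `"reduced"`.
#' @param dt integration step.
#' @return Scalar mean of `x1` over the first seizure interval. Deterministic
#'   and cached per parameter set.
#' @export
ez_mean_drive <- function(params, model = c("full", "reduced"), dt = 0.05) {
  model <- match.arg(model)
  .ez_reference_run(params, model, dt)$x_bar
}

#' Auto-calibrated seizure detection thresholds
#'
#' Onset threshold halfway between the resting baseline and the ictal
#' plateau of the detection variable in a deterministic isolated-EZ reference
#' run, with the termination (hysteresis) threshold at 90 percent of the rise
#' to the onset threshold. Values are in the units of the detection variable
#' (`g` for the full model).
#'
#' @inheritParams ez_mean_drive
#' @return List with `thr_on`, `thr_off`, `baseline`, `plateau`.
#' @export
calibrate_threshold <- function(params, model = c("full", "reduced"),
                                dt = 0.05) {
  model <- match.arg(model)
  ref <- .ez_reference_run(params, model, dt)
  ref[c("thr_on", "thr_off", "baseline", "plateau")]
}

# ---- network fixed points -------------------------------------------------

# On the resting branch (all x1 < 0) the (x1, y1, z, g) subsystem closes on
# itself: y1 = 1 - 5 x1^2, g = x1/gamma, z = -x1^3 - 2 x1^2 + 1 + I1, and the
# z equation becomes a smooth m-dimensional system in x1 alone. The slaved
# (x2, y2) pair then solves a per-node piecewise cubic. This both speeds up
# and stabilizes the fixed-point search (no Newton iteration ever crosses
# the f2 kink).
.resting_x1_solve <- function(sys, params, x1_start) {
  m <- sys$m
  W <- sys$W; rs0 <- rowSums(W)
  ext_w <- if (is.null(sys$ext_w)) rep(0, m) else sys$ext_w
  ext_x <- if (is.null(sys$ext_x)) 0 else sys$ext_x
  w <- params$w
  Gfun <- function(x1) {
    z <- -x1^3 - 2 * x1^2 + 1 + params$I1
    cpl <- as.vector(W %*% x1) - rs0 * x1 + ext_w * (ext_x - x1)
    4 * (x1 - sys$x0) - z - w * cpl
  }
  Gjac <- function(x1) {
    J <- -w * W
    diag(J) <- 4 + 3 * x1^2 + 4 * x1 + w * (rs0 + ext_w)
    J
  }
  sol <- .newton(Gfun, Gjac, x1_start, tol = 1e-12, maxit = 40,
                 rescue = FALSE)
  if (sol$residual > 1e-10 || any(sol$x >= 0)) return(NULL)
  sol$x
}

# all real roots of the slaved (x2, y2) subsystem for a given drive c:
# x2 - x2^3 - f2(x2) + c = 0 with the branch-validity constraint
.x2_roots <- function(c) {
  roots <- c()
  r1 <- polyroot(c(c, 1, 0, -1))            # y2 = 0 branch: -x2^3 + x2 + c
  r1 <- Re(r1[abs(Im(r1)) < 1e-8])
  roots <- c(roots, r1[r1 < -0.25])
  r2 <- polyroot(c(c - 1.5, -5, 0, -1))     # y2 = 6(x2 + .25): -x2^3 - 5 x2 + c - 1.5
  r2 <- Re(r2[abs(Im(r2)) < 1e-8])
  roots <- c(roots, r2[r2 >= -0.25])
  sort(roots)
}

# assemble the resting-branch network fixed point; x2_prev tracks the slaved
# root family across continuation steps. NULL when outside the resting
# branch or when the tracked x2 family has no nearby root (fast-subsystem
# fold).
.resting_network_fp <- function(sys, params, model, x1_start, x2_prev = NULL) {
  x1 <- .resting_x1_solve(sys, params, x1_start)
  if (is.null(x1)) return(NULL)
  m <- sys$m
  z <- -x1^3 - 2 * x1^2 + 1 + params$I1
  if (model == "reduced") return(cbind(x = x1, z = z))
  y1 <- 1 - 5 * x1^2
  g <- x1 / params$gamma
  cdrive <- params$I2 + 0.002 * g - 0.3 * (z - 3.5)
  x2 <- numeric(m)
  for (i in seq_len(m)) {
    cand <- .x2_roots(cdrive[i])
    if (!length(cand)) return(NULL)
    ref <- if (is.null(x2_prev)) NULL else x2_prev[i]
    if (is.null(ref)) {
      # default to the most negative root, the family containing the stable
      # single-node equilibrium
      x2[i] <- cand[1]
    } else {
      j <- which.min(abs(cand - ref))
      if (abs(cand[j] - ref) > 0.25) return(NULL) # family lost in a fold
      x2[i] <- cand[j]
    }
  }
  y2 <- f2_epileptor(x2)
  cbind(x1 = x1, y1 = y1, z = z, x2 = x2, y2 = y2, g = g)
}

#' Fixed point of the deterministic Epileptor network
#'
#' Solves the deterministic network drift for a zero, with delays ignored,
#' seeded from the single-node stable fixed point at the surround
#' excitability tiled across nodes. For the `"with_ez"` variant the active EZ
#' node carries `x0_ez` inside the network; for `"ez_removed"` the EZ node is
#' replaced by the constant drive [ez_mean_drive()] into its neighbours.
#'
#' @inheritParams build_jacobian
#' @param connectome a normalized [connectome].
#' @return `m x nv` state matrix (`m = n` or `n - 1` nodes) with attributes
#'   `residual` (max-norm of the drift) and `nodes` (original node indices).
#' @export
find_network_fixed_point <- function(connectome, params,
                                     variant = c("with_ez", "ez_removed"),
                                     active_ez = NULL,
                                     model = c("full", "reduced"),
                                     x_bar = NULL) {
  variant <- match.arg(variant)
  model <- match.arg(model)
  if (variant == "ez_removed" && is.null(x_bar))
    x_bar <- ez_mean_drive(params, model = model)
  sys <- .network_system(connectome, params, variant, active_ez, model, x_bar)
  nv <- if (model == "full") 6 else 2
  fps <- find_fixed_points_single(params, params$x0_surround, model)
  stable <- Filter(function(f) f$stable, fps)
  if (!length(stable))
    stop("no stable single-node fixed point at the surround excitability")
  start <- matrix(rep(stable[[1]]$state, each = sys$m), nrow = sys$m)
  if (variant == "with_ez") {
    # at w = 0 the EZ node decouples and sits on its own resting branch:
    # seed it with the root continuing the stable family
    ez_fps <- find_fixed_points_single(params, params$x0_ez, model)
    d <- vapply(ez_fps, function(f) max(abs(f$state - stable[[1]]$state)), 0)
    start[sys$active_ez, ] <- ez_fps[[which.min(d)]]$state
  }

  # continuation in the global coupling: the decoupled (w = 0) fixed point is
  # exact; track it to the target w, refining the step on failure
  # continuation in the global coupling: the decoupled (w = 0) fixed point is
  # exact; track the resting branch to the target w, refining the step on
  # failure. A persistent failure (no nearby root) is a fold: the resting
  # state has been lost.
  attempt <- function(w_try, prev) {
    p <- params; p$w <- w_try
    st <- .resting_network_fp(sys, p, model, x1_start = prev[, 1],
                              x2_prev = if (model == "full") prev[, 4])
    if (!is.null(st) && max(abs(st[, 1] - prev[, 1])) <= 0.25) return(st)
    # generic damped-Newton fallback (e.g. ictal-branch equilibria)
    fn <- .sys_drift(sys, p, model)
    jf <- function(v) .network_jacobian(matrix(v, ncol = nv), p, sys$W,
                                        sys$ext_w, model)
    sol <- .newton(fn, jf, as.vector(prev), rescue = FALSE)
    cand <- matrix(sol$x, ncol = nv)
    jidx <- seq_len(if (model == "full") 5L else 2L) # all O(1) blocks; g ~ x1/gamma excluded
    if (sol$residual < 1e-9 &&
        max(abs(cand[, jidx] - prev[, jidx])) <= 0.25) return(cand)
    NULL
  }
  cur <- attempt(0, start)
  if (is.null(cur)) cur <- start # w = 0 start is already exact
  w_cur <- 0
  step0 <- if (params$w > 0) min(params$w, 0.25) else 0
  step <- step0
  while (w_cur < params$w) {
    w_try <- min(w_cur + step, params$w)
    cand <- attempt(w_try, cur)
    if (!is.null(cand)) {
      cur <- cand; w_cur <- w_try
      step <- min(step * 2, step0)
    } else {
      step <- step / 2
      if (step / params$w < 1e-5) {
        cond <- structure(class = c("epileptornet_fold_error", "error",
                                    "condition"),
                          list(message = sprintf(
                            "fixed point of the %s system is lost in a fold near w = %.4g (target w = %.4g)",
                            variant, w_cur, params$w), call = sys.call(-1),
                            w_fold = w_cur))
        stop(cond)
      }
    }
  }
  fn <- .sys_drift(sys, params, model)
  sol <- list(x = as.vector(cur), residual = max(abs(fn(as.vector(cur)))))
  if (sol$residual > 1e-9) {
    jf <- function(v) .network_jacobian(matrix(v, ncol = nv), params, sys$W,
                                        sys$ext_w, model)
    sol <- .newton(fn, jf, sol$x)
    if (sol$residual > 1e-9)
      stop(sprintf("network fixed point search did not converge (variant %s): best residual %.3e",
                   variant, sol$residual))
  }
  out <- matrix(sol$x, ncol = nv)
  colnames(out) <- if (model == "full") .state_cols_full else .state_cols_reduced
  attr(out, "residual") <- sol$residual
  attr(out, "nodes") <- sys$nodes
  out
}

# ---- phase classification and ranking -------------------------------------

.leading_eigen <- function(J) {
  e <- eigen(J)
  i <- which.max(Re(e$values))
  v <- e$vectors[, i]
  v <- v / sqrt(sum(Mod(v)^2))
  list(value = e$values[i], vector = v)
}

#' Two-Jacobian phase prediction for seizure spread
#'
#' Predicts the phase of the seizure-spread order parameter from the leading
#' eigenvalues of two Jacobians evaluated at the corresponding network fixed
#' points: `lambda_R` from the network including the active EZ node, and
#' `lambda_tilde_R` from the network with the EZ node replaced by its
#' constant mean ictal drive. The joint signs give the phase:
#' \itemize{
#'   \item `lambda_R < 0`: `no_seizure` (the surround stabilizes the EZ);
#'   \item `lambda_R > 0`, `lambda_tilde_R < 0`: `no_spread`;
#'   \item `lambda_R > 0`, `lambda_tilde_R > 0`: `spread`.
#' }
#' Eigenvalues here scale with `1/tau0`, so the numeric zero threshold is
#' tight (`1e-9`). When spread is predicted the leading eigenvector of the
#' with-EZ Jacobian is used to rank surround nodes: larger `|v_z,i|` (the
#' complex modulus of the eigenvector component for the permittivity variable
#' `z` of node `i`, eigenvector scaled to unit 2-norm) means earlier
#' predicted recruitment.
#'
#' @inheritParams find_network_fixed_point
#' @param zero_tol numeric threshold separating positive from non-positive
#'   real parts.
#' @return An object of class `stability_report`: a list with the two fixed
#'   points, `lambda_R`, `lambda_tilde_R`, `x1_ez_mean`, per-surround-node
#'   `v_z` magnitudes, `predicted_phase` and (when spread is predicted)
#'   `predicted_ranks`.
#' @export
classify_phase <- function(connectome, params, active_ez = NULL,
                           model = c("full", "reduced"), x_bar = NULL,
                           zero_tol = 1e-9) {
  model <- match.arg(model)
  if (is.null(active_ez)) {
    if (!length(connectome$ez_nodes)) stop("no active EZ node specified")
    active_ez <- connectome$ez_nodes[1]
  }
  if (is.null(x_bar)) x_bar <- ez_mean_drive(params, model = model)

  # a fold (loss of the tracked resting equilibrium below the target w) means
  # the corresponding resting state no longer exists: maximally unstable
  fp1 <- tryCatch(find_network_fixed_point(connectome, params, "with_ez",
                                           active_ez, model),
                  epileptornet_fold_error = function(e) NULL)
  le1 <- NULL
  if (!is.null(fp1)) {
    J1 <- build_jacobian(fp1, connectome, params, "with_ez", active_ez, model)
    le1 <- .leading_eigen(J1)
  }

  fp2 <- tryCatch(find_network_fixed_point(connectome, params, "ez_removed",
                                           active_ez, model, x_bar = x_bar),
                  epileptornet_fold_error = function(e) NULL)
  le2 <- NULL
  if (!is.null(fp2)) {
    J2 <- build_jacobian(fp2, connectome, params, "ez_removed", active_ez,
                         model, x_bar = x_bar)
    le2 <- .leading_eigen(J2)
  }

  lam <- if (is.null(le1)) Inf else Re(le1$value)
  lam_t <- if (is.null(le2)) Inf else Re(le2$value)
  phase <- if (lam < zero_tol) "no_seizure"
           else if (lam_t < zero_tol) "no_spread"
           else "spread"

  n <- connectome$n_nodes
  surround <- setdiff(seq_len(n), active_ez)
  zblock <- if (model == "full") 2L * n else n # offset of the z block
  if (!is.null(le1)) {
    v_z <- Mod(le1$vector[zblock + surround])
  } else {
    v_z <- rep(NA_real_, length(surround))
  }
  names(v_z) <- as.character(surround)

  rep <- structure(list(fixed_point = fp1, fixed_point_ez_removed = fp2,
                        lambda_R = lam, lambda_tilde_R = lam_t,
                        x1_ez_mean = x_bar, v_z = v_z,
                        predicted_phase = phase, predicted_ranks = NULL,
                        active_ez = active_ez, model = model,
                        n_nodes = n),
                   class = "stability_report")
  if (phase == "spread" && !anyNA(v_z))
    rep$predicted_ranks <- recruitment_ranks(rep)
  rep
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Epileptor network stability report (", x$model, " model)\n", sep = "")
  cat(sprintf("  active EZ node: %d of %d\n", x$active_ez, x$n_nodes))
  cat(sprintf("  lambda_R = %.3e, lambda_tilde_R = %.3e\n",
              x$lambda_R, x$lambda_tilde_R))
  cat(sprintf("  mean ictal EZ drive x1 = %.4f\n", x$x1_ez_mean))
  cat("  predicted phase:", x$predicted_phase, "\n")
  if (!is.null(x$predicted_ranks)) {
    r <- x$predicted_ranks
    cat("  predicted recruitment order (first 10):",
        paste(utils::head(r$node[order(r$rank)], 10), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted recruitment order from the leading eigenvector
#'
#' Ranks the surround nodes by the magnitudes `|v_z,i|` of the leading
#' eigenvector's permittivity components: rank 1 is the largest magnitude,
#' i.e. the node predicted to be recruited first. Exact ties are broken by
#' ascending node index.
#'
#' @param report a `stability_report` with `predicted_phase == "spread"`.
#' @return A `data.frame` with columns `node`, `v_z`, `rank`.
#' @export
recruitment_ranks <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  if (report$predicted_phase != "spread")
    stop("recruitment ranks are defined only when the predicted phase is 'spread' (got '",
         report$predicted_phase, "')")
  node <- as.integer(names(report$v_z))
  ord <- order(-report$v_z, node)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  data.frame(node = node, v_z = as.numeric(report$v_z), rank = rank)
}
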