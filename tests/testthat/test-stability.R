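test_that("an isolated node has three resting fixed points, one stable", {
  p <- default_params()
  fps <- find_fixed_points_single(p, -2.2, "full")
  expect_length(fps, 3)
  expect_equal(sum(vapply(fps, `[[`, TRUE, "stable")), 1)
  for (f in fps) expect_lt(f$residual, 1e-9)
  # the three resting roots share x1 and differ in the slaved (x2, y2) pair
  x1s <- vapply(fps, function(f) f$state[1, 1], 0)
  expect_lt(diff(range(x1s)), 1e-8)
})

test_that("reduced-model fixed points match the cubic-root oracle", {
  p <- default_params()
  for (x0 in c(-2.3, -2.2, -2.1)) {
    fps <- find_fixed_points_single(p, x0, "reduced")
    xs <- sort(vapply(fps, function(f) f$state[1, 1], 0))
    # oracle: real roots of -x^3 - 2x^2 + 1 + I1 - 4(x - x0) = 0, z = 4(x - x0)
    rts <- polyroot(c(4 * x0 + 1 + p$I1, -4, -2, -1))
    oracle <- sort(Re(rts[abs(Im(rts)) < 1e-8]))
    expect_equal(xs, oracle, tolerance = 1e-8)
    for (f in fps)
      expect_equal(f$state[1, 2], 4 * (f$state[1, 1] - x0), tolerance = 1e-8)
  }
})

test_that("critical excitability of an isolated node is about -2.061", {
  p <- default_params()
  x0c <- critical_excitability_single(p, "full")
  expect_lt(abs(x0c - (-2.061)), 5e-3)
  # the EZ excitability lies above the critical value (epileptogenic), the
  # whole admissible surround range below it (non-epileptic)
  expect_gt(-1.6, x0c)
  expect_true(all(c(-2.3, -2.09) < x0c))
  expect_error(critical_excitability_single(p, bracket = c(-1.7, -1.6)),
               "bracket")
})

test_that("the EZ mean ictal drive is deterministic and step-size robust", {
  p <- default_params()
  v1 <- ez_mean_drive(p)
  v2 <- ez_mean_drive(p)
  expect_identical(v1, v2)
  ref <- epileptornet:::.ez_reference_run(p, "full")
  # a mean is bounded by the extremes of the averaged segment
  expect_gt(v1, -2.5)
  expect_lt(v1, 2)
  expect_gt(ref$plateau, ref$baseline)
  v_half <- epileptornet:::.ez_reference_run(p, "full", dt = 0.025,
                                             max_steps = 800000L)$x_bar
  expect_lt(abs(v1 - v_half) / abs(v1), 0.01)
})

test_that("network fixed points reduce correctly in degenerate limits", {
  cn <- net3()
  # w = 0, homogeneous x0: the tiled single-node stable fixed point
  p0 <- default_params(x0_surround = -2.2, w = 0, x0_ez = -2.2)
  fp <- find_network_fixed_point(cn, p0, "with_ez", active_ez = 1)
  st <- Filter(function(f) f$stable,
               find_fixed_points_single(p0, -2.2))[[1]]$state
  expect_equal(unname(fp[, ]), matrix(rep(st, each = 3), 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  # homogeneous x0 at every node, any w: the tiling is still a fixed point
  p1 <- default_params(x0_surround = -2.2, w = 1.7, x0_ez = -2.2)
  fp1 <- find_network_fixed_point(cn, p1, "with_ez", active_ez = 1)
  expect_equal(unname(fp1[, ]), matrix(rep(st, each = 3), 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  # ez_removed with the drive frozen at the surround resting x1 equals the
  # no-input fixed point of the remaining nodes
  p2 <- default_params(x0_surround = -2.2, w = 0.9)
  fp2 <- find_network_fixed_point(cn, p2, "ez_removed", active_ez = 1,
                                  x_bar = st[1, 1])
  expect_equal(unname(fp2[, ]), matrix(rep(st, each = 2), 2),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("analytic Jacobians match central finite differences", {
  p <- default_params(x0_surround = -2.15, w = 0.8)
  xb <- ez_mean_drive(p)
  xbr <- ez_mean_drive(p, "reduced")
  for (cn in list(net3(), net10())) {
    for (model in c("full", "reduced")) {
      x_bar <- if (model == "full") xb else xbr
      for (variant in c("with_ez", "ez_removed")) {
        fp <- find_network_fixed_point(cn, p, variant, active_ez = 1,
                                       model = model, x_bar = x_bar)
        J <- build_jacobian(fp, cn, p, variant, active_ez = 1, model = model,
                            x_bar = x_bar)
        fn <- variant_drift(cn, p, variant, 1, model, x_bar)
        Jfd <- fd_jacobian(fn, as.vector(fp))
        expect_lt(max(abs(J - Jfd)), 1e-6)
      }
    }
  }
})

test_that("Jacobian blocks carry the structural entries", {
  cn <- net3()
  p <- default_params(x0_surround = -2.2, w = 0.5)
  fp <- find_network_fixed_point(cn, p, "with_ez", active_ez = 1)
  J <- build_jacobian(fp, cn, p, "with_ez", active_ez = 1)
  n <- 3
  gb <- 5 * n + 1:n
  expect_equal(J[gb, gb], diag(-p$gamma, n)) # g-diagonal block is -gamma I
  expect_equal(J[gb, 1:n], diag(n)) # J_g,x1 = I
  zb <- 2 * n + 1:n
  expect_equal(J[zb, zb], diag(-1 / p$tau0, n))
  # w = 0: block-diagonal, no cross-node entries
  p0 <- default_params(x0_surround = -2.2, w = 0)
  fp0 <- find_network_fixed_point(cn, p0, "with_ez", active_ez = 1)
  J0 <- build_jacobian(fp0, cn, p0, "with_ez", active_ez = 1)
  cross <- outer(rep(1:n, 6), rep(1:n, 6), "!=")
  expect_true(all(J0[cross] == 0))
})

test_that("the J_y2,x2 entry follows the differentiated flow", {
  # on the active f2 branch the entry is +6/tau2; certified against finite
  # differences rather than any printed sign convention
  p <- default_params(x0_surround = -2.2, w = 0)
  fps <- find_fixed_points_single(p, -2.2)
  st <- Filter(function(f) f$state[1, 4] >= -0.25, fps)
  expect_gte(length(st), 1)
  s <- st[[1]]$state
  J <- epileptornet:::.network_jacobian(s, p, matrix(0, 1, 1), NULL, "full")
  expect_equal(J[5, 4], 6 / p$tau2)
  fn <- function(v) as.vector(drift_full(matrix(v, 1), p, x0 = -2.2))
  expect_equal(fd_jacobian(fn, as.vector(s))[5, 4], 6 / p$tau2,
               tolerance = 1e-6)
})

test_that("phase classification follows the two-eigenvalue sign logic", {
  cn <- net10()
  # representative regimes validated against simulation elsewhere
  r1 <- classify_phase(cn, default_params(x0_surround = -2.3, w = 8))
  expect_lt(r1$lambda_R, 0)
  expect_equal(r1$predicted_phase, "no_seizure")
  r2 <- classify_phase(cn, default_params(x0_surround = -2.3, w = 0.2))
  expect_gt(r2$lambda_R, 0)
  expect_lt(r2$lambda_tilde_R, 0)
  expect_equal(r2$predicted_phase, "no_spread")
  r3 <- classify_phase(cn, default_params(x0_surround = -2.1, w = 1))
  expect_gt(r3$lambda_R, 0)
  expect_gt(r3$lambda_tilde_R, 0)
  expect_equal(r3$predicted_phase, "spread")
  expect_s3_class(r3$predicted_ranks, "data.frame")
})

test_that("recruitment ranks order magnitudes with index tie-breaks", {
  rep <- structure(list(v_z = c(`2` = 0.5, `3` = 0.1, `4` = 0.3),
                        predicted_phase = "spread"),
                   class = "stability_report")
  rk <- recruitment_ranks(rep)
  expect_equal(rk$rank, c(1, 3, 2))
  rep2 <- structure(list(v_z = c(`2` = 0.2, `3` = 0.2),
                         predicted_phase = "spread"),
                    class = "stability_report")
  expect_equal(recruitment_ranks(rep2)$rank, c(1, 2))
  rep3 <- structure(list(v_z = c(`2` = 0.2), predicted_phase = "no_spread"),
                    class = "stability_report")
  expect_error(recruitment_ranks(rep3), "spread")
})

test_that("the leading eigenvalue is invariant under node relabeling", {
  cn <- net10()
  p <- default_params(x0_surround = -2.15, w = 1)
  r <- classify_phase(cn, p, active_ez = 1)
  perm <- c(3, 1, 5, 2, 4, 7, 10, 6, 9, 8)
  cn2 <- connectome(cn$weights[perm, perm], cn$tract_lengths[perm, perm],
                    ez_nodes = which(perm == 1))
  r2 <- classify_phase(cn2, p, active_ez = which(perm == 1))
  expect_lt(abs(r$lambda_R - r2$lambda_R), 1e-10)
  expect_lt(abs(r$lambda_tilde_R - r2$lambda_tilde_R), 1e-10)
})

test_that("reduced and full phase classifications agree on most of a grid", {
  cn <- net10()
  agree <- 0; tot <- 0
  for (x0 in c(-2.28, -2.2, -2.12)) {
    for (w in c(0.3, 1, 3, 7)) {
      p <- default_params(x0_surround = x0, w = w)
      pf <- classify_phase(cn, p, model = "full")$predicted_phase
      pr <- classify_phase(cn, p, model = "reduced")$predicted_phase
      tot <- tot + 1
      agree <- agree + (pf == pr)
    }
  }
  expect_gte(agree / tot, 0.8)
})

test_that("eigenvector magnitudes track the EZ coupling weights on a hub", {
  cn <- synth_fixtures("star_hub", n = 10)
  p <- default_params(x0_surround = -2.12, w = 1.2)
  r <- classify_phase(cn, p)
  expect_equal(r$predicted_phase, "spread")
  w_ez <- cn$weights[2:10, 1]
  rho <- cor(log(r$v_z), log(w_ez), method = "spearman")
  expect_gt(rho, 0.8)
})
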