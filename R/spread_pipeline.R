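# Orchestration of (x0, w) grid sweeps, phase diagrams, near-criticality
# statistics, and scoring of eigenvector-based predictions against
# simulated recruitment.

#' Sweep a seizure-spread phase diagram
#'
#' Runs `n_realizations` stochastic seizures for every cell of the
#' `(x0_surround, w)` grid and aggregates the spread sizes into an empirical
#' phase diagram. A cell is labelled `no_seizure` if no realization seized,
#' `no_spread` if the active EZ seized but never recruited another node, and
#' `spread` otherwise. Per-realization seeds are `base_seed + counter` and
#' are recorded so that any realization can be replayed exactly.
#'
#' @param connectome a normalized [connectome].
#' @param active_ez active EZ node index.
#' @param x0_grid sorted vector of surround excitabilities (non-epileptic).
#' @param w_grid sorted vector of global coupling strengths.
#' @param sigma noise standard deviation.
#' @param n_realizations stochastic realizations per cell (default 30).
#' @param base_seed integer; realization seeds count up from it.
#' @param protocol a [seizure_protocol] template; its `record` is forced to
#'   `"none"` and its `seed`/`active_ez` are overridden per realization.
#' @param params an [epileptor_params] template supplying the model
#'   constants.
#' @param model `"full"` or `"reduced"`.
#' @return An object of class `phase_diagram`: grids, matrices `mean_size`,
#'   `sd_size` (w rows, x0 columns), a label matrix, the per-realization
#'   records (`data.frame` with x0, w, seed, spread size, phase) and the cell
#'   error log (cells whose integration diverged are flagged and skipped).
#' @export
sweep_phase_diagram <- function(connectome, active_ez = NULL, x0_grid, w_grid,
                                sigma = 0.05, n_realizations = 30,
                                base_seed = 1L,
                                protocol = seizure_protocol(),
                                params = epileptor_params(),
                                model = c("full", "reduced")) {
  model <- match.arg(model)
  if (is.null(active_ez)) {
    if (!length(connectome$ez_nodes)) stop("no active EZ node specified")
    active_ez <- connectome$ez_nodes[1]
  }
  x0_grid <- sort(x0_grid); w_grid <- sort(w_grid)
  nx <- length(x0_grid); nw <- length(w_grid)
  mean_size <- sd_size <- matrix(NA_real_, nw, nx,
                                 dimnames = list(w = format(w_grid),
                                                 x0 = format(x0_grid)))
  label <- matrix(NA_character_, nw, nx)
  failed <- matrix(FALSE, nw, nx)
  rec <- vector("list", nw * nx)
  counter <- 0L
  # thresholds depend only on the node constants: calibrate once up front
  thr <- if (is.null(protocol$threshold))
    calibrate_threshold(params, model, protocol$dt) else protocol$threshold

  for (iw in seq_len(nw)) {
    for (ix in seq_len(nx)) {
      p <- params
      p$x0_surround <- x0_grid[ix]; p$w <- w_grid[iw]; p$sigma <- sigma
      sizes <- rep(NA_integer_, n_realizations)
      phases <- rep(NA_character_, n_realizations)
      seeds <- base_seed + counter + seq_len(n_realizations) - 1L
      counter <- counter + n_realizations
      for (r in seq_len(n_realizations)) {
        pr <- protocol
        pr$record <- "none"; pr$seed <- seeds[r]; pr$active_ez <- active_ez
        pr$threshold <- thr
        out <- tryCatch({
          traj <- simulate_seizure_protocol(connectome, p, pr, model)
          extract_spread(traj)
        }, error = function(e) e)
        if (inherits(out, "error")) {
          failed[iw, ix] <- TRUE
          next
        }
        sizes[r] <- out$spread_size
        phases[r] <- out$phase
      }
      ok <- !is.na(sizes)
      if (any(ok)) {
        mean_size[iw, ix] <- mean(sizes[ok])
        sd_size[iw, ix] <- stats::sd(sizes[ok])
        if (sum(ok) == 1) sd_size[iw, ix] <- 0
        label[iw, ix] <-
          if (all(phases[ok] == "no_seizure")) "no_seizure"
          else if (any(phases[ok] == "spread")) "spread"
          else "no_spread"
      }
      rec[[(iw - 1) * nx + ix]] <-
        data.frame(x0 = x0_grid[ix], w = w_grid[iw],
                   realization = seq_len(n_realizations), seed = seeds,
                   spread_size = sizes, phase = phases)
    }
  }
  structure(list(x0_grid = x0_grid, w_grid = w_grid,
                 mean_size = mean_size, sd_size = sd_size, label = label,
                 failed = failed, records = do.call(rbind, rec),
                 n_realizations = n_realizations, sigma = sigma,
                 active_ez = active_ez, base_seed = base_seed,
                 n_nodes = connectome$n_nodes, model = model),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram: %d x0 values x %d w values, %d realizations/cell (sigma = %g)\n",
              length(x$x0_grid), length(x$w_grid), x$n_realizations, x$sigma))
  tab <- table(factor(x$label, levels = c("no_seizure", "no_spread", "spread")))
  cat("  cell labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  fluctuating cells (sd > 0): %d\n",
              sum(x$sd_size > 0, na.rm = TRUE)))
  invisible(x)
}

#' Plot a phase diagram
#'
#' Image of the mean spread size over the `(x0, w)` grid with the
#' fluctuation region (cells with non-zero spread-size standard deviation)
#' outlined by points.
#'
#' @param x a `phase_diagram`.
#' @param what `"mean"` (mean spread size) or `"sd"` (its standard
#'   deviation).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.phase_diagram <- function(x, what = c("mean", "sd"), ...) {
  what <- match.arg(what)
  M <- if (what == "mean") x$mean_size else x$sd_size
  graphics::image(x$x0_grid, x$w_grid, t(M), xlab = "surround excitability x0",
                  ylab = "global coupling w",
                  main = if (what == "mean") "mean spread size"
                         else "spread-size SD", ...)
  fl <- which(x$sd_size > 0, arr.ind = TRUE)
  if (nrow(fl))
    graphics::points(x$x0_grid[fl[, 2]], x$w_grid[fl[, 1]], pch = 4)
  invisible(x)
}

#' Near-criticality fluctuation mask and spread-size distribution
#'
#' Identifies the cells of a phase diagram whose spread size fluctuates
#' across stochastic realizations (standard deviation above zero; these
#' concentrate near the no-spread/spread transition curve) and pools their
#' outcomes. Following the convention of the near-criticality analysis, the
#' pooled quantity is the number of recruited *surrounding* nodes (the
#' active EZ excluded; one less than the order-parameter spread size
#' whenever anything seized). The pooled distribution is summarized by the
#' fraction of probability mass in the two extreme bins: up to `k_small`
#' recruited surround nodes ("small or no spread") and at least
#' `(n - 1) - k_small` ("full network spread").
#'
#' @param diagram a `phase_diagram` with at least 2 realizations per cell.
#' @param k_small width of the extreme bins; defaults to 10 percent of the
#'   network, rounded up.
#' @param min_sd alternative minimum standard deviation defining the mask.
#' @return A list: logical `mask` matrix, pooled `sizes` (recruited surround
#'   nodes per realization), their relative frequency `histogram`,
#'   `extreme_mass` (fraction in the two extreme bins), `k_small`.
#' @export
near_criticality_stats <- function(diagram, k_small = NULL, min_sd = 0) {
  stopifnot(inherits(diagram, "phase_diagram"))
  if (diagram$n_realizations < 2)
    stop("need at least 2 realizations per cell to assess fluctuations")
  ns <- diagram$n_nodes - 1L # surrounding nodes
  if (is.null(k_small)) k_small <- ceiling(0.1 * diagram$n_nodes)
  mask <- !is.na(diagram$sd_size) & diagram$sd_size > min_sd
  if (!any(mask)) {
    return(list(mask = mask, sizes = integer(), histogram = NULL,
                extreme_mass = NA_real_, k_small = k_small))
  }
  rec <- diagram$records
  keep <- rep(FALSE, nrow(rec))
  for (idx in which(mask)) {
    iw <- (idx - 1) %% nrow(mask) + 1
    ix <- (idx - 1) %/% nrow(mask) + 1
    keep <- keep | (rec$w == diagram$w_grid[iw] &
                    rec$x0 == diagram$x0_grid[ix])
  }
  spread <- rec$spread_size[keep & !is.na(rec$spread_size)]
  sizes <- pmax(spread - 1L, 0L) # seizures start at the EZ
  h <- table(factor(sizes, levels = 0:ns)) / length(sizes)
  extreme <- sum(h[as.integer(names(h)) <= k_small]) +
    sum(h[as.integer(names(h)) >= ns - k_small])
  list(mask = mask, sizes = sizes, histogram = h,
       extreme_mass = as.numeric(extreme), k_small = k_small)
}

#' Score predicted recruitment ranks against simulated onsets
#'
#' Compares the stability-based recruitment ranking (`|v_z,i|` magnitudes)
#' with the true onset-time ranking in full-spread realizations. Rank 1 is
#' the node recruited first. Realizations with partial spread are filtered
#' out with a warning, matching the evaluation protocol: rank statistics are
#' defined over seizures that spread to the full network.
#'
#' @param outcomes a list of `spread_outcome` objects (one per realization).
#' @param report a `stability_report` with `predicted_phase == "spread"`, or
#'   a rank table from [recruitment_ranks()].
#' @return An object of class `rank_evaluation`: per-realization rank tables,
#'   absolute errors, overall mean absolute error, per-true-rank mean error
#'   with empirical 95 percent bands, and mean-corrected onset times.
#' @export
evaluate_rank_prediction <- function(outcomes, report) {
  if (inherits(outcomes, "spread_outcome")) outcomes <- list(outcomes)
  pred <- if (inherits(report, "stability_report")) recruitment_ranks(report)
          else report
  stopifnot(is.data.frame(pred), all(c("node", "rank") %in% names(pred)))

  full <- vapply(outcomes, function(o) o$spread_size == o$n_nodes, TRUE)
  if (any(!full)) {
    warning(sum(!full), " partial-spread realization(s) filtered out")
    outcomes <- outcomes[full]
  }
  if (!length(outcomes)) stop("no full-spread realizations to evaluate")

  per <- lapply(seq_along(outcomes), function(k) {
    o <- outcomes[[k]]
    surround <- setdiff(seq_len(o$n_nodes), o$active_ez)
    ot <- o$onset_times[surround]
    true_rank <- rank(ot, ties.method = "first")
    m <- merge(data.frame(node = surround, true_rank = true_rank,
                          onset_time = ot,
                          onset_centered = ot - mean(ot)),
               pred[, c("node", "rank")], by = "node")
    names(m)[names(m) == "rank"] <- "predicted_rank"
    m$abs_error <- abs(m$true_rank - m$predicted_rank)
    m$realization <- k
    m
  })
  tab <- do.call(rbind, per)
  by_rank <- split(tab$abs_error, tab$true_rank)
  per_rank <- data.frame(
    true_rank = as.integer(names(by_rank)),
    mean_abs_error = vapply(by_rank, mean, 0),
    q025 = vapply(by_rank, stats::quantile, 0, probs = 0.025),
    q975 = vapply(by_rank, stats::quantile, 0, probs = 0.975),
    row.names = NULL)
  structure(list(table = tab, per_rank = per_rank,
                 mean_abs_error = mean(tab$abs_error),
                 n_realizations = length(outcomes)),
            class = "rank_evaluation")
}

#' @export
print.rank_evaluation <- function(x, ...) {
  cat(sprintf("Rank prediction over %d full-spread realization(s): MAE = %.3f\n",
              x$n_realizations, x$mean_abs_error))
  invisible(x)
}

#' Associations between onsets, connectivity and eigenvector magnitudes
#'
#' For full-spread outcomes, relates (i) mean-corrected seizure onset times
#' to the direct coupling weight `W[i, EZ]`, (ii) onset times to the shortest
#' path length from the EZ, and (iii) the leading-eigenvector magnitudes
#' `|v_z,i|` to `W[i, EZ]`. Onset times are mean-corrected per realization
#' (the realization's average onset is subtracted) to remove run-to-run
#' shifts in seizure start. Spearman rank correlations are reported, and for
#' the strictly positive pairs a log-log least-squares fit with a 95 percent
#' confidence interval on the slope.
#'
#' @param outcomes list of full-spread `spread_outcome` objects.
#' @param connectome the [connectome] the outcomes were simulated on.
#' @param active_ez active EZ node index.
#' @param report optional `stability_report` supplying `|v_z,i|`.
#' @param cost edge-cost transform for shortest paths (see [graph_metrics()]).
#' @return A list of association tables: `per_node` data and `correlations`
#'   (one row per relation: Spearman rho, log-log slope and CI where
#'   defined).
#' @export
onset_covariates <- function(outcomes, connectome, active_ez = NULL,
                             report = NULL, cost = "inverse") {
  if (inherits(outcomes, "spread_outcome")) outcomes <- list(outcomes)
  if (is.null(active_ez)) active_ez <- outcomes[[1]]$active_ez
  full <- vapply(outcomes, function(o) o$spread_size == o$n_nodes, TRUE)
  if (any(!full)) {
    warning(sum(!full), " partial-spread realization(s) filtered out")
    outcomes <- outcomes[full]
  }
  if (!length(outcomes)) stop("no full-spread realizations")
  n <- connectome$n_nodes
  surround <- setdiff(seq_len(n), active_ez)
  gm <- graph_metrics(connectome, active_ez, cost = cost)

  per_node <- do.call(rbind, lapply(seq_along(outcomes), function(k) {
    o <- outcomes[[k]]
    ot <- o$onset_times[surround]
    data.frame(realization = k, node = surround,
               onset_centered = ot - mean(ot),
               w_ez = connectome$weights[surround, active_ez],
               path_length = gm$shortest_path_length_to_ez[surround])
  }))
  if (!is.null(report)) {
    vz <- report$v_z[as.character(per_node$node)]
    per_node$v_z <- as.numeric(vz)
  }

  assoc <- function(x, y, name) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(relation = name, spearman = NA_real_,
                        loglog_slope = NA_real_, slope_lo = NA_real_,
                        slope_hi = NA_real_))
    rho <- stats::cor(x, y, method = "spearman")
    pos <- x > 0 & y > 0
    if (sum(pos) >= 3) {
      fit <- stats::lm(log(y[pos]) ~ log(x[pos]))
      ci <- stats::confint(fit)[2, ]
      data.frame(relation = name, spearman = rho,
                 loglog_slope = unname(stats::coef(fit)[2]),
                 slope_lo = ci[1], slope_hi = ci[2])
    } else {
      data.frame(relation = name, spearman = rho, loglog_slope = NA_real_,
                 slope_lo = NA_real_, slope_hi = NA_real_)
    }
  }
  spearman_row <- function(x, y, name) {
    rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
           else stats::cor(x, y, method = "spearman")
    data.frame(relation = name, spearman = rho, loglog_slope = NA_real_,
               slope_lo = NA_real_, slope_hi = NA_real_)
  }
  rows <- list(
    spearman_row(per_node$w_ez, per_node$onset_centered, "onset_vs_w_ez"),
    spearman_row(per_node$path_length, per_node$onset_centered,
                 "onset_vs_path"))
  if (!is.null(report))
    rows[[3]] <- assoc(per_node$w_ez, per_node$v_z, "v_z_vs_w_ez")
  correlations <- do.call(rbind, rows)
  row.names(correlations) <- NULL
  list(per_node = per_node, correlations = correlations)
}
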