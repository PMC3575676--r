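#' Run one simulation
#'
#' Advances the network iteration by iteration: nonsynaptic state update,
#' membrane potential (with stimulus and, when active, the GABAa weight
#' modulation), firing probability, stochastic state sampling, running
#' activity average and coincidence counting.  At the end of every
#' morphogenetic window (150 iterations) the structural rules run: the
#' compensation step, then the Hebbian and anti-Hebbian updates.  One
#' simulated day spans 4000 iterations of 0.36 min.
#'
#' @param config a [dg_config()].
#' @param protocol a [dg_protocol()].
#' @param rho Hebbian gain, `0 <= rho < 0.5` (0 disables Hebbian rewiring).
#' @param v morphogenesis speed, `0 <= v <= 0.1` (0 disables compensation).
#' @param mu anti-Hebbian gain.  Defaults to `rho / 5`, the strongest
#'   depression for which the epileptogenic transition still occurs: with
#'   `mu` near `rho`, unpreceded discharges outnumber coincidences at the
#'   moderate activities of the post-ictal recovery (`lambda > eta` whenever
#'   firing probabilities are below one half), depression cancels
#'   potentiation, and the sprouted granule-cell synapses can never ratchet
#'   the network into spontaneous events.
#' @param days simulated days; defaults to `protocol$total_days`.
#' @param seed integer seed for the run (defaults to `config$seed`; `NULL`
#'   continues the current RNG stream).
#' @param substeps plasticity sub-increment count per morphogenetic step, or
#'   `"auto"` (default; see [apply_hebbian()]).
#' @param k_fpr_H optional override of the free-presynaptic production rate
#'   (see [kinetic_rates()]).
#' @param verbose print one progress line per simulated day.
#' @return An object of class `dg_sim`: per-iteration mean average activity
#'   by cell type (`type_activity`), per-window summaries including the nine
#'   group mean connectivities (`window`), detected activity events
#'   (`events`, with spontaneous ones flagged), the initial and final
#'   connection matrices, and the run metadata.
#' @examples
#' sim <- run_simulation(days = 0.5, seed = 1)
#' summary(sim)
#' @export
run_simulation <- function(config = dg_config(),
                           protocol = dg_protocol("rest"),
                           rho = 0, v = 0, mu = rho / 5,
                           days = protocol$total_days,
                           seed = config$seed,
                           substeps = "auto",
                           k_fpr_H = NULL,
                           verbose = FALSE) {
  validate_dg_config(config)
  if (rho < 0 || rho >= 0.5) stop("`rho` must satisfy 0 <= rho < 0.5", call. = FALSE)
  if (v < 0 || v > 0.1) stop("`v` must satisfy 0 <= v <= 0.1", call. = FALSE)
  if (mu < 0) stop("`mu` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- config$n_total
  W <- config$morphogenetic_window
  ipd <- round(1440 / config$iteration_minutes)      # iterations per day
  T_ <- as.integer(round(days * ipd))
  if (T_ < 1) stop("`days` too small: no iterations to run", call. = FALSE)
  gc <- gc_idx(config); mc <- mc_idx(config); inn <- in_idx(config)
  kappa_vec <- kappa_by_target(config)
  graded <- config$drive == "probability"

  # --- RNG draw order: topology, initial states, GABAa targets, iterations
  C <- build_initial_connectivity(config)
  C_init <- C
  z <- as.numeric(stats::runif(n) < config$init_activity)
  gab <- NULL
  if (protocol$scenario == "stimulation_gabaa") {
    gab <- select_gabaa_targets(config, protocol)
  }

  rates <- if (is.null(k_fpr_H)) kinetic_rates(v) else kinetic_rates(v, k_fpr_H)
  pools <- element_pools(C, config)
  np <- config$ns
  dt <- if (config$ns_unit == "iteration") 1 else config$iteration_minutes
  use_avg <- config$ns_activity == "average"

  alpha_all <- stimulation_schedule(seq_len(T_), protocol, config)
  stim_range <- if (any(alpha_all > 0)) range(which(alpha_all > 0)) else NULL
  phi_def <- NULL
  if (!is.null(gab)) {
    t_days_all <- (seq_len(T_) - 0.5) * config$iteration_minutes / 1440
    phi_def <- config$phi - gabaa_weight(t_days_all, config$phi, protocol)
  }

  build_A <- function(C) {
    A <- C
    A[, gc] <- A[, gc, drop = FALSE] * config$tau
    A[, mc] <- A[, mc, drop = FALSE] * kappa_vec
    A[, inn] <- -config$phi * A[, inn, drop = FALSE]
    A
  }
  A <- build_A(C)
  Cin_mod <- if (!is.null(gab)) C[, inn, drop = FALSE] * gab$mask else NULL

  nse <- numeric(n); nsi <- numeric(n); rnse <- numeric(n); rnsi <- numeric(n)
  repol <- logical(n)
  Pbuf <- matrix(0, W, n); Zbuf <- matrix(0, W, n)
  ssum <- numeric(n); nfill <- 0L
  s <- rep(config$activity_setpoint, n)
  p <- rep(config$init_activity, n)
  z0w <- z                                  # state preceding the current window

  type_act <- matrix(NA_real_, T_, 3, dimnames = list(NULL, c("GC", "MC", "IN")))
  n_win <- T_ %/% W
  win_rec <- matrix(NA_real_, n_win, 15)
  colnames(win_rec) <- c("network", "GC", "MC", "IN", group_labels(),
                         "nse_mean", "nsi_mean")
  win <- 0L

  theta <- config$theta; beta <- config$beta
  a <- np$a; b <- np$b; cc <- np$c; dd <- np$d; ff <- np$f
  ebar <- np$e_bar; grep_ <- np$g_rep; hrep <- np$h_rep
  ll <- np$l; mm <- np$m; Lthr <- np$L
  nfl <- np$nse_floor; ifl <- np$nsi_floor
  sat0 <- np$nse_sat; satw <- np$sat_scale
  pump_active <- identical(np$pump_recovery, "active")
  do_morph <- v > 0
  do_plast <- rho > 0 || mu > 0

  for (t in seq_len(T_)) {
    sdrv <- if (use_avg) s else p
    in_rep <- (repol | nse < nsi) & nse > nfl
    sus <- !in_rep & (sdrv > Lthr) & (nse >= nsi)
    h <- numeric(n); k <- numeric(n)
    if (any(sus)) {
      ds <- sdrv[sus] - 0.25
      h[sus] <- ebar * ds * ds * (1 - tanh((nse[sus] - sat0) / satw))
      k[sus] <- ff * nse[sus]
    }
    if (any(in_rep)) {
      h[in_rep] <- -grep_ * rnse[in_rep] * (nse[in_rep] > nfl)
      if (pump_active) {
        k[in_rep] <- -hrep * rnsi[in_rep] * (nsi[in_rep] > ifl)
      }
    }
    nse <- pmax(nse + dt * (h - cc * nse), 0)
    nsi <- pmax(nsi + dt * (k - dd * nsi), 0)
    rnse <- ifelse(nse > nfl, pmin(rnse + dt * ll * (1 - rnse), 1), 0)
    rnsi <- ifelse(nsi > ifl, pmin(rnsi + dt * mm * (1 - rnsi), 1), 0)
    repol <- in_rep & nse > nfl

    drv <- if (graded) p else z
    mp <- drop(A %*% drv) + (a * nse - b * nsi)
    if (!is.null(phi_def) && phi_def[t] > 1e-9) {
      mp <- mp + phi_def[t] * drop(Cin_mod %*% drv[inn])
    }
    p <- 1 / (1 + exp((mp + alpha_all[t] - theta) / (-beta)))
    z <- as.numeric(stats::runif(n) < p)

    bi <- (t - 1L) %% W + 1L
    if (nfill < W) {
      nfill <- nfill + 1L
      ssum <- ssum + p
    } else {
      ssum <- ssum + p - Pbuf[bi, ]
    }
    Pbuf[bi, ] <- p
    Zbuf[bi, ] <- z
    s <- ssum / nfill
    type_act[t, ] <- c(mean(s[gc]), mean(s[mc]), mean(s[inn]))

    if (bi == W) {
      win <- win + 1L
      if (!all(is.finite(s)) || !all(is.finite(nse))) {
        stop(sprintf("non-finite state at iteration %d (window %d)", t, win),
             call. = FALSE)
      }
      changed <- FALSE
      if (do_morph || any(pools$fpr > 0) || any(pools$fepo > 0) || any(pools$fipo > 0)) {
        step <- morphogenetic_step(C, pools, s, rates, config)
        C <- step$C; pools <- step$pools
        changed <- TRUE
      }
      if (do_plast) {
        counters <- window_counters(Zbuf, z0w)
        delta_s <- morphogenetic_state(s, config$activity_setpoint)
        C2 <- apply_plasticity(C, delta_s, s, counters, rho, mu,
                               high = config$high_threshold, substeps = substeps,
                               n_excitatory = config$n_excitatory)
        if (!identical(C2, C)) {
          C <- C2
          pools$bpr <- colSums(C)
          pools$bepo <- rowSums(C[, exc_idx(config), drop = FALSE])
          pools$bipo <- rowSums(C[, inn, drop = FALSE])
          changed <- TRUE
        }
      }
      if (changed) {
        A <- build_A(C)
        if (!is.null(gab)) Cin_mod <- C[, inn, drop = FALSE] * gab$mask
      }
      win_rec[win, ] <- c(mean(s), mean(s[gc]), mean(s[mc]), mean(s[inn]),
                          vapply(group_labels(), function(g) {
                            blk <- group_block(config, g)
                            mean(C[blk$rows, blk$cols])
                          }, numeric(1)),
                          mean(nse), mean(nsi))
      z0w <- z
      if (verbose && (t %% ipd == 0)) {
        message(sprintf("day %d: network activity %.3f", t %/% ipd, mean(s)))
      }
    }
  }

  window <- data.frame(step = seq_len(n_win),
                       end_iteration = seq_len(n_win) * W,
                       win_rec, check.names = FALSE)
  events <- detect_sica(window$network,
                        step_iterations = W,
                        iteration_minutes = config$iteration_minutes,
                        stim_window = stim_range)

  structure(list(
    config = config, protocol = protocol,
    rho = rho, v = v, mu = mu, seed = seed,
    days = days, iterations = T_,
    type_activity = type_act,
    window = window,
    events = events,
    sica_events = events[!events$stimulus_triggered, , drop = FALSE],
    C_init = C_init, C_final = C,
    s_final = s,
    ns_final = structure(list(nse = nse, nsi = nsi, r_nse = rnse,
                              r_nsi = rnsi, repol = repol),
                         class = "dg_ns_state"),
    pools = pools,
    gabaa_targets = gab,
    stim_window = stim_range
  ), class = "dg_sim")
}

#' @export
print.dg_sim <- function(x, ...) {
  cat(sprintf("dg_sim: %s scenario, %g days (%d iterations), rho = %g, v = %g, mu = %g\n",
              x$protocol$scenario, x$days, x$iterations, x$rho, x$v, x$mu))
  cat(sprintf("  final network activity: %.3f\n", utils::tail(x$window$network, 1)))
  cat(sprintf("  events: %d detected (%d spontaneous)\n",
              nrow(x$events), nrow(x$sica_events)))
  invisible(x)
}

#' @export
summary.dg_sim <- function(object, ...) {
  last_day <- floor(object$days)
  out <- list(
    scenario = object$protocol$scenario,
    days = object$days, rho = object$rho, v = object$v, mu = object$mu,
    mean_activity = mean(object$window$network),
    sica_count = nrow(object$sica_events),
    activity_change = if (last_day >= 2) {
      vapply(c("GC", "MC", "IN"), function(ty)
        activity_change(object, type = ty, day_cmp = last_day), numeric(1))
    } else NULL,
    connectivity_change = if (last_day >= 2) {
      vapply(group_labels(), function(g)
        connectivity_change(object, g, day_cmp = last_day), numeric(1))
    } else NULL
  )
  class(out) <- "summary.dg_sim"
  out
}

#' @export
print.summary.dg_sim <- function(x, ...) {
  cat(sprintf("%s scenario, %g days (rho = %g, v = %g, mu = %g)\n",
              x$scenario, x$days, x$rho, x$v, x$mu))
  cat(sprintf("mean network activity: %.3f; spontaneous events: %d\n",
              x$mean_activity, x$sica_count))
  if (!is.null(x$activity_change)) {
    cat(sprintf("activity change day 1 -> day %d (%%): GC %+.3g, MC %+.3g, IN %+.3g\n",
                floor(x$days), x$activity_change["GC"], x$activity_change["MC"],
                x$activity_change["IN"]))
    cat("group mean connectivity change:\n")
    print(round(x$connectivity_change, 4))
  }
  invisible(x)
}

#' @export
plot.dg_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  d <- x$window$end_iteration * x$config$iteration_minutes / 1440
  graphics::plot(d, x$window$network, type = "l", xlab = "day",
                 ylab = "mean activity", main = "network activity", ...)
  graphics::abline(h = c(x$config$low_threshold, x$config$high_threshold),
                   lty = 3, col = "grey50")
  grp <- c("I", "IV", "VII")
  cols <- c("forestgreen", "steelblue", "firebrick")
  graphics::matplot(d, as.matrix(x$window[, grp]), type = "l", lty = 1,
                    col = cols, xlab = "day", ylab = "mean weight",
                    main = "group mean connectivity")
  graphics::legend("topleft", legend = paste("group", grp), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Percentage activity change between two days
#'
#' `100 * (mean over day_cmp - mean over day_ref) / mean over day_ref` of
#' the per-iteration mean average activity of a cell type.
#'
#' @param sim a `dg_sim`.
#' @param type `"GC"`, `"MC"`, `"IN"` or `"network"`.
#' @param day_ref,day_cmp day indices (1-based; day `d` spans iterations
#'   `(d-1)*4000 + 1` to `d*4000`).
#' @return Percentage change.
#' @export
activity_change <- function(sim, type = "GC", day_ref = 1, day_cmp = 41) {
  ipd <- round(1440 / sim$config$iteration_minutes)
  day_rows <- function(d) {
    if (d * ipd > sim$iterations) {
      stop(sprintf("day %g outside the simulated range", d), call. = FALSE)
    }
    ((d - 1) * ipd + 1):(d * ipd)
  }
  tr <- if (type == "network") {
    w <- c(sim$config$n_granule, sim$config$n_mossy, sim$config$n_interneuron)
    drop(sim$type_activity %*% w) / sum(w)
  } else {
    sim$type_activity[, type]
  }
  ref <- mean(tr[day_rows(day_ref)])
  cmp <- mean(tr[day_rows(day_cmp)])
  100 * (cmp - ref) / ref
}

#' Group mean connectivity change between two days
#'
#' Difference of the group's mean weight between the last morphogenetic step
#' of `day_cmp` and of `day_ref`.
#'
#' @inheritParams activity_change
#' @param group roman-numeral group label.
#' @return Change in mean weight.
#' @export
connectivity_change <- function(sim, group, day_ref = 1, day_cmp = 41) {
  stopifnot(group %in% group_labels())
  ipd <- round(1440 / sim$config$iteration_minutes)
  pick <- function(d) {
    i <- max(which(sim$window$end_iteration <= d * ipd))
    if (!is.finite(i)) stop(sprintf("day %g has no completed window", d), call. = FALSE)
    sim$window[[group]][i]
  }
  pick(day_cmp) - pick(day_ref)
}
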