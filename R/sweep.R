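#' Sweep the plasticity-gain plane
#'
#' Runs the given protocol over a grid of Hebbian gains `rho` and
#' morphogenesis speeds `v`, with several seeded replicates per grid point,
#' and tabulates for each run the spontaneous event (SICA) count, the
#' percentage activity change of each cell type between `day_ref` and
#' `day_cmp`, and the change in mean connectivity of each of the nine
#' groups.
#'
#' @param config a [dg_config()].
#' @param protocol a [dg_protocol()].
#' @param rho_grid,v_grid numeric grids (`0 <= rho < 0.5`, `0 <= v <= 0.1`).
#' @param replicates seeded replicates per grid point.
#' @param days simulated days per run.
#' @param day_ref,day_cmp days compared by the change metrics.
#' @param seed base seed; run `r` of grid point `g` uses
#'   `seed + 1000 * (g - 1) + r`.
#' @param mu anti-Hebbian gain; default ties it to each run's `rho` as
#'   `rho / 5` (see [run_simulation()]).
#' @param verbose print a line per completed run.
#' @return data.frame with one row per (rho, v, replicate).
#' @export
sweep_parameters <- function(config = dg_config(),
                             protocol = dg_protocol("rest"),
                             rho_grid, v_grid, replicates = 3,
                             days = protocol$total_days,
                             day_ref = 1, day_cmp = 41,
                             seed = 1, mu = NULL, verbose = FALSE) {
  if (length(rho_grid) == 0 || length(v_grid) == 0) {
    stop("`rho_grid` and `v_grid` must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(rho = rho_grid, v = v_grid, replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- (i - 1) %/% replicates + 1
    run_seed <- as.integer(seed + 1000 * (which(rho_grid == grid$rho[i]) - 1 +
                           length(rho_grid) * (which(v_grid == grid$v[i]) - 1)) +
                           grid$replicate[i])
    sim <- run_simulation(config, protocol,
                          rho = grid$rho[i], v = grid$v[i],
                          mu = if (is.null(mu)) grid$rho[i] / 5 else mu,
                          days = days, seed = run_seed)
    ac <- vapply(c("GC", "MC", "IN"), function(ty)
      activity_change(sim, ty, day_ref, min(day_cmp, floor(days))), numeric(1))
    cc <- vapply(group_labels(), function(gr)
      connectivity_change(sim, gr, day_ref, min(day_cmp, floor(days))), numeric(1))
    res[[i]] <- data.frame(rho = grid$rho[i], v = grid$v[i],
                           replicate = grid$replicate[i], seed = run_seed,
                           sica_count = nrow(sim$sica_events),
                           act_GC = ac[["GC"]], act_MC = ac[["MC"]], act_IN = ac[["IN"]],
                           t(stats::setNames(cc, paste0("dconn_", group_labels()))))
    if (verbose) {
      message(sprintf("rho = %g, v = %g, rep %d: %d SICA, GC %+0.2f%%",
                      grid$rho[i], grid$v[i], grid$replicate[i],
                      res[[i]]$sica_count, res[[i]]$act_GC))
    }
  }
  do.call(rbind, res)
}
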