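test_that("with all plasticity disabled the matrix never changes", {
  sim <- run_simulation(rho = 0, v = 0, days = 1, seed = 51)
  expect_identical(sim$C_final, sim$C_init)
  expect_equal(nrow(sim$events), 0)
})

test_that("the resting network holds the stability band over 50,000 iterations", {
  sim <- run_simulation(rho = 0, v = 0, days = 12.5, seed = 53)
  expect_gte(min(sim$window$network), 0.15)
  expect_lte(max(sim$window$network), 0.25)
  expect_gte(mean(sim$window$network), 0.15)
  expect_lte(mean(sim$window$network), 0.25)
})

test_that("runs are exactly reproducible from their seed", {
  a <- run_simulation(rho = 0.2182, v = 0.1, days = 0.5, seed = 57)
  b <- run_simulation(rho = 0.2182, v = 0.1, days = 0.5, seed = 57)
  expect_identical(a$type_activity, b$type_activity)
  expect_identical(a$C_final, b$C_final)
})

# Reference path: the exported operations composed step by step, consuming
# the RNG in the simulator's documented draw order.
composed_reference <- function(cfg, prot, rho, v, mu, iters, seed) {
  set.seed(seed)
  n <- cfg$n_total
  W <- cfg$morphogenetic_window
  C <- build_initial_connectivity(cfg)
  z <- as.numeric(runif(n) < cfg$init_activity)
  rates <- kinetic_rates(v)
  pools <- element_pools(C, cfg)
  st <- ns_state(n)
  p <- rep(cfg$init_activity, n)
  Phist <- matrix(NA_real_, iters, n)
  Zwin <- matrix(NA_real_, W, n)
  z0w <- z
  s <- rep(cfg$activity_setpoint, n)
  for (t in seq_len(iters)) {
    st <- step_nonsynaptic(st, p, cfg$ns, dt = 1)
    mp <- membrane_potential(C, p, ns_effect(st, cfg$ns), cfg)
    p <- firing_probability(mp, stimulation_schedule(t, prot, cfg), cfg)
    z <- as.numeric(sample_states(p))
    Phist[t, ] <- p
    s <- update_activity_average(Phist[1:t, , drop = FALSE], W)
    Zwin[(t - 1) %% W + 1, ] <- z
    if (t %% W == 0) {
      cnt <- init_counters(n)
      prev <- z0w
      for (k in 1:W) {
        cnt <- accumulate_counters(cnt, prev, Zwin[k, ])
        prev <- Zwin[k, ]
      }
      step <- morphogenetic_step(C, pools, s, rates, cfg)
      C <- step$C; pools <- step$pools
      C <- dgnet:::apply_plasticity(C, morphogenetic_state(s), s, cnt, rho, mu,
                                    high = cfg$high_threshold,
                                    substeps = "auto",
                                    n_excitatory = cfg$n_excitatory)
      z0w <- z
    }
  }
  list(C = C, s = unname(s), st = st)
}

test_that("the simulator loop equals the composed operations on the plastic path", {
  # narrow neutral band so compensation and the coincidence rules both act;
  # weak stimulus keeps the sodium dynamics disengaged, so the trajectory is
  # numerically stable and the two code paths must agree to round-off
  cfg <- dg_config(n_granule = 9L, n_mossy = 1L, n_interneuron = 1L,
                   gc_afferents = 3L,
                   low_threshold = 0.195, high_threshold = 0.205)
  prot <- dg_protocol("stimulation", stim_onset_day = 200 / 4000, alpha = 0.3)
  rho <- 0.2182; v <- 0.1; mu <- rho / 5
  sim <- run_simulation(cfg, prot, rho = rho, v = v, mu = mu,
                        days = 300 / 4000, seed = 61)
  ref <- composed_reference(cfg, prot, rho, v, mu, iters = 300, seed = 61)
  expect_false(identical(sim$C_final, sim$C_init))  # plasticity really acted
  expect_equal(sim$C_final, ref$C, tolerance = 1e-7)
  expect_equal(sim$s_final, ref$s, tolerance = 1e-7)
})

test_that("the simulator loop equals the composed operations through ignition", {
  # a full-strength stimulus engages the sodium dynamics; the saturating
  # influx term amplifies last-digit differences between summation orders,
  # so agreement is asserted at the accumulated-round-off scale
  cfg <- dg_config(n_granule = 9L, n_mossy = 1L, n_interneuron = 1L,
                   gc_afferents = 3L)
  prot <- dg_protocol("stimulation", stim_onset_day = 20 / 4000)
  sim <- run_simulation(cfg, prot, rho = 0.2182, v = 0.1,
                        days = 150 / 4000, seed = 61)
  ref <- composed_reference(cfg, prot, 0.2182, 0.1, 0.2182 / 5,
                            iters = 150, seed = 61)
  expect_gt(max(sim$ns_final$nse), 1)               # ignition happened
  expect_equal(sim$ns_final$nse, ref$st$nse, tolerance = 1e-6)
  expect_equal(sim$ns_final$nsi, ref$st$nsi, tolerance = 1e-6)
  expect_equal(sim$s_final, ref$s, tolerance = 1e-6)
  expect_equal(sim$C_final, ref$C, tolerance = 1e-6)
})

test_that("a suprathreshold stimulus ignites a terminating maximal-activation event", {
  sim <- run_simulation(protocol = dg_protocol("stimulation"),
                        rho = 0.2182, v = 0.1, days = 4, seed = 63)
  ev <- sim$events[sim$events$stimulus_triggered, , drop = FALSE]
  expect_equal(nrow(ev), 1)
  expect_gt(ev$peak_activity, 0.9)               # maximal activation
  # the event ends: activity returns below threshold before the run ends
  expect_lt(utils::tail(sim$window$network, 1), 0.2)
  # and the sodium dynamics engaged at onset, not before
  pre <- sim$window$nse_mean[sim$window$end_iteration < 6000]
  expect_true(all(pre == 0))
})

test_that("the transient GABAa shift uses its modified weights only when active", {
  cfg <- dg_config()
  # with zero targets the GABAa scenario must behave like plain stimulation
  p0 <- dg_protocol("stimulation_gabaa", n_target_granule = 0)
  sim0 <- run_simulation(config = cfg, protocol = p0, days = 0.2, seed = 67)
  expect_equal(sum(sim0$gabaa_targets$mask), 0)
  expect_equal(nrow(sim0$events), 0)

  # weight trace: before onset the modified weight equals phi
  prot <- dg_protocol("stimulation_gabaa")
  expect_equal(gabaa_weight(1.0, cfg$phi, prot), cfg$phi, tolerance = 1e-4)
})

test_that("activity and connectivity change metrics are consistent with the traces", {
  sim <- run_simulation(rho = 0, v = 0, days = 2, seed = 71)
  ipd <- 4000
  gc_trace <- sim$type_activity[, "GC"]
  ref <- 100 * (mean(gc_trace[4001:8000]) - mean(gc_trace[1:4000])) /
    mean(gc_trace[1:4000])
  expect_equal(activity_change(sim, "GC", 1, 2), ref, tolerance = 1e-12)
  expect_equal(connectivity_change(sim, "IV", 1, 2), 0)
  expect_error(activity_change(sim, "GC", 1, 10), "outside")
  s <- summary(sim)
  expect_s3_class(s, "summary.dg_sim")
  expect_output(print(s), "mean network activity")
})
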