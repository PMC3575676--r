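test_that("state classification follows the three-state machine", {
  p <- ns_params()
  st <- ns_state(3)
  st$nse <- c(1, 0.5, 0)
  st$nsi <- c(0, 1, 0)
  s <- c(0.5, 0.5, 0.1)
  expect_equal(classify_ns_state(s, st, p),
               c("sustained_depolarization", "in_repolarization", "polarized"))
})

test_that("repolarization is hysteretic until the influx drains", {
  p <- ns_params()
  st <- ns_state(1)
  st$nse <- 5; st$nsi <- 6                       # pump has overcome influx
  st <- step_nonsynaptic(st, s = 0.9, p, dt = 1)
  expect_equal(st$label, "in_repolarization")
  # influx now back below the pump level would re-engage without memory;
  # force that situation and check the state stays repolarizing
  st$nsi <- st$nse - 1
  st2 <- step_nonsynaptic(st, s = 0.9, p, dt = 1)
  expect_equal(st2$label, "in_repolarization")
  # drained influx polarizes even though the pump level is still high
  st2$nse <- 0.05
  st3 <- step_nonsynaptic(st2, s = 0.1, p, dt = 1)
  expect_equal(st3$label, "polarized")
  expect_false(st3$repol)
})

test_that("state-dependent rates match their closed forms", {
  p <- ns_params()
  st <- ns_state(1)

  expect_equal(ns_state_rates("polarized", 0.1, st, p), list(h = 0, k = 0))

  st$nse <- 1
  r <- ns_state_rates("sustained_depolarization", 0.25, st, p)
  expect_equal(r$h, 0)                           # (s - 0.25) factor vanishes
  expect_equal(r$k, p$f * 1)

  st$nse <- p$nse_sat                            # saturation factor = 1 - tanh(0)
  r <- ns_state_rates("sustained_depolarization", 0.5, st, p)
  expect_equal(r$h, p$e_bar * 0.25^2, tolerance = 1e-12)

  # active pump recovery drains NSI through its aid; passive does not
  st$nse <- 0.5; st$nsi <- 1; st$r_nse <- 0.7; st$r_nsi <- 0.4
  r_pas <- ns_state_rates("in_repolarization", 0.5, st, p)
  expect_equal(r_pas$h, -p$g_rep * 0.7)
  expect_equal(r_pas$k, 0)
  pa <- ns_params(pump_recovery = "active")
  r_act <- ns_state_rates("in_repolarization", 0.5, st, pa)
  expect_equal(r_act$k, -pa$h_rep * 0.4)
})

test_that("repolarization aids integrate and reset as specified", {
  p <- ns_params()
  st <- ns_state(2)
  st$nse <- c(0.05, 0.5)                         # below / above the floor
  st$r_nse <- c(0.3, 0)
  st <- step_repolarization_aux(st, p, dt = 0.36)
  expect_equal(st$r_nse[1], 0)
  expect_equal(st$r_nse[2], 0.36 * p$l * 1, tolerance = 1e-12)  # 0.01008

  st$r_nse <- c(0, 1)
  st <- step_repolarization_aux(st, p, dt = 0.36)
  expect_equal(st$r_nse[2], 1)                   # fixed point of (1 - r)
})

test_that("nonsynaptic Euler step decays, clamps and errors correctly", {
  p <- ns_params()
  st <- ns_state(1)
  st$nse <- 1
  dt <- 0.36
  st2 <- step_nonsynaptic(st, s = 0.1, p, dt)    # polarized: pure decay
  expect_equal(st2$nse, 1 * (1 - p$c * dt), tolerance = 1e-12)

  st0 <- ns_state(1)
  st0b <- step_nonsynaptic(st0, s = 0.1, p, dt)
  expect_equal(st0b$nse, 0)                      # rest state is absorbing
  expect_equal(st0b$nsi, 0)

  sus <- ns_state(1)
  sus1 <- step_nonsynaptic(sus, s = 0.5, p, dt)
  expect_gt(sus1$nse, 0)                         # influx engages above L

  expect_error(step_nonsynaptic(st, 0.1, p, dt = 0), "dt")
})

test_that("levels and aids never go negative along random trajectories", {
  p <- ns_params()
  set.seed(31)
  for (rep in 1:5) {
    st <- ns_state(4)
    for (t in 1:300) {
      s <- runif(4)
      st <- step_nonsynaptic(st, s, p, dt = 1)
      expect_true(all(st$nse >= 0) && all(st$nsi >= 0))
      expect_true(all(st$r_nse >= 0 & st$r_nse <= 1))
      expect_true(all(st$r_nsi >= 0 & st$r_nsi <= 1))
    }
  }
})

test_that("a forced excursion traverses the depolarization cycle", {
  p <- ns_params()
  st <- ns_state(1)
  labels <- character(0)
  for (t in 1:2600) {
    # rest, then a 600-iteration clamp at high activity, then release
    s <- if (t <= 100) 0.05 else if (t <= 700) 0.5 else 0.05
    st <- step_nonsynaptic(st, s, p, dt = 1)
    labels <- c(labels, st$label)
  }
  visited <- rle(labels)$values
  expect_equal(visited[1], "polarized")
  expect_true("sustained_depolarization" %in% visited)
  i_sus <- match("sustained_depolarization", visited)
  expect_true("in_repolarization" %in% visited[-seq_len(i_sus)])
  expect_equal(labels[length(labels)], "polarized")
})

test_that("polarized dynamics never raise the sodium levels", {
  p <- ns_params()
  st <- ns_state(1)
  st$nse <- 19; st$nsi <- 3                      # s below L: polarized
  for (t in 1:50) {
    prev <- c(st$nse, st$nsi)
    st <- step_nonsynaptic(st, s = 0.05, p, dt = 1)
    expect_equal(st$label, "polarized")
    expect_lte(st$nse, prev[1])
    expect_lte(st$nsi, prev[2])
  }
})

test_that("vectorized module equals the scalar reference to machine precision", {
  p <- ns_params()
  set.seed(41)
  s_seq <- c(rep(0.6, 300), rep(0.05, 800), runif(200))
  ref <- ns_scalar_reference(s_seq, p, dt = 1)
  st <- ns_state(1)
  got <- matrix(NA_real_, length(s_seq), 4)
  for (t in seq_along(s_seq)) {
    st <- step_nonsynaptic(st, s_seq[t], p, dt = 1)
    got[t, ] <- c(st$nse, st$nsi, st$r_nse, st$r_nsi)
  }
  expect_equal(got, ref, tolerance = 1e-14)
})

test_that("the nonsynaptic effect is the weighted level difference", {
  p <- ns_params()
  st <- ns_state(3)
  expect_equal(ns_effect(st, p), c(0, 0, 0))
  st$nse <- c(1, 1, 2); st$nsi <- c(0, 4, 1)
  expect_equal(ns_effect(st, p), c(0.8, 0.8 - 0.8, 1.6 - 0.2), tolerance = 1e-12)
})
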