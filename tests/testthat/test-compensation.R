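test_that("kinetic rates satisfy the published ratios for any closure", {
  for (kf in list(NULL, 0.9)) {
    r <- if (is.null(kf)) kinetic_rates(0.1) else kinetic_rates(0.1, k_fpr_H = kf)
    expect_equal(r$k_fipo_H, 0.1)
    expect_equal(r$k_fepo_L, 0.9)
    expect_equal(r$k_bpr_L, 0.033 * r$k_fpr_H, tolerance = 1e-12)
    expect_equal(r$k_bpr_L, 0.167 * r$k_fpr_L, tolerance = 1e-12)
    expect_equal(r$k_fepo_H, r$k_fpr_L)
    expect_equal(r$k_fipo_L, r$k_fpr_L)
    expect_equal(r$k_bepo_H, r$k_bpr_L)
    expect_equal(r$k_bipo_L, r$k_bpr_L)
  }
  r0 <- kinetic_rates(0)
  expect_true(all(unlist(r0) == 0))
  expect_error(kinetic_rates(-0.01), ">= 0")
})

test_that("morphogenetic state is the deviation from the setpoint", {
  expect_equal(morphogenetic_state(c(0.2, 0.3, 0)), c(0, 0.1, -0.2))
})

test_that("the rule table yields the published element changes", {
  cfg <- tiny_config()
  set.seed(2)
  C <- build_initial_connectivity(cfg)
  pools <- element_pools(C, cfg, fpr = rep(1, 4), fepo = rep(2, 4), fipo = rep(3, 4))
  rates <- kinetic_rates(0.1, k_fpr_H = 0.9)

  # neutral band: nothing moves
  d0 <- element_deltas(rep(0, 4), rep(0.2, 4), pools, rates)
  expect_true(all(unlist(d0) == 0))

  # hyperactive neuron: no presynaptic bound loss
  dh <- element_deltas(rep(0.1, 4), rep(0.3, 4), pools, rates)
  expect_equal(dh$bpr, rep(0, 4))
  expect_equal(dh$bepo, rep(-rates$k_bepo_H * 0.1, 4))
  expect_equal(dh$fipo, rep(rates$k_fipo_H * 0.1, 4))

  # hypoactive neuron: bound presynaptic loss -0.0297 * 0.1
  dl <- element_deltas(rep(-0.1, 4), rep(0.1, 4), pools, rates)
  expect_equal(dl$bpr, rep(-0.00297, 4), tolerance = 1e-12)
  expect_equal(dl$fpr, rep(-rates$k_fpr_L * 1 * 0.1, 4))
  expect_equal(dl$fepo, rep(rates$k_fepo_L * 0.1, 4))
})

test_that("bound decay scales synapses in proportion to their weight", {
  cfg <- tiny_config()
  n <- cfg$n_total
  zero <- list(bpr = numeric(n), bepo = numeric(n), bipo = numeric(n),
               fpr = numeric(n), fepo = numeric(n), fipo = numeric(n))

  # no deltas: identity
  set.seed(4)
  C <- build_initial_connectivity(cfg)
  pools <- element_pools(C, cfg)
  out <- apply_bound_decay(C, zero, pools, cfg)
  expect_equal(out$C, C)
  expect_true(all(out$degraded_post == 0))

  # single synapse, presynaptic loss 0.1 of a unit pool
  C1 <- matrix(0, n, n); C1[2, 1] <- 1
  p1 <- element_pools(C1, cfg)
  d1 <- zero; d1$bpr[1] <- -0.1
  out1 <- apply_bound_decay(C1, d1, p1, cfg)
  expect_equal(out1$C[2, 1], 0.9, tolerance = 1e-12)

  # two equal excitatory weights in one row share the postsynaptic loss
  C2 <- matrix(0, n, n); C2[1, 2] <- 1; C2[1, 3] <- 1
  p2 <- element_pools(C2, cfg)
  d2 <- zero; d2$bepo[1] <- -0.2
  out2 <- apply_bound_decay(C2, d2, p2, cfg)
  expect_equal(out2$C[1, 2], 0.9, tolerance = 1e-12)
  expect_equal(out2$C[1, 3], 0.9, tolerance = 1e-12)
  expect_equal(sum(out2$degraded_post[1, ]), 0.2, tolerance = 1e-12)
})

test_that("degraded postsynaptic weight is conserved into free presynaptic pools", {
  cfg <- penta_config()
  set.seed(8)
  for (rep in 1:10) {
    C <- build_initial_connectivity(cfg) * runif(1, 0.5, 2)
    pools <- element_pools(C, cfg, fpr = runif(5), fepo = runif(5), fipo = runif(5))
    s <- runif(5)
    deltas <- element_deltas(morphogenetic_state(s), s, pools, kinetic_rates(0.1))
    dec <- apply_bound_decay(C, deltas, pools, cfg)
    new_pools <- update_free_pools(pools, deltas, dec$degraded_post)
    transferred <- sum(new_pools$fpr - pmax(pools$fpr + deltas$fpr, 0))
    expect_equal(transferred, sum(dec$degraded_post), tolerance = 1e-10)
  }
})

test_that("recombination binds free elements and depletes the pools", {
  cfg <- tiny_config()
  n <- cfg$n_total
  C <- matrix(0, n, n)
  pools <- element_pools(C, cfg)

  # nothing free: identity
  out0 <- recombine_free_elements(C, pools, cfg)
  expect_equal(out0$C, C)

  # fpr_1 = 1 binds with fepo_2 = 2; denominators max(2, 1) = 2
  pools$fpr[1] <- 1; pools$fepo[2] <- 2
  out <- recombine_free_elements(C, pools, cfg)
  expect_equal(out$C[2, 1], 1.0, tolerance = 1e-12)
  expect_true(all(out$C >= 0))
  expect_equal(out$pools$fpr[1], 0)
  expect_equal(out$pools$fepo[2], 1.0, tolerance = 1e-12)
  expect_true(all(diag(out$C) == 0))
})

test_that("a full morphogenetic step is the identity when nothing drives it", {
  cfg <- tiny_config()
  set.seed(12)
  C <- build_initial_connectivity(cfg)
  pools <- element_pools(C, cfg)
  # v = 0: all rates zero
  out <- morphogenetic_step(C, pools, s = c(0.3, 0.1, 0.5, 0.2), kinetic_rates(0), cfg)
  expect_equal(out$C, C)
  # setpoint activity with empty free pools
  out2 <- morphogenetic_step(C, pools, s = rep(0.2, 4), kinetic_rates(0.1), cfg)
  expect_equal(out2$C, C)
})

test_that("a hyperactive neuron loses excitatory inputs and gains free inhibitory elements", {
  cfg <- tiny_config()
  set.seed(13)
  C <- build_initial_connectivity(cfg)
  pools <- element_pools(C, cfg)
  s <- c(0.4, 0.2, 0.2, 0.2)
  out <- morphogenetic_step(C, pools, s, kinetic_rates(0.1), cfg)
  expect_lt(out$pools$bepo[1], pools$bepo[1])
  expect_gt(out$pools$fipo[1], 0)
  expect_true(all(out$C >= 0))
})

test_that("the composed step matches an independent straight-line oracle", {
  cfg <- tiny_config()
  set.seed(14)
  for (rep in 1:5) {
    C <- build_initial_connectivity(cfg)
    fpr <- runif(4); fepo <- runif(4); fipo <- runif(4)
    s <- runif(4, 0, 0.6)
    rates <- kinetic_rates(0.1)
    got <- morphogenetic_step(C, element_pools(C, cfg, fpr, fepo, fipo), s, rates, cfg)
    ref <- morph_step_oracle(C, fpr, fepo, fipo, s, rates, cfg)
    expect_equal(got$C, ref$C, tolerance = 1e-12)
    expect_equal(got$pools$fpr, ref$fpr, tolerance = 1e-12)
    expect_equal(got$pools$fepo, ref$fepo, tolerance = 1e-12)
    expect_equal(got$pools$fipo, ref$fipo, tolerance = 1e-12)
  }
})

test_that("compensation alone keeps activity deviations from trending upward", {
  sim <- run_simulation(rho = 0, v = 0.02, days = 50 * 150 / 4000, seed = 19)
  dev <- abs(sim$window$network - 0.2)
  fit <- stats::lm(dev ~ seq_along(dev))
  expect_lte(unname(coef(fit)[2]), 1e-4)
})
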