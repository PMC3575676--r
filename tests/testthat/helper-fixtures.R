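# Small networks and independent reference implementations used as oracles.

# Report every expectation; the end-to-end reproduction checks carry several
# documented quantitative mismatches and must not truncate the run.
testthat::set_max_fails(Inf)

# A 4-neuron circuit (2 GC, 1 MC, 1 IN) with afferent sampling reduced to fit.
tiny_config <- function(...) {
  dg_config(n_granule = 2L, n_mossy = 1L, n_interneuron = 1L,
            gc_afferents = 1L, ...)
}

# 5-neuron circuit (3 GC, 1 MC, 1 IN).
penta_config <- function(...) {
  dg_config(n_granule = 3L, n_mossy = 1L, n_interneuron = 1L,
            gc_afferents = 2L, ...)
}

# Naive triple-loop membrane potential, written directly from the drive
# definition: tau for granule inputs, kappa by target population for mossy
# inputs, -phi for interneuron inputs, plus the nonsynaptic effect.
mp_loop_oracle <- function(C, z, ns, cfg) {
  n <- cfg$n_total
  gc <- seq_len(cfg$n_granule)
  mc <- cfg$n_granule + seq_len(cfg$n_mossy)
  inn <- cfg$n_excitatory + seq_len(cfg$n_interneuron)
  out <- numeric(n)
  for (i in seq_len(n)) {
    kap <- if (cfg$kappa_rule == "granule_target") {
      if (i <= cfg$n_granule) cfg$kappa1 else cfg$kappa2
    } else {
      if (i <= cfg$n_excitatory) cfg$kappa1 else cfg$kappa2
    }
    acc <- 0
    for (j in gc) acc <- acc + cfg$tau * C[i, j] * z[j]
    for (j in mc) acc <- acc + kap * C[i, j] * z[j]
    for (j in inn) acc <- acc - cfg$phi * C[i, j] * z[j]
    out[i] <- acc + ns[i]
  }
  out
}

# Scalar straight-line nonsynaptic reference for a single neuron, passive
# pump recovery.  Returns the trajectory of (nse, nsi, r_nse, r_nsi) under a
# given activity sequence.
ns_scalar_reference <- function(s_seq, p, dt) {
  nse <- 0; nsi <- 0; rn <- 0; ri <- 0; repol <- FALSE
  out <- matrix(NA_real_, length(s_seq), 4)
  for (t in seq_along(s_seq)) {
    s <- s_seq[t]
    in_rep <- (repol || nse < nsi) && nse > p$nse_floor
    sus <- !in_rep && s > p$L && nse >= nsi
    if (sus) {
      h <- p$e_bar * (s - 0.25)^2 * (1 - tanh((nse - p$nse_sat) / p$sat_scale))
      k <- p$f * nse
    } else if (in_rep) {
      h <- -p$g_rep * rn * (nse > p$nse_floor)
      k <- if (identical(p$pump_recovery, "active")) {
        -p$h_rep * ri * (nsi > p$nsi_floor)
      } else 0
    } else {
      h <- 0; k <- 0
    }
    nse <- max(nse + dt * (h - p$c * nse), 0)
    nsi <- max(nsi + dt * (k - p$d * nsi), 0)
    rn <- if (nse > p$nse_floor) min(rn + dt * p$l * (1 - rn), 1) else 0
    ri <- if (nsi > p$nsi_floor) min(ri + dt * p$m * (1 - ri), 1) else 0
    repol <- in_rep && nse > p$nse_floor
    out[t, ] <- c(nse, nsi, rn, ri)
  }
  out
}

# Straight-line compensation step: a direct loop transcription of the rule
# table, bound decay, element transfer and recombination for one step.
morph_step_oracle <- function(C, fpr, fepo, fipo, s, rates, cfg) {
  n <- cfg$n_total
  ne <- cfg$n_excitatory
  ds <- s - cfg$activity_setpoint
  bpr <- colSums(C)
  bepo <- rowSums(C[, 1:ne, drop = FALSE])
  bipo <- rowSums(C[, (ne + 1):n, drop = FALSE])

  d_bpr <- d_bepo <- d_bipo <- d_fpr <- d_fepo <- d_fipo <- numeric(n)
  for (i in seq_len(n)) {
    if (s[i] > cfg$high_threshold) {
      d_bepo[i] <- -rates$k_bepo_H * abs(ds[i])
      d_fpr[i] <- rates$k_fpr_H * abs(ds[i])
      d_fepo[i] <- -rates$k_fepo_H * fepo[i] * abs(ds[i])
      d_fipo[i] <- rates$k_fipo_H * abs(ds[i])
    } else if (s[i] < cfg$low_threshold) {
      d_bpr[i] <- -rates$k_bpr_L * abs(ds[i])
      d_bipo[i] <- -rates$k_bipo_L * abs(ds[i])
      d_fpr[i] <- -rates$k_fpr_L * fpr[i] * abs(ds[i])
      d_fepo[i] <- rates$k_fepo_L * abs(ds[i])
      d_fipo[i] <- -rates$k_fipo_L * fipo[i] * abs(ds[i])
    }
  }
  C1 <- C
  for (j in seq_len(n)) if (bpr[j] > 0) {
    C1[, j] <- C[, j] * max(1 + d_bpr[j] / bpr[j], 0)
  }
  C2 <- C1
  for (i in seq_len(n)) {
    if (bepo[i] > 0) C2[i, 1:ne] <- C1[i, 1:ne] * max(1 + d_bepo[i] / bepo[i], 0)
    if (bipo[i] > 0) C2[i, (ne + 1):n] <- C1[i, (ne + 1):n] * max(1 + d_bipo[i] / bipo[i], 0)
  }
  degraded <- abs(C1 - C2)
  fpr <- pmax(fpr + d_fpr + colSums(degraded), 0)
  fepo <- pmax(fepo + d_fepo, 0)
  fipo <- pmax(fipo + d_fipo, 0)

  inc <- matrix(0, n, n)
  den_e <- max(sum(fepo), sum(fpr[1:ne]))
  if (den_e > 0) for (i in seq_len(n)) for (j in 1:ne) {
    if (i != j) inc[i, j] <- fpr[j] * fepo[i] / den_e
  }
  den_i <- max(sum(fipo), sum(fpr[(ne + 1):n]))
  if (den_i > 0) for (i in seq_len(n)) for (j in (ne + 1):n) {
    if (i != j) inc[i, j] <- fpr[j] * fipo[i] / den_i
  }
  C3 <- C2 + inc
  fpr <- pmax(fpr - colSums(inc), 0)
  fepo <- pmax(fepo - rowSums(inc[, 1:ne, drop = FALSE]), 0)
  fipo <- pmax(fipo - rowSums(inc[, (ne + 1):n, drop = FALSE]), 0)
  list(C = C3, fpr = fpr, fepo = fepo, fipo = fipo)
}

# Brute-force per-pair Hebbian / anti-Hebbian pass (one-shot form).
hebbian_pair_oracle <- function(C, ds, s, eta, lam, rho, mu, high, ne) {
  n <- nrow(C)
  out <- C
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || j > ne) next
    if (s[i] > high && s[j] > high && C[i, j] > 0) {
      eps <- rho / (1 + exp((C[i, j] - 0.4) / 0.05))
      out[i, j] <- max(C[i, j] + eps * ds[i] * ds[j] * eta[i, j], 0)
    }
  }
  out2 <- out
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || j > ne) next
    if (s[i] > high && s[j] > high && out[i, j] > 0) {
      out2[i, j] <- max(out[i, j] - mu * ds[i] * ds[j] * lam[i, j], 0)
    }
  }
  out2
}
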