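#' Coincidence counters
#'
#' `eta[i, j]` counts, within the current morphogenetic step, the iterations
#' at which presynaptic neuron `j` fired and postsynaptic neuron `i` fired on
#' the following iteration; `lam[i, j]` counts the discharges of `i` that
#' were not preceded by a discharge of `j`.  For every pair,
#' `eta + lam` equals the number of discharges of `i` in the window.
#'
#' @param n number of neurons.
#' @return List of class `dg_counters` with integer matrices `eta`, `lam`.
#' @export
init_counters <- function(n) {
  structure(list(eta = matrix(0, n, n), lam = matrix(0, n, n)),
            class = "dg_counters")
}

#' Accumulate one iteration into the coincidence counters
#'
#' @param counters a [init_counters()].
#' @param z_prev,z_curr binary state vectors of consecutive iterations.
#' @return Updated counters.
#' @export
accumulate_counters <- function(counters, z_prev, z_curr) {
  counters$eta <- counters$eta + outer(z_curr, z_prev)
  counters$lam <- counters$lam + outer(z_curr, 1 - z_prev)
  counters
}

# Counters for a whole window at once: Z holds one row per iteration
# (oldest first), z_before is the state preceding the window.  Equivalent to
# folding accumulate_counters over the rows.
window_counters <- function(Z, z_before) {
  Zprev <- rbind(z_before, Z[-nrow(Z), , drop = FALSE])
  structure(list(eta = crossprod(Z, Zprev),
                 lam = crossprod(Z, 1 - Zprev)),
            class = "dg_counters")
}

#' Saturating Hebbian gain
#'
#' The potentiation gain decreases sigmoidally with the current weight,
#' `epsilon = rho / (1 + exp((c - 0.4) / 0.05))`, so that both the formation
#' of new synapses and the strengthening of existing ones are limited:
#' weights much above 0.4 receive essentially no further potentiation.
#'
#' @param c_ij weight (vector or matrix).
#' @param rho Hebbian proportionality gain, `0 < rho < 0.5`.
#' @return Gain values, bounded by `rho`.
#' @examples
#' hebbian_epsilon(0.4, 0.2182)  # rho / 2
#' @export
hebbian_epsilon <- function(c_ij, rho) {
  rho / (1 + exp((c_ij - 0.4) / 0.05))
}

# Pairs eligible for the coincidence rules: both activities above the gate,
# no self-pairs, an existing synaptic contact, and an excitatory presynaptic
# neuron.  Potentiation and depression modify synapses; contacts are created
# (and removed) only by the structural recombination of the compensation
# rules, which the Hebbian pass then amplifies -- this is what confines
# mossy-fiber sprouting to the latent period instead of letting a single
# ictal window wire the granule cells to saturation.  Inhibitory synapses
# are remodelled by compensation alone; subjecting them to the coincidence
# rules would strip the interneuron outputs during an ictal event and leave
# the network unable to repolarize into a latent period.
gate_matrix <- function(s, high, C = NULL, n_excitatory = NULL) {
  open <- s > high
  g <- outer(open, open, "&")
  diag(g) <- FALSE
  if (!is.null(C)) g <- g & (C > 0)
  if (!is.null(n_excitatory) && n_excitatory < length(s)) {
    g[, (n_excitatory + 1):length(s)] <- FALSE
  }
  g
}

#' Hebbian weight update
#'
#' For ordered pairs whose average activities both exceed the gate (0.25),
#' the weight grows by `epsilon(c) * delta_s_i * delta_s_j * eta_ij`.
#' `substeps > 1` splits the coincidence count into that many equal
#' sub-increments, re-evaluating the saturating gain in between; this is the
#' per-coincidence reading of the rule and prevents a large count from
#' overshooting the saturation ceiling in a single jump (see the methods
#' vignette).  Only existing synapses (`c_ij > 0`) are modified — new
#' contacts are the business of the structural recombination — and
#' self-connections never are.
#'
#' @param C connection matrix.
#' @param delta_s morphogenetic states.
#' @param s average activities at the end of the step.
#' @param counters a [init_counters()] accumulated over the step.
#' @param rho Hebbian gain.
#' @param high gate threshold (0.25).
#' @param substeps number of sub-increments (default 1: the one-shot rule).
#' @param n_excitatory when given, only synapses with an excitatory
#'   presynaptic neuron (`j <= n_excitatory`) are eligible; inhibitory
#'   synapses are left to the compensation rules.
#' @return Updated matrix, clamped at zero.
#' @export
apply_hebbian <- function(C, delta_s, s, counters, rho, high = 0.25,
                          substeps = 1L, n_excitatory = NULL) {
  g <- gate_matrix(s, high, C, n_excitatory)
  if (!any(g)) return(C)
  amp <- outer(delta_s, delta_s)[g] * counters$eta[g]
  w <- C[g]
  for (k in seq_len(substeps)) {
    w <- w + hebbian_epsilon(w, rho) * amp / substeps
  }
  C[g] <- pmax(w, 0)
  C
}

#' Anti-Hebbian weight update
#'
#' Depresses, under the same activity gate, the weight of pairs whose
#' postsynaptic discharges were not preceded by presynaptic ones:
#' `c_ij <- c_ij - mu * delta_s_i * delta_s_j * lam_ij`, clamped at zero.
#' With `saturating = TRUE` the gain follows the same weight-dependent
#' sigmoid as the potentiation ([hebbian_epsilon()] with base `mu`), so the
#' coincidence rules sculpt only the weak, newly formed synapses and leave
#' mature contacts to the compensation machinery; the simulator uses this
#' form, without which a single gated window strips the mature excitatory
#' groups.
#'
#' @inheritParams apply_hebbian
#' @param mu anti-Hebbian gain (the model default ties it to `rho`).
#' @param saturating scale the depression by the weight-dependent sigmoid.
#' @return Updated matrix.
#' @export
apply_anti_hebbian <- function(C, delta_s, s, counters, mu, high = 0.25,
                               n_excitatory = NULL, saturating = FALSE) {
  g <- gate_matrix(s, high, C, n_excitatory)
  if (!any(g)) return(C)
  gain <- if (saturating) hebbian_epsilon(C[g], mu) else mu
  dec <- gain * outer(delta_s, delta_s)[g] * counters$lam[g]
  C[g] <- pmax(C[g] - dec, 0)
  C
}

# Combined plasticity pass used by the simulator.  With substeps = 1 it is
# exactly apply_hebbian followed by apply_anti_hebbian; with more substeps the
# potentiation and depression are interleaved, approximating their temporal
# mixing within the window.  substeps = "auto" picks the count from the
# largest prospective increment so that no weight moves by more than ~0.02
# per sub-increment.
apply_plasticity <- function(C, delta_s, s, counters, rho, mu, high = 0.25,
                             substeps = "auto", n_excitatory = NULL) {
  g <- gate_matrix(s, high, C, n_excitatory)
  if (!any(g) || (rho == 0 && mu == 0)) return(C)
  A <- outer(delta_s, delta_s)[g]
  pot <- A * counters$eta[g]
  dep <- A * counters$lam[g]
  if (identical(substeps, "auto")) {
    biggest <- max(rho * pot, mu * dep, 0)
    substeps <- max(1L, min(150L, as.integer(ceiling(biggest / 0.02))))
  }
  w <- C[g]
  for (k in seq_len(substeps)) {
    w <- w + hebbian_epsilon(w, rho) * pot / substeps
    w <- pmax(w - hebbian_epsilon(w, mu) * dep / substeps, 0)
  }
  C[g] <- w
  C
}
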