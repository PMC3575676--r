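#' Kinetic rates of the compensation rules
#'
#' The compensation theory distinguishes bound (b) and free (f), pre- (pr)
#' and postsynaptic (po; excitatory e / inhibitory i) synaptic elements, each
#' with a kinetic constant for the high (H) and low (L) activity regimes.
#' The published ratios leave a single degree of freedom, taken up by the
#' morphogenesis speed `v`:
#' `k_fipo_H = v`, `k_fepo_L = 9 v`, `k_bpr_L = 0.033 k_fpr_H =
#' 0.167 k_fpr_L`, `k_fepo_H = k_fipo_L = k_fpr_L`, and
#' `k_bepo_H = k_bipo_L = k_bpr_L`.  The production rate of free presynaptic
#' elements, `k_fpr_H`, is not tied to `v` by those ratios.  The default
#' closes the system by extending the no-bias symmetry of the free-element
#' rates to the presynaptic class — `k_fpr_L = k_fepo_L = 9 v` — which
#' forces `k_fpr_H = (0.167 / 0.033) * 9 v` (about `45.5 v`).  This closure
#' also makes the free-presynaptic pool produced during an ictal event large
#' enough to sustain the excitatory rebuilding of the latent period; with a
#' much smaller `k_fpr_H` the pool evaporates within a couple of simulated
#' days, sprouting stalls, and no epileptogenic transition occurs.
#'
#' @param v morphogenesis speed, `0 <= v <= 0.1`; `v = 0` disables all
#'   structural change.
#' @param k_fpr_H override for the free-presynaptic production rate.
#' @return A list of class `dg_kinetic_rates`.
#' @examples
#' kinetic_rates(0.1)$k_fipo_H  # 0.1
#' kinetic_rates(0.1)$k_fepo_L  # 0.9
#' @export
kinetic_rates <- function(v, k_fpr_H = (0.167 / 0.033) * 9 * v) {
  if (v < 0) stop("`v` must be >= 0", call. = FALSE)
  k_bpr_L <- 0.033 * k_fpr_H
  k_fpr_L <- k_bpr_L / 0.167
  structure(list(
    v = v,
    k_fipo_H = v,
    k_fepo_L = 9 * v,
    k_fpr_H = k_fpr_H,
    k_bpr_L = k_bpr_L,
    k_fpr_L = k_fpr_L,
    k_fepo_H = k_fpr_L,
    k_fipo_L = k_fpr_L,
    k_bepo_H = k_bpr_L,
    k_bipo_L = k_bpr_L
  ), class = "dg_kinetic_rates")
}

#' Synaptic element pools
#'
#' Bound element sums are read off the connection matrix: `bpr_j` is column
#' sum `j` (presynaptic elements bound in outgoing synapses), `bepo_i` the
#' row sum over excitatory columns and `bipo_i` over inhibitory columns.
#' Free pools are carried alongside and default to zero.
#'
#' @param C connection matrix.
#' @param config a [dg_config()].
#' @param fpr,fepo,fipo free-element amounts per neuron.
#' @return A list of class `dg_element_pools`.
#' @export
element_pools <- function(C, config, fpr = NULL, fepo = NULL, fipo = NULL) {
  n <- config$n_total
  zed <- function(x) if (is.null(x)) numeric(n) else x
  structure(list(
    fpr = zed(fpr), fepo = zed(fepo), fipo = zed(fipo),
    bpr = colSums(C),
    bepo = rowSums(C[, exc_idx(config), drop = FALSE]),
    bipo = rowSums(C[, in_idx(config), drop = FALSE])
  ), class = "dg_element_pools")
}

#' Morphogenetic state
#'
#' Deviation of the average activity from the homeostatic setpoint,
#' `delta_s = s - setpoint`; the quantity the compensation rules try to
#' return to zero.
#'
#' @param s per-neuron average activity at the end of a morphogenetic step.
#' @param setpoint target activity (0.2).
#' @return Numeric vector.
#' @export
morphogenetic_state <- function(s, setpoint = 0.2) {
  s - setpoint
}

#' Per-neuron element changes (morphogenetic rules)
#'
#' Applies the compensation rule table.  Hyperactive neurons
#' (`s > high`) degrade bound and free excitatory postsynaptic elements and
#' produce free presynaptic and free inhibitory postsynaptic elements;
#' hypoactive neurons (`s < low`) do the opposite.  Inside the neutral band
#' nothing changes.  Free-pool losses scale with the current pool
#' (`-k * pool * |delta_s|`), bound losses and all gains scale with
#' `|delta_s|` alone.
#'
#' @param delta_s morphogenetic states from [morphogenetic_state()].
#' @param s per-neuron average activity.
#' @param pools a [element_pools()].
#' @param rates a [kinetic_rates()].
#' @param high,low bounds of the neutral band.
#' @return List of six per-neuron delta vectors
#'   (`bpr`, `bepo`, `bipo`, `fpr`, `fepo`, `fipo`).
#' @export
element_deltas <- function(delta_s, s, pools, rates, high = 0.25, low = 0.15) {
  n <- length(s)
  d <- list(bpr = numeric(n), bepo = numeric(n), bipo = numeric(n),
            fpr = numeric(n), fepo = numeric(n), fipo = numeric(n))
  ab <- abs(delta_s)
  hi <- s > high
  lo <- s < low
  if (any(hi)) {
    d$bepo[hi] <- -rates$k_bepo_H * ab[hi]
    d$fpr[hi]  <-  rates$k_fpr_H * ab[hi]
    d$fepo[hi] <- -rates$k_fepo_H * pools$fepo[hi] * ab[hi]
    d$fipo[hi] <-  rates$k_fipo_H * ab[hi]
  }
  if (any(lo)) {
    d$bpr[lo]  <- -rates$k_bpr_L * ab[lo]
    d$bipo[lo] <- -rates$k_bipo_L * ab[lo]
    d$fpr[lo]  <- -rates$k_fpr_L * pools$fpr[lo] * ab[lo]
    d$fepo[lo] <-  rates$k_fepo_L * ab[lo]
    d$fipo[lo] <- -rates$k_fipo_L * pools$fipo[lo] * ab[lo]
  }
  d
}

#' Decay of bound synaptic elements
#'
#' Distributes each neuron's bound-element loss over its synapses in
#' proportion to their strength.  Presynaptic decay rescales column `j` by
#' `1 + delta_bpr_j / bpr_j`; postsynaptic decay then rescales row `i`
#' separately over excitatory and inhibitory columns by
#' `1 + delta_b{e,i}po_i / b{e,i}po_i`.  Zero-sum columns or rows are left
#' untouched, scale factors are clamped at zero, and the absolute amount each
#' synapse loses to the postsynaptic decay is returned so it can be recycled
#' into free presynaptic elements.
#'
#' @param C connection matrix.
#' @param deltas from [element_deltas()].
#' @param pools bound sums consistent with `C`.
#' @param config a [dg_config()].
#' @return List with the updated matrix `C` and the matrix `degraded_post` of
#'   per-synapse postsynaptic losses.
#' @export
apply_bound_decay <- function(C, deltas, pools, config) {
  n <- config$n_total
  fac_col <- ifelse(pools$bpr > 0, pmax(1 + deltas$bpr / pools$bpr, 0), 1)
  C1 <- sweep(C, 2, fac_col, "*")

  fac_e <- ifelse(pools$bepo > 0, pmax(1 + deltas$bepo / pools$bepo, 0), 1)
  fac_i <- ifelse(pools$bipo > 0, pmax(1 + deltas$bipo / pools$bipo, 0), 1)
  C2 <- C1
  e_cols <- exc_idx(config); i_cols <- in_idx(config)
  C2[, e_cols] <- C1[, e_cols, drop = FALSE] * fac_e
  C2[, i_cols] <- C1[, i_cols, drop = FALSE] * fac_i

  list(C = C2, degraded_post = abs(C1 - C2))
}

#' Transfer degraded elements and apply free-pool deltas
#'
#' Presynaptic elements freed by postsynaptic degradation are recycled:
#' `fpr_j` gains the column sum of the degraded amounts plus its own delta;
#' `fepo` and `fipo` receive their deltas.  Pools are clamped at zero.
#'
#' @param pools a [element_pools()].
#' @param deltas from [element_deltas()].
#' @param degraded_post from [apply_bound_decay()].
#' @return Updated pools.
#' @export
update_free_pools <- function(pools, deltas, degraded_post) {
  pools$fpr <- pmax(pools$fpr + deltas$fpr + colSums(degraded_post), 0)
  pools$fepo <- pmax(pools$fepo + deltas$fepo, 0)
  pools$fipo <- pmax(pools$fipo + deltas$fipo, 0)
  pools
}

#' Recombination of free synaptic elements
#'
#' Free presynaptic elements of neuron `j` bind with free postsynaptic
#' elements of neuron `i`: excitatory presynaptic neurons (`j <= NE`) pair
#' with free excitatory postsynaptic elements, interneurons with free
#' inhibitory ones.  The increment is
#' `fpr_j * f{e,i}po_i / max(total f{e,i}po, total fpr of the branch)`;
#' a branch with a zero denominator is skipped, and no autapses are formed.
#' Each neuron's free pools are then reduced by exactly the amount it bound,
#' keeping the element bookkeeping consistent.
#'
#' @param C connection matrix.
#' @param pools a [element_pools()].
#' @param config a [dg_config()].
#' @return List with updated `C` and `pools`.
#' @export
recombine_free_elements <- function(C, pools, config) {
  n <- config$n_total
  e_cols <- exc_idx(config); i_cols <- in_idx(config)

  inc <- matrix(0, n, n)
  denom_e <- max(sum(pools$fepo), sum(pools$fpr[e_cols]))
  if (denom_e > 0) {
    inc[, e_cols] <- outer(pools$fepo, pools$fpr[e_cols]) / denom_e
  }
  denom_i <- max(sum(pools$fipo), sum(pools$fpr[i_cols]))
  if (denom_i > 0) {
    inc[, i_cols] <- outer(pools$fipo, pools$fpr[i_cols]) / denom_i
  }
  diag(inc) <- 0

  C <- C + inc
  pools$fpr <- pmax(pools$fpr - colSums(inc), 0)
  pools$fepo <- pmax(pools$fepo - rowSums(inc[, e_cols, drop = FALSE]), 0)
  pools$fipo <- pmax(pools$fipo - rowSums(inc[, i_cols, drop = FALSE]), 0)
  list(C = C, pools = pools)
}

#' One morphogenetic step of the compensation rules
#'
#' Runs, in order: morphogenetic state, rule-table element deltas, bound
#' decay, free-pool transfer, recombination; then recomputes the bound sums
#' from the updated matrix.
#'
#' @param C connection matrix.
#' @param pools a [element_pools()] consistent with `C`.
#' @param s per-neuron average activity over the elapsed window.
#' @param rates a [kinetic_rates()].
#' @param config a [dg_config()].
#' @return List with updated `C` and `pools`.
#' @export
morphogenetic_step <- function(C, pools, s, rates, config) {
  delta_s <- morphogenetic_state(s, config$activity_setpoint)
  deltas <- element_deltas(delta_s, s, pools, rates,
                           high = config$high_threshold,
                           low = config$low_threshold)
  dec <- apply_bound_decay(C, deltas, pools, config)
  pools <- update_free_pools(pools, deltas, dec$degraded_post)
  rec <- recombine_free_elements(dec$C, pools, config)
  pools <- rec$pools
  pools$bpr <- colSums(rec$C)
  pools$bepo <- rowSums(rec$C[, exc_idx(config), drop = FALSE])
  pools$bipo <- rowSums(rec$C[, in_idx(config), drop = FALSE])
  list(C = rec$C, pools = pools)
}
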