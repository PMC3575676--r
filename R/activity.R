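#' Membrane potential of every neuron
#'
#' Sums the three synaptic drives given the previous iteration's states and
#' adds the nonsynaptic effect: granule-cell inputs are weighted by `tau`,
#' mossy-cell inputs by `kappa1` or `kappa2` according to the target
#' population (see `kappa_rule` in [dg_config()]), and interneuron inputs
#' enter negatively with weight `phi` (or a per-synapse weight while the
#' GABAa shift is active).
#'
#' @param C connection matrix.
#' @param z_prev state vector of the previous iteration: binary discharges
#'   or, under the rate-based drive, firing probabilities.
#' @param ns per-neuron nonsynaptic effect (see [ns_effect()]); scalar 0 is
#'   recycled.
#' @param config a [dg_config()].
#' @param w_in inhibitory weights: either the scalar `phi` (default) or an
#'   `n_total` x `n_interneuron` matrix of per-synapse weights, used while the
#'   transient GABAa modulation replaces `phi` on selected synapses.
#' @return Numeric vector of membrane potentials.
#' @export
membrane_potential <- function(C, z_prev, ns = 0, config, w_in = NULL) {
  n <- config$n_total
  if (!is.matrix(C) || nrow(C) != n || ncol(C) != n) {
    stop(sprintf("`C` must be a %d x %d matrix", n, n), call. = FALSE)
  }
  if (length(z_prev) != n) {
    stop(sprintf("`z_prev` must have length %d", n), call. = FALSE)
  }
  gc <- gc_idx(config); mc <- mc_idx(config); inn <- in_idx(config)
  kappa <- kappa_by_target(config)
  exc_gc <- config$tau * drop(C[, gc, drop = FALSE] %*% z_prev[gc])
  exc_mc <- kappa * drop(C[, mc, drop = FALSE] %*% z_prev[mc])
  if (is.null(w_in)) w_in <- config$phi
  if (is.matrix(w_in)) {
    inh <- drop((w_in * C[, inn, drop = FALSE]) %*% z_prev[inn])
  } else {
    inh <- w_in * drop(C[, inn, drop = FALSE] %*% z_prev[inn])
  }
  exc_gc + exc_mc - inh + ns
}

#' Firing probability from the stochastic threshold function
#'
#' Logistic threshold function: `p = 1 / (1 + exp((MP + alpha - theta) /
#' (-beta)))`.  `beta` sets the noise of the threshold; `alpha` is the
#' external stimulus.
#'
#' @param mp membrane potential vector.
#' @param alpha stimulus amplitude (scalar).
#' @param config a [dg_config()].
#' @return Probability vector, strictly increasing in `mp` and `alpha`.
#' @examples
#' firing_probability(0, 0, dg_config())  # 1 / (1 + exp(0.5)) ~ 0.3775
#' @export
firing_probability <- function(mp, alpha = 0, config) {
  if (config$beta <= 0) stop("`beta` must be positive", call. = FALSE)
  1 / (1 + exp((mp + alpha - config$theta) / (-config$beta)))
}

#' Sample binary firing states
#'
#' Each neuron fires (`z = 1`) independently with its probability, using the
#' global RNG.
#'
#' @param p probability vector with entries in `[0, 1]`.
#' @return Integer 0/1 vector.
#' @export
sample_states <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  as.integer(stats::runif(length(p)) < p)
}

#' Running average activity
#'
#' The average activity `s_i` is the mean firing probability over the most
#' recent morphogenetic window.  When fewer iterations have elapsed than the
#' window holds, the mean runs over what is available.
#'
#' @param history matrix of firing probabilities, one row per iteration
#'   (oldest first), one column per neuron.
#' @param window window length in iterations (the morphogenetic window, 150).
#' @return Vector of per-neuron average activities.
#' @export
update_activity_average <- function(history, window) {
  if (is.null(dim(history))) history <- matrix(history, nrow = 1)
  if (nrow(history) == 0) stop("empty activity history", call. = FALSE)
  take <- min(nrow(history), window)
  colMeans(history[nrow(history) - take + seq_len(take), , drop = FALSE])
}
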