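#' Create a nonsynaptic state
#'
#' Per-neuron state of the sodium dynamics: the excitatory level `nse`
#' (Na+ influx), the inhibitory level `nsi` (Na/K-pump efflux), and the two
#' repolarization aids `r_nse`, `r_nsi` in `[0, 1]`.  All start at zero
#' (fully polarized rest).
#'
#' @param n number of neurons.
#' @return A list of class `dg_ns_state`.
#' @export
ns_state <- function(n) {
  structure(list(nse = numeric(n), nsi = numeric(n),
                 r_nse = numeric(n), r_nsi = numeric(n),
                 repol = logical(n)),
            class = "dg_ns_state")
}

#' Classify the dynamical state of each neuron
#'
#' Three-state machine of the nonsynaptic dynamics:
#' `in_repolarization` when the pump has overcome the influx (`NSE < NSI`)
#' and the influx level is still above its floor;
#' `sustained_depolarization` when the activity exceeds `L` and influx
#' dominates (`NSE >= NSI`); `polarized` otherwise (the interictal
#' condition `s < L`).
#'
#' Repolarization is hysteretic: once the pump has overcome the influx the
#' repolarization runs to completion — the neuron stays in
#' `in_repolarization` until the influx level has drained to its floor, and
#' only then does it polarize.  Without this memory the levels would
#' flip-flop at the `NSE = NSI` crossing (the influx term re-engages the
#' moment NSE dips below NSI) and an ictal event could never terminate.
#'
#' @param s per-neuron average activity.
#' @param st a `dg_ns_state`.
#' @param params [ns_params()].
#' @return Character vector of state labels.
#' @export
classify_ns_state <- function(s, st, params) {
  repol <- if (is.null(st$repol)) rep(FALSE, length(st$nse)) else st$repol
  in_rep <- (repol | st$nse < st$nsi) & st$nse > params$nse_floor
  sus <- !in_rep & (s > params$L) & (st$nse >= st$nsi)
  out <- rep("polarized", length(st$nse))
  out[in_rep] <- "in_repolarization"
  out[sus] <- "sustained_depolarization"
  out
}

#' Production/drain rates of the sodium dynamics
#'
#' Returns the state-dependent rate functions `h` (driving NSE) and `k`
#' (driving NSI).  During sustained depolarization, NSE production grows with
#' the squared excess activity and saturates as NSE approaches `nse_sat`
#' (`h = e_bar * (s - 0.25)^2 * (1 - tanh((NSE - nse_sat)/sat_scale))`),
#' while the pump is recruited in proportion to NSE (`k = f * NSE`).  In
#' repolarization both levels drain through the aids (`h = -g_rep * R_NSE`
#' while NSE is above its floor, similarly for NSI).  Polarized neurons have
#' `h = k = 0`.
#'
#' @inheritParams classify_ns_state
#' @param label state labels from [classify_ns_state()].
#' @return List with vectors `h` and `k`.
#' @export
ns_state_rates <- function(label, s, st, params) {
  n <- length(st$nse)
  h <- numeric(n); k <- numeric(n)
  sus <- label == "sustained_depolarization"
  if (any(sus)) {
    ds <- s[sus] - 0.25
    sat <- 1 - tanh((st$nse[sus] - params$nse_sat) / params$sat_scale)
    h[sus] <- params$e_bar * ds * ds * sat
    k[sus] <- params$f * st$nse[sus]
  }
  rep_ <- label == "in_repolarization"
  if (any(rep_)) {
    h[rep_] <- -params$g_rep * st$r_nse[rep_] * (st$nse[rep_] > params$nse_floor)
    if (identical(params$pump_recovery, "active")) {
      k[rep_] <- -params$h_rep * st$r_nsi[rep_] * (st$nsi[rep_] > params$nsi_floor)
    }
  }
  list(h = h, k = k)
}

#' Advance the repolarization aids
#'
#' Euler update `r <- r + dt * rate * (1 - r)` while the corresponding level
#' is above its floor; the aid resets to zero once the level drains to or
#' below the floor.  Values stay in `[0, 1]`.
#'
#' @param st a `dg_ns_state` (with already-updated `nse`/`nsi` levels).
#' @param params [ns_params()].
#' @param dt integration step.
#' @return The state with updated `r_nse`, `r_nsi`.
#' @export
step_repolarization_aux <- function(st, params, dt) {
  st$r_nse <- ifelse(st$nse > params$nse_floor,
                     pmin(st$r_nse + dt * params$l * (1 - st$r_nse), 1), 0)
  st$r_nsi <- ifelse(st$nsi > params$nsi_floor,
                     pmin(st$r_nsi + dt * params$m * (1 - st$r_nsi), 1), 0)
  st
}

#' One Euler step of the nonsynaptic dynamics
#'
#' Classifies every neuron, evaluates the state-dependent rates, advances
#' `NSE` and `NSI` (`NSE <- NSE + dt * (h - c * NSE)`, similarly for NSI with
#' drain `d`), clamps both at zero, then advances the repolarization aids.
#'
#' @param st a `dg_ns_state`.
#' @param s per-neuron average activity.
#' @param params [ns_params()].
#' @param dt integration step (> 0).
#' @return Updated `dg_ns_state`; the labels used are attached as `$label`.
#' @export
step_nonsynaptic <- function(st, s, params, dt) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  label <- classify_ns_state(s, st, params)
  r <- ns_state_rates(label, s, st, params)
  st$nse <- pmax(st$nse + dt * (r$h - params$c * st$nse), 0)
  st$nsi <- pmax(st$nsi + dt * (r$k - params$d * st$nsi), 0)
  st <- step_repolarization_aux(st, params, dt)
  st$repol <- label == "in_repolarization" & st$nse > params$nse_floor
  st$label <- label
  st
}

#' Nonsynaptic effect on the membrane potential
#'
#' `NS_i = a * NSE_i - b * NSI_i`: the net depolarizing drive of the sodium
#' influx against the pump current.
#'
#' @param st a `dg_ns_state`.
#' @param params [ns_params()].
#' @return Numeric vector.
#' @export
ns_effect <- function(st, params) {
  params$a * st$nse - params$b * st$nsi
}
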