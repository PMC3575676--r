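#' Nonsynaptic dynamics parameters
#'
#' Constants of the phenomenological sodium dynamics: `NSE` tracks the
#' depolarizing Na+ influx through voltage-gated channels and `NSI` the
#' hyperpolarizing electrogenic Na/K-pump current.  Rates are expressed per
#' integration step of the nonsynaptic clock (see `ns_unit` in [dg_config()]).
#'
#' @param a,b gains balancing the excitatory (`a * NSE`) and inhibitory
#'   (`b * NSI`) contributions to the membrane potential.
#' @param c,d passive decay rates of NSE and NSI.
#' @param f production rate of NSI during sustained depolarization
#'   (pump recruitment proportional to NSE).
#' @param e_bar gain of the activity-driven NSE production.
#' @param g_rep,h_rep repolarization rates draining NSE and NSI once the pump
#'   dominates.
#' @param l,m growth rates of the repolarization aids `R_NSE`, `R_NSI`.
#' @param L average-activity threshold above which the nonsynaptic machinery
#'   engages (sustained depolarization requires `s > L`).
#' @param nse_floor,nsi_floor levels below which a variable is considered
#'   drained; its repolarization aid resets to zero there.
#' @param nse_sat saturation level of NSE: production shuts off smoothly as
#'   NSE approaches this value.
#' @param sat_scale width of the saturation sigmoid.
#' @param pump_recovery how the pump level NSI returns to rest after an
#'   ictal event.  `"passive"` (default): repolarization actively drains
#'   only the influx level NSE, and NSI then relaxes through its intrinsic
#'   decay `d` — whose time constant of several simulated days produces the
#'   post-ictal depression of the latent period.  `"active"`: NSI is also
#'   drained during repolarization at rate `h_rep` (no latent depression
#'   survives the event).
#' @return A list of class `dg_ns_params`.
#' @export
ns_params <- function(a = 0.8, b = 0.2,
                      c = 2.8e-6, d = 5.6e-5, f = 2.8e-3, e_bar = 1.1,
                      g_rep = 2.8e-2, h_rep = 2.8e-2, l = 2.8e-2, m = 1.1e-2,
                      L = 0.32,
                      nse_floor = 0.1, nsi_floor = 0.009,
                      nse_sat = 18, sat_scale = 0.5,
                      pump_recovery = c("passive", "active")) {
  pump_recovery <- match.arg(pump_recovery)
  p <- list(a = a, b = b, c = c, d = d, f = f, e_bar = e_bar,
            g_rep = g_rep, h_rep = h_rep, l = l, m = m, L = L,
            nse_floor = nse_floor, nsi_floor = nsi_floor,
            nse_sat = nse_sat, sat_scale = sat_scale,
            pump_recovery = pump_recovery)
  rates <- c("c", "d", "f", "e_bar", "g_rep", "h_rep", "l", "m")
  if (any(unlist(p[rates]) < 0)) {
    stop("nonsynaptic rate constants must be >= 0", call. = FALSE)
  }
  if (L <= 0 || L >= 1) stop("`L` must lie in (0, 1)", call. = FALSE)
  structure(p, class = "dg_ns_params")
}

#' Network configuration
#'
#' Builds the parameter set of the dentate gyrus network: population sizes,
#' synaptic weight scales, the firing threshold function, and the two
#' simulation clocks (the 0.36-minute iteration and the 150-iteration
#' morphogenetic window).
#'
#' @param n_granule,n_mossy,n_interneuron population sizes.  The defaults are
#'   the 1:10,000 reduction of the rat dentate gyrus: 99 granule cells (GC),
#'   3 mossy cells (MC) and 3 interneurons (IN), so `N = 105` with
#'   `NE = 102` excitatory neurons.
#' @param tau synaptic weight scale of granule-cell outputs.
#' @param kappa1,kappa2 weight scales of mossy-cell outputs; which targets
#'   receive which scale is set by `kappa_rule`.
#' @param phi weight scale of interneuron (inhibitory) outputs.
#' @param theta firing threshold.
#' @param beta noise scale of the threshold function; must be positive.
#' @param iteration_minutes real-time duration of one iteration (0.36 min,
#'   i.e. 4000 iterations per simulated day).
#' @param morphogenetic_window iterations per morphogenetic step (150; one
#'   step spans 54 minutes).
#' @param activity_setpoint target average activity of the compensation rules.
#' @param high_threshold,low_threshold bounds of the neutral band: average
#'   activity above `high_threshold` marks a neuron as hyperactive (H),
#'   below `low_threshold` as hypoactive (L); in between no structural
#'   change occurs.
#' @param init_activity probability used to sample the initial firing states;
#'   defaults to the setpoint.
#' @param gc_afferents number of distinct granule cells feeding each mossy
#'   cell and each interneuron (33).
#' @param ns nonsynaptic parameter set, see [ns_params()].
#' @param ns_unit clock of the nonsynaptic Euler integration.  `"iteration"`
#'   (default) advances the NSE/NSI equations by one unit per iteration, the
#'   convention under which the stimulus-triggered afterdischarge lasts about
#'   two hours; `"minute"` uses `iteration_minutes` as the Euler step.
#' @param ns_activity which activity measure drives the nonsynaptic state
#'   machine: the instantaneous firing probability (`"probability"`,
#'   default) or the running window average (`"average"`).  The
#'   probability reading makes a suprathreshold stimulus engage the sodium
#'   dynamics at onset — the amplitude 1.0 is then just sufficient for
#'   ignition, while 0.5 is not — whereas the slow window average never
#'   crosses the engagement threshold `L` under stimulation.
#' @param normalize_inputs rescale every neuron's afferent weights within
#'   each connection group to a mean of exactly 1.0 (default `TRUE`).  Each
#'   model cell pools thousands of real neurons, so per-target input totals
#'   are tightly regulated; without this, sampling noise in the handful of
#'   large afferent weights spreads the per-neuron operating points over
#'   several percent of activity, some neurons land outside the homeostatic
#'   band or beyond the ictal threshold `L` at rest, and the resting network
#'   ignites spontaneously for many seeds.
#' @param kappa_rule assignment of the mossy-cell weight scales.
#'   `"granule_target"` (default) gives `kappa1` to mossy synapses onto
#'   granule cells and `kappa2` to those onto mossy cells and interneurons —
#'   the assignment under which the resting network settles in the published
#'   stability band 0.15-0.25; `"excitatory_target"` gives `kappa1` to all
#'   excitatory targets and `kappa2` to interneuron targets.
#' @param drive what the synaptic sums integrate: the firing
#'   probabilities of the previous iteration (`"probability"`, default — the
#'   rate-based reading under which the resting state is stationary) or the
#'   sampled binary states (`"binary"`).  Binary discharges are always
#'   sampled and drive the Hebbian coincidence counters.
#' @param seed optional integer seed applied by [run_simulation()].
#' @return A list of class `dg_config` with derived totals `n_total` and
#'   `n_excitatory`.
#' @examples
#' cfg <- dg_config()
#' cfg$n_total       # 105
#' cfg$n_excitatory  # 102
#' @export
dg_config <- function(n_granule = 99L, n_mossy = 3L, n_interneuron = 3L,
                      tau = 0.19, kappa1 = 4.92, kappa2 = 2.37, phi = 8,
                      theta = 1.0, beta = 2,
                      iteration_minutes = 0.36,
                      morphogenetic_window = 150L,
                      activity_setpoint = 0.2,
                      high_threshold = 0.25, low_threshold = 0.15,
                      init_activity = NULL,
                      gc_afferents = 33L,
                      ns = ns_params(),
                      ns_unit = c("iteration", "minute"),
                      ns_activity = c("probability", "average"),
                      normalize_inputs = TRUE,
                      kappa_rule = c("granule_target", "excitatory_target"),
                      drive = c("probability", "binary"),
                      seed = NULL) {
  ns_unit <- match.arg(ns_unit)
  ns_activity <- match.arg(ns_activity)
  kappa_rule <- match.arg(kappa_rule)
  drive <- match.arg(drive)
  if (is.null(init_activity)) init_activity <- activity_setpoint
  cfg <- list(
    n_granule = as.integer(n_granule), n_mossy = as.integer(n_mossy),
    n_interneuron = as.integer(n_interneuron),
    n_excitatory = as.integer(n_granule + n_mossy),
    n_total = as.integer(n_granule + n_mossy + n_interneuron),
    tau = tau, kappa1 = kappa1, kappa2 = kappa2, phi = phi,
    theta = theta, beta = beta,
    iteration_minutes = iteration_minutes,
    morphogenetic_window = as.integer(morphogenetic_window),
    activity_setpoint = activity_setpoint,
    high_threshold = high_threshold, low_threshold = low_threshold,
    init_activity = init_activity,
    gc_afferents = as.integer(gc_afferents),
    ns = ns, ns_unit = ns_unit, ns_activity = ns_activity,
    normalize_inputs = isTRUE(normalize_inputs),
    kappa_rule = kappa_rule, drive = drive,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_dg_config(structure(cfg, class = "dg_config"))
}

validate_dg_config <- function(cfg) {
  stopifnot(inherits(cfg, "dg_config"))
  if (cfg$n_granule < 1 || cfg$n_mossy < 1 || cfg$n_interneuron < 1) {
    stop("each cell population needs at least one neuron", call. = FALSE)
  }
  if (cfg$n_granule < cfg$gc_afferents) {
    stop(sprintf(
      "`n_granule` (%d) must be >= `gc_afferents` (%d): each mossy cell and interneuron samples that many distinct granule-cell afferents",
      cfg$n_granule, cfg$gc_afferents), call. = FALSE)
  }
  w <- c(tau = cfg$tau, kappa1 = cfg$kappa1, kappa2 = cfg$kappa2,
         phi = cfg$phi, beta = cfg$beta)
  bad <- names(w)[w <= 0]
  if (length(bad)) {
    stop(sprintf("weights must be positive; offending: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!(cfg$low_threshold > 0 && cfg$low_threshold < cfg$activity_setpoint &&
        cfg$activity_setpoint < cfg$high_threshold && cfg$high_threshold < 1)) {
    stop("need 0 < low_threshold < activity_setpoint < high_threshold < 1",
         call. = FALSE)
  }
  if (cfg$iteration_minutes <= 0) stop("`iteration_minutes` must be > 0", call. = FALSE)
  if (cfg$morphogenetic_window < 1) stop("`morphogenetic_window` must be >= 1", call. = FALSE)
  if (cfg$init_activity < 0 || cfg$init_activity > 1) {
    stop("`init_activity` must lie in [0, 1]", call. = FALSE)
  }
  if (!inherits(cfg$ns, "dg_ns_params")) stop("`ns` must come from ns_params()", call. = FALSE)
  cfg
}

#' @export
print.dg_config <- function(x, ...) {
  cat("Dentate gyrus network configuration\n")
  cat(sprintf("  populations: %d GC + %d MC + %d IN  (N = %d, NE = %d)\n",
              x$n_granule, x$n_mossy, x$n_interneuron, x$n_total, x$n_excitatory))
  cat(sprintf("  weights: tau = %.3g, kappa1 = %.3g, kappa2 = %.3g, phi = %.3g\n",
              x$tau, x$kappa1, x$kappa2, x$phi))
  cat(sprintf("  threshold function: theta = %.3g, beta = %.3g\n", x$theta, x$beta))
  cat(sprintf("  clocks: %.2f min/iteration, %d iterations/morphogenetic step\n",
              x$iteration_minutes, x$morphogenetic_window))
  cat(sprintf("  activity setpoint %.2f, neutral band [%.2f, %.2f]\n",
              x$activity_setpoint, x$low_threshold, x$high_threshold))
  invisible(x)
}

# Per-target mossy-cell weight scale (length n_total).
kappa_by_target <- function(cfg) {
  i <- seq_len(cfg$n_total)
  if (cfg$kappa_rule == "granule_target") {
    ifelse(i <= cfg$n_granule, cfg$kappa1, cfg$kappa2)
  } else {
    ifelse(i <= cfg$n_excitatory, cfg$kappa1, cfg$kappa2)
  }
}

# Index helpers (1-based; granule cells first, then mossy cells, interneurons).
gc_idx <- function(cfg) seq_len(cfg$n_granule)
mc_idx <- function(cfg) cfg$n_granule + seq_len(cfg$n_mossy)
in_idx <- function(cfg) cfg$n_excitatory + seq_len(cfg$n_interneuron)
exc_idx <- function(cfg) seq_len(cfg$n_excitatory)

#' Simulation protocol
#'
#' Describes one of the three in-silico scenarios: `"rest"` (no external
#' input), `"stimulation"` (a suprathreshold stimulus mimicking the induction
#' of status epilepticus) and `"stimulation_gabaa"` (stimulation followed by a
#' transient loss of inhibition on selected interneuron-to-granule-cell
#' synapses, modelling the post-injury excitatory shift of GABAa signalling).
#'
#' @param scenario one of `"rest"`, `"stimulation"`, `"stimulation_gabaa"`.
#' @param alpha stimulus amplitude added to the membrane potential during the
#'   stimulation window (1.0 by default; 0.5 and 1.5 probe weaker/stronger
#'   induction).
#' @param stim_onset_day onset of the stimulus, in simulated days (1.5).
#' @param stim_duration_min stimulus duration in minutes (70).
#' @param t_i_day,t_f_day onset and end, in days, of the inflammatory period
#'   during which the GABAa weight modulation acts (2 and 12.5).
#' @param n_modified_interneurons how many of the interneurons undergo the
#'   GABAa shift (2 of 3).
#' @param n_target_granule number of granule cells whose afferents from the
#'   modified interneurons are affected (22, about 22% of the granule cells).
#' @param total_days default duration of a run, in days.
#' @param gabaa_formula `"transient_suppression"` (default: the inhibitory
#'   weight falls from `phi` to about zero during the inflammatory window and
#'   recovers afterwards) or `"literal"` (the printed modulation formula,
#'   which instead starts near zero and saturates at `phi`); see
#'   [gabaa_weight()].
#' @return A list of class `dg_protocol`.
#' @export
dg_protocol <- function(scenario = c("rest", "stimulation", "stimulation_gabaa"),
                        alpha = 1.0,
                        stim_onset_day = 1.5, stim_duration_min = 70,
                        t_i_day = 2.0, t_f_day = 12.5,
                        n_modified_interneurons = 2L,
                        n_target_granule = 22L,
                        total_days = 100,
                        gabaa_formula = c("transient_suppression", "literal")) {
  scenario <- match.arg(scenario)
  gabaa_formula <- match.arg(gabaa_formula)
  if (stim_duration_min <= 0) stop("`stim_duration_min` must be > 0", call. = FALSE)
  if (total_days <= 0) stop("`total_days` must be > 0", call. = FALSE)
  if (stim_onset_day < 0 || stim_onset_day >= total_days) {
    stop("`stim_onset_day` must satisfy 0 <= onset < total_days", call. = FALSE)
  }
  structure(list(
    scenario = scenario, alpha = alpha,
    stim_onset_day = stim_onset_day, stim_duration_min = stim_duration_min,
    t_i_day = t_i_day, t_f_day = t_f_day,
    n_modified_interneurons = as.integer(n_modified_interneurons),
    n_target_granule = as.integer(n_target_granule),
    total_days = total_days,
    gabaa_formula = gabaa_formula
  ), class = "dg_protocol")
}

#' @export
print.dg_protocol <- function(x, ...) {
  cat(sprintf("Protocol: %s (%g days)\n", x$scenario, x$total_days))
  if (x$scenario != "rest") {
    cat(sprintf("  stimulus: alpha = %g at day %g for %g min\n",
                x$alpha, x$stim_onset_day, x$stim_duration_min))
  }
  if (x$scenario == "stimulation_gabaa") {
    cat(sprintf("  GABAa shift: %d interneurons x %d granule cells, days %g-%g (%s)\n",
                x$n_modified_interneurons, x$n_target_granule,
                x$t_i_day, x$t_f_day, x$gabaa_formula))
  }
  invisible(x)
}
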