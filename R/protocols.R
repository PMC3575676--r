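#' Stimulus amplitude at a given iteration
#'
#' The stimulus is a square pulse: `alpha = protocol$alpha` while the
#' iteration falls inside the stimulation window, 0 otherwise.  Iteration
#' `t` (1-based) starts at minute `(t - 1) * iteration_minutes`; a 70-minute
#' pulse at 0.36 min/iteration spans `floor(70 / 0.36) = 194` iterations.
#'
#' @param t_iteration iteration index (1-based; vectorized).
#' @param protocol a [dg_protocol()].
#' @param config a [dg_config()].
#' @return Stimulus amplitude(s).
#' @export
stimulation_schedule <- function(t_iteration, protocol, config) {
  if (protocol$scenario == "rest") return(rep(0, length(t_iteration)))
  it_per_min <- 1 / config$iteration_minutes
  onset <- floor(protocol$stim_onset_day * 1440 * it_per_min)     # 0-based
  len <- floor(protocol$stim_duration_min * it_per_min)
  t0 <- t_iteration - 1
  ifelse(t0 >= onset & t0 < onset + len, protocol$alpha, 0)
}

#' Select the synapses affected by the transient GABAa shift
#'
#' Picks `n_modified_interneurons` of the interneurons and one common random
#' set of `n_target_granule` granule cells; every (modified interneuron,
#' target granule cell) synapse follows the time-varying weight of
#' [gabaa_weight()] instead of the fixed `phi`.  Selection uses the global
#' RNG, so a seeded run always chooses the same targets.
#'
#' @param config a [dg_config()].
#' @param protocol a [dg_protocol()].
#' @return List with `interneurons` (global indices), `granule` (global
#'   indices) and `mask`, an `n_total` x `n_interneuron` 0/1 matrix marking
#'   the modified synapses in the interneuron column block.
#' @export
select_gabaa_targets <- function(config, protocol) {
  if (protocol$n_target_granule > config$n_granule) {
    stop("`n_target_granule` exceeds the number of granule cells", call. = FALSE)
  }
  if (protocol$n_modified_interneurons > config$n_interneuron) {
    stop("`n_modified_interneurons` exceeds the number of interneurons", call. = FALSE)
  }
  ins <- sort(sample(in_idx(config), protocol$n_modified_interneurons))
  gcs <- if (protocol$n_target_granule > 0) {
    sort(sample(gc_idx(config), protocol$n_target_granule))
  } else integer(0)
  mask <- matrix(0, config$n_total, config$n_interneuron)
  cols <- match(ins, in_idx(config))
  mask[gcs, cols] <- 1
  list(interneurons = ins, granule = gcs, mask = mask)
}

#' Time-varying inhibitory weight during the inflammatory period
#'
#' Models the post-injury excitatory shift of GABAa transmission as a
#' transient rescaling of the inhibitory weight on the selected synapses.
#' In the default `"transient_suppression"` mode the weight equals `phi`
#' before the inflammation onset `t_i`, collapses to about zero between
#' `t_i` and `t_f`, and recovers to `phi` afterwards:
#' `phi * (1 - 0.25 * (tanh((t - t_i)/0.2) + 1) * (1 - tanh((t - t_f)/1.5)))`.
#' The `"literal"` mode evaluates the printed modulation
#' `phi * 0.25 * (tanh((t - t_i)/0.2) + 1) * (tanh((t - t_f)/1.5) + 1)`,
#' which instead starts near zero and saturates at `phi` after `t_f`.
#'
#' @param t_days model time in days (vectorized).
#' @param phi baseline inhibitory weight.
#' @param protocol a [dg_protocol()] carrying `t_i_day`, `t_f_day` and the
#'   mode.
#' @return Weight value(s) replacing `phi` on the modified synapses.
#' @export
gabaa_weight <- function(t_days, phi, protocol) {
  rise <- tanh((t_days - protocol$t_i_day) / 0.2) + 1
  if (protocol$gabaa_formula == "literal") {
    phi * 0.25 * rise * (tanh((t_days - protocol$t_f_day) / 1.5) + 1)
  } else {
    phi * (1 - 0.25 * rise * (1 - tanh((t_days - protocol$t_f_day) / 1.5)))
  }
}

#' Detect spontaneous increases of cell activity (SICA)
#'
#' Scans the per-morphogenetic-step mean network activity for maximal runs of
#' consecutive steps exceeding `(1 + threshold_fraction)` times a rolling
#' baseline, the median of the preceding `baseline_window` steps.  Events are
#' the model's proxy for ictal (seizure-like) episodes; an event overlapping
#' a supplied stimulation window is flagged as stimulus-triggered rather than
#' spontaneous.
#'
#' @param activity_trace per-step mean network activity.
#' @param baseline_window steps used for the rolling median baseline.
#' @param threshold_fraction relative rise defining an event (0.30).
#' @param step_iterations iterations per step, used to report iteration
#'   indices and durations.
#' @param iteration_minutes minutes per iteration.
#' @param stim_window optional length-2 iteration range `(first, last)` of
#'   the stimulus; overlapping events are marked `stimulus_triggered`.
#' @return data.frame with one row per event: `start_step`, `end_step`,
#'   `start_iteration`, `end_iteration`, `peak_activity`,
#'   `duration_minutes`, `stimulus_triggered`.
#' @export
detect_sica <- function(activity_trace, baseline_window = 10,
                        threshold_fraction = 0.30,
                        step_iterations = 150, iteration_minutes = 0.36,
                        stim_window = NULL) {
  empty <- data.frame(start_step = integer(0), end_step = integer(0),
                      start_iteration = integer(0), end_iteration = integer(0),
                      peak_activity = numeric(0), duration_minutes = numeric(0),
                      stimulus_triggered = logical(0))
  n <- length(activity_trace)
  if (n <= baseline_window) {
    warning("activity trace shorter than the baseline window; no events detectable")
    return(empty)
  }
  elevated <- logical(n)
  for (k in (baseline_window + 1):n) {
    base <- stats::median(activity_trace[(k - baseline_window):(k - 1)])
    elevated[k] <- activity_trace[k] > (1 + threshold_fraction) * base
  }
  r <- rle(elevated)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  out <- data.frame(
    start_step = starts, end_step = ends,
    start_iteration = (starts - 1) * step_iterations + 1,
    end_iteration = ends * step_iterations,
    peak_activity = mapply(function(a, b) max(activity_trace[a:b]), starts, ends),
    duration_minutes = (ends - starts + 1) * step_iterations * iteration_minutes
  )
  out$stimulus_triggered <- FALSE
  if (!is.null(stim_window)) {
    out$stimulus_triggered <- out$start_iteration <= stim_window[2] &
      out$end_iteration >= stim_window[1]
  }
  out
}
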