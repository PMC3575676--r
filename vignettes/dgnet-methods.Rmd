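---
title: "Modelling epileptogenesis in the dentate gyrus: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling epileptogenesis in the dentate gyrus: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgnet)
```

# The model

dgnet simulates the dentate gyrus as a reduced-scale (1:10,000) network of
105 stochastic binary neurons: 99 granule cells (GC), 3 mossy cells (MC) and
3 interneurons (IN), each model cell standing for thousands of real ones.
Three processes interact across two clocks — a 0.36-minute iteration (4000
per simulated day) and a 150-iteration *morphogenetic window* (54 minutes):

1. **Membrane dynamics.** Each neuron fires with probability
   `p = 1 / (1 + exp((MP + alpha - theta) / (-beta)))`, where the membrane
   potential sums granule inputs (weight `tau = 0.19`), mossy inputs
   (`kappa1 = 4.92` onto granule cells, `kappa2 = 2.37` onto mossy cells and
   interneurons), inhibitory inputs (`-phi = -8`), the external stimulus
   `alpha`, and a nonsynaptic term.
2. **Nonsynaptic sodium dynamics.** Per neuron, a depolarizing influx level
   `NSE` and a Na/K-pump level `NSI` follow a three-state machine
   (polarized, sustained depolarization, in repolarization).  Their net
   effect `a*NSE - b*NSI` enters the membrane potential and is what turns a
   suprathreshold stimulus into an hours-long afterdischarge.
3. **Structural plasticity.** At every morphogenetic window the compensation
   rules convert each neuron's deviation from the activity setpoint (0.2)
   into creation/degradation of free and bound synaptic elements
   (recombination of free elements forms new synapses — including the
   initially absent granule-to-granule group, the model's mossy-fiber
   sprouting), and the Hebbian/anti-Hebbian coincidence rules re-weight
   existing excitatory synapses.

`run_simulation()` executes one of three protocols: `rest`, `stimulation`
(a 70-minute pulse of amplitude 1.0 at day 1.5, the in-silico status
epilepticus), and `stimulation_gabaa` (stimulation plus a transient
excitatory shift of GABAa transmission on 2 interneurons x 22 granule
cells between days 2 and 12.5).  Spontaneous increases of cell activity
(SICA), the model's seizure proxy, are detected on the per-window network
activity as runs exceeding 1.3x a rolling 10-window median baseline.

# Reference behaviour

The default parameterization reproduces this progression in the
stimulation scenario (`rho = 0.2182`, `v = 0.1`):

* flat resting activity at 0.20 before the stimulus;
* ignition at stimulus onset, activity saturating near 1.0, sustained by
  NSE for about 4.5 hours until the pump level overtakes the influx;
* a post-ictal latent period (activity 0.07-0.15, days ~2-8) during which
  the lingering pump current suppresses firing while the compensation rules
  prune inhibition and seed granule-to-granule synapses from the free
  elements released during the event;
* an epileptogenic transition around day 12, when the Hebbian rule ratchets
  the seeded sprouting upward and spontaneous SICAs begin;
* the familiar end-state signature: group I (GC->GC) grown from zero,
  group IV (MC->GC) reduced, group VII (IN->GC) increased.

Scenario severity is ordered throughout: rest runs stay quiet, stimulation
produces the transition, and the transient excitatory GABAa widens it.

# Resolving the under-determined pieces

The published description leaves several elements ambiguous or mutually
inconsistent.  Every resolution below was chosen so that the *documented
behaviour* of the model (stability band, ignition threshold, event
termination, latent period, sprouting) follows from the printed constants;
each alternative reading is retained as an option.

**Mossy-weight assignment and within-population links** (`kappa_rule`,
topology).  With `kappa1` assigned to granule-cell targets and `kappa2` to
mossy-cell and interneuron targets, and with the "projects to all cells"
groups (MC->MC, IN->IN) including the cell's own population (a
self-connection is within-population recurrence at this pooling), the
resting fixed point is (GC 0.202, MC 0.189, IN 0.189) — centred in the
stability band 0.15-0.25 that the weight constants were tuned to reach.
Under the main alternative (kappa1 for all excitatory targets, no
self-links) the resting network sits at 0.11, outside the band.

**Rate-based drive** (`drive`).  The synaptic sums integrate the previous
iteration's firing probabilities.  Binary-state drive is available, but
with only three mossy cells and three interneurons a single discharge swings
the membrane potential by 5-8 units; the network then operates around 0.3
rather than 0.2 and every realization ignites spontaneously.  Binary
discharges are still sampled each iteration and are what the coincidence
counters see, so plasticity remains stochastic.

**Per-target input normalization** (`normalize_inputs`).  Initial weights
are Normal(1.0, 0.2), then each neuron's afferents are rescaled within each
connection group to mean 1.0.  Without this the luck of six large afferent
weights spreads per-neuron operating points by about +/-0.05; some neurons
then exceed the ictal threshold `L = 0.32` at rest and the quiet scenario
ignites for roughly half the seeds.  Homogeneous inputs also explain the
extraordinarily small published rest-state drift (thousandths of a percent
over 41 days): the resting model is a deterministic fixed point, and the
package reproduces drift of that order.

**Ignition condition** (`ns_activity = "probability"`).  The sodium
machinery engages when the *instantaneous* firing probability exceeds
`L = 0.32`.  At stimulus onset the network-wide probability jumps to
`1 / (1 + exp((-1.85 + 1 - 1) / (-2))) = 0.34`: amplitude 1.0 is just
sufficient, 0.5 is not — matching the description of the stimulus as "less
intense but sufficient" for maximal activation.  The slow 150-iteration
average (the `"average"` option) never crosses `L` under any stimulus the
model admits.

**Event termination and the latent period.**  As printed, the state machine
re-enters sustained depolarization the moment NSE dips below NSI; the two
levels then lock just below the saturation level with a strongly
depolarizing net effect, and an ictal event can never end.  The package
makes repolarization *hysteretic* (it runs until NSE drains to its floor)
and, by default, lets the pump level recover only through its intrinsic
decay `d = 5.6e-5` (`pump_recovery = "passive"`).  That decay constant has
a time scale of days and is what produces the post-ictal depression of the
latent period; with the concurrent active drain (`"active"`), NSI empties
together with NSE within hours and no latent period survives.

**Nonsynaptic clock** (`ns_unit = "iteration"`).  The sodium equations take
one Euler step per iteration with the constants as printed.  The pump
accumulation time `1/f` then spans about 357 iterations (2.1 h), the order
of the published afterdischarge duration; stepping by 0.36 min instead
stretches the event to ~6 h.

**Plasticity eligibility.**  The coincidence rules act on *existing*
synapses with excitatory presynaptic neurons.  Letting potentiation act on
empty pair slots wires the granule-cell block to saturation within a single
ictal window (increments `eps * ds_i * ds_j * eta` reach ~14 per pair) and
makes the seizure permanent; letting depression act on inhibitory synapses
strips the interneuron outputs during the event.  New contacts are the
business of the structural recombination, which the Hebbian rule then
amplifies — the division of labour the original mechanism description lays
out.  Within a window the updates are applied in interleaved sub-increments
(`substeps = "auto"`), re-evaluating the saturating gain
`eps(c) = rho / (1 + exp((c - 0.4) / 0.05))` along the way, so large
coincidence counts cannot overshoot the ~0.5 weight ceiling the sigmoid is
there to impose; the one-shot printed form is the `substeps = 1` case and
the two agree for small increments.  Depression uses the same
weight-dependent gain with base `mu`.

**Free parameters `mu` and `k_fpr_H`.**  Neither the anti-Hebbian gain nor
the high-state production rate of free presynaptic elements is given a
value.  `k_fpr_H` defaults to `(0.167/0.033) * 9 * v` (~`45.5 v`), the
closure obtained by extending the printed no-bias symmetry of free-element
rates to the presynaptic class (`k_fpr_L = k_fepo_L = 9 v`); it also makes
the free-element pool released during an ictal event large enough to
sustain rebuilding across the latent period.  `mu` defaults to `rho / 5`,
the strongest depression for which the epileptogenic transition still
occurs: at the moderate activities of the recovery phase, unpreceded
discharges outnumber coincidences (`lambda > eta` whenever firing
probabilities are below one half), so with `mu` near `rho` depression
cancels potentiation and no spontaneous event ever develops.  Both were
fixed from these qualitative requirements, not from any quantitative
target.

**Other conventions.**  The Eq-form saturation of NSE production is read as
`1 - tanh((NSE - 18) / 0.5)`; the GABAa weight modulation defaults to the
transient-suppression form (phi before day 2, ~0 during the inflammatory
window, phi after), with the literal printed product also selectable; the
SICA baseline is the rolling median of the preceding 10 windows; pool
depletion after recombination removes exactly the amounts bound; no new
self-connections are ever formed; degenerate denominators (empty pools,
zero row/column sums) skip their scaling step.

# The synthetic-data generator

The model *is* its own data generator: there are no external inputs.  The
initial connectivity (the nine-group template with sampled granule-cell
afferents and normalized Normal(1.0, 0.2) weights) and the seeded
Bernoulli discharges define the study conditions.  What passing tests show
is therefore internal consistency with the published model description and
its printed constants — not agreement with biological recordings, which
the model only caricatures (no spatial structure, no conduction delays,
six non-granule cells, phenomenological sodium dynamics).

# Problem sizes and determinism

Tests and the acceptance script run the full 105-neuron network; scenario
metrics use 41 simulated days (164,000 iterations, ~20 s per run), the
horizon at which the published activity and connectivity changes are
quoted, with three seeded replicates for the stochastic scenarios and a
2x2 (rho, v) grid for the rest scenario (which is deterministic at the
network level, so a denser grid adds nothing).  Module-level oracle tests
use 4-11 neuron fixtures.  All randomness flows through R's global RNG in
a fixed draw order (topology, initial states, GABAa targets, per-iteration
sampling), so a run is a pure function of its seed.

# Known limitations

* Several published day-41 magnitudes are not reproduced quantitatively
  (see the acceptance materials): the reconstructed dynamics settle into a
  stable reorganized state after the first one or two spontaneous events,
  where the original reports ongoing event activity; the interneuron
  day-41 activity change comes out positive rather than mildly negative,
  and the group-IV reduction is weaker than printed.  The readings above
  were fixed from qualitative milestones before those numbers were
  computed, and left untuned.
* The afterdischarge measured by the event detector lasts ~4.5 h against a
  published ~1.8 h; the pump accumulation constant `f` bounds the sustained
  phase below at ~2.1 h, so the printed duration is only reachable with a
  different (unpublished) measurement convention.
* Event counting is resolution-limited by the 54-minute window and the
  rolling baseline; closely spaced events merge.
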