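---
title: "Modeling lateral and feedforward inhibition in a striatal microcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling lateral and feedforward inhibition in a striatal microcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(striatnet)
```

## The system being modeled

The striatum's principal projection neurons, medium spiny neurons (MSNs),
inhibit one another through sparse, weak GABA-A connections onto distal
dendrites (*lateral inhibition*), and are inhibited by parvalbumin-positive
fast-spiking interneurons (FSIs) through clustered, strong GABA-A contacts
near the soma (*feedforward inhibition*). `striatnet` builds a spatially
explicit network of multicompartment MSN and FSI models, drives it with
structured synaptic input trains, and measures how each kind of inhibition
shapes population spiking: how much uncorrelated activity it removes, how
it treats synchronized ensembles versus background cells, and how large the
underlying unitary IPSPs are.

The package has three tiers:

1. **Anatomy** — compartment scaffolds and distance-gated stochastic wiring
   with empirically constrained contact statistics.
2. **Input generation** — the jitter-and-shift spike-train algorithm that
   produces partially synchronized but randomized input.
3. **Reduced dynamics and analysis** — a passive-cable network simulator
   with a spiking-soma surrogate, paired ON/OFF runs, and the measurement
   procedures (IPSP extraction and fitting, peri-event suppression
   statistics).

## Anatomy

The MSN scaffold has 189 compartments (1 soma, 4 primary dendrites of one
compartment, 8 secondary dendrites of one compartment, 16 tertiary
dendrites of 11 compartments each); the FSI scaffold has 148 (1 soma,
3 primary dendrites of 3 compartments, 6 secondary of 5, 12 tertiary
of 9). The per-dendrite compartment counts are fixed anatomy; the total
counts follow from the binary branching pattern, which is the unique
simple pattern compatible with the totals (for the FSI, `1 + 49P = 148`
forces `P = 3` primary dendrites). Compartment geometry (lengths and
diameters) defaults to generic values giving a roughly 190-micron
soma-to-tip path; the original cell models take their geometry from prior
single-cell work, so these defaults are placeholders that only affect the
reduced dynamics tier and are configurable through `msn_geometry()`.

Synapse targeting follows the anatomy: lateral contacts sample uniformly
over secondary + tertiary compartments, feedforward contacts over
soma + primary, cortical glutamatergic contacts over the MSN's dendritic
(non-soma) compartments and over the whole FSI. Sampling is
per-compartment (not per-length), with replacement: repeated contacts on
one compartment are allowed.

```{r}
msn <- build_msn_scaffold()
c(total = nrow(msn$compartments),
  proximal = length(placement_zone(msn, "feedforward_target")),
  distal = length(placement_zone(msn, "lateral_target")))
```

## Network construction

MSNs sit on a cubic lattice, 20 microns apart, 14 per side (2744 cells) at
full scale; FSIs are interspersed uniformly at 4 FSIs per 90 MSNs
(`floor(2744 * 4/90) = 121`). Ordered MSN pairs within 380 microns connect
with probability 0.155 (1-3 contacts with probabilities 0.83/0.13/0.04);
FSI-to-MSN pairs within 250 microns connect with probability 0.25 (7-12
contacts, uniform). All connections conduct with a 2.4 ms delay.
Self-connections are forbidden, reciprocal connections allowed, and
projections are never wrapped across the cube boundary, so peripheral
cells receive fewer afferents than central ones — a deliberate property of
the open-boundary design that `network_summary()` exposes.

One master seed streams independent sub-seeds to each stochastic stage
(FSI placement, lateral wiring, feedforward wiring, cortical assignment,
input generation) via `derive_seed()`, so a stage can be reproduced
without replaying the ones before it, and a `run_manifest()` suffices to
rebuild everything bit-exactly.

```{r}
net <- build_network(placement_params(n_per_side = 6, seed = 1))
s <- network_summary(net)
round(c(p_lateral = s$p_lateral_realized,
        p_feedforward = s$p_feedforward_realized,
        one_contact = s$lateral_contact_hist[1],
        ff_mean_contacts = s$ff_contact_mean), 3)
```

The network's per-MSN afferent means are reported, not asserted: the
published per-MSN figures (636 lateral contacts from 430 cells, 116
feedforward contacts from 18 FSIs) are not exactly reconcilable with the
stated probability and contact-count rules, so the summary reports what
the rules actually produce.

## Input generation: jitter and shift

Each synapse receives its own train built in three steps: a constant-ISI
scaffold at the target frequency; a Gaussian re-draw of every spike time
(sd `jitter_sd`); a single uniform shift of the whole train in
`[0, shift_max]`. *Uncorrelated* input uses `jitter_sd = ISI/4` and
`shift_max = ISI`; a *shared rhythm* (e.g. the 8 Hz ensemble drive) uses
zero jitter and zero shift and is bit-identical across ensemble members.
This algorithm — rather than a Poisson process — lets partially
synchronized input be generated by simply shrinking the jitter and shift.

Two conventions are ours to state. First, the Gaussian re-draw can reorder
neighbouring spikes at large sd; trains are re-sorted afterwards so spike
times stay strictly increasing. Second, the scaffold extends past both
window edges by `shift_max + 6 * jitter_sd` and the result is clipped to
the half-open window `(0, duration]`. Clipping a one-sided scaffold would
lose about half an ISI's worth of spikes per train on average; with the
symmetric margin, spikes displaced out of the window are balanced in
expectation by spikes displaced in, the restriction of the process to the
window is stationary, and the empirical rate is unbiased at the requested
frequency. Spikes outside the window are dropped, never wrapped, matching
the network's no-wrap philosophy. In the deterministic limit the train is
exactly `ISI, 2*ISI, ...`:

```{r}
generate_train(input_train_spec(100, 100)) # zero jitter, zero shift
mean(vapply(1:50, function(s)
  length(generate_train(uncorrelated_spec(600, 2000, seed = s))) / 2,
  numeric(1)))
```

## The reduced dynamics tier

The original network was simulated with full multichannel membrane
dynamics (fifteen MSN current species, four FSI species, calcium pools).
Those mechanisms are specified in prior single-cell papers and are out of
scope here; `striatnet` replaces them with a reduced tier: passive cable
dynamics on the full compartment trees plus a leaky-integrate-and-fire
surrogate at the soma (threshold, reset, absolute refractory period), and
two-state difference-of-exponentials conductance synapses. The integrator
is a backward-Euler Hines solve over each cell's tree (unconditionally
stable; one elimination sweep and one back-substitution per step),
implemented in C++. Default steps: 0.1 ms for network runs, 0.025 ms for
IPSP studies; a self-convergence test (halving dt) bounds the
discretization error in place of a formal order statement. Synaptic
events, including recurrent spikes after the 2.4 ms delay, are quantized
to the dt grid.

Because the dynamics tier is reduced, every emergent-dynamics claim is
treated as a *directional* property, never a numeric match to full-model
figures: lateral inhibition lowers the mean MSN rate and widens the
across-cell rate distribution at high drive; ensemble spikes suppress
non-ensemble cells in the 5-30 ms window more deeply with lateral
inhibition on; feedforward inhibition spares ensemble cells relative to
non-ensemble cells; desynchronized FSIs suppress at least as much as
synchronized FSIs at matched (or conservatively higher) sync FSI rate; and
ensemble spike-timing sd does not increase with lateral inhibition on.

### Parameters and calibration

Passive membrane: 1 uF/cm^2, leak 5e-5 S/cm^2 (20 ms time constant),
axial resistivity 150 ohm cm, leak reversal -85 mV (MSN, near the
down-state) and -70 mV (FSI). Dendritic spines are not explicit; a factor
of 2 on dendritic capacitance and leak accounts for their membrane area
in the MSN. Soma surrogate: threshold -45 mV, reset -70 mV, refractory
2 ms (MSN); -50 / -65 / 1.5 ms (FSI).

Synapses (per contact): AMPA 0.30 nS onto MSNs and 0.20 nS onto FSIs
(rise 1.1 ms, decay 5.75 ms), a small slow NMDA component (0.06 nS
equivalent, rise 2.8 ms, decay 160 ms; the voltage-dependent magnesium
block is omitted in the reduced tier), and GABA-A 0.09 nS with reversal
-60 mV (rise 0.6 ms, decay 11 ms). Lateral and feedforward contacts share
the single GABA-A conductance — the two projections have approximately
equal per-contact conductances, so the larger feedforward IPSP comes
entirely from contact number (7-12 vs 1-3) and proximal placement. The
GABA-A value is calibrated so that unitary lateral IPSPs measured by the
paired-subtraction protocol fall within the +/-0.2 mV band; with that
single shared conductance, feedforward IPSPs come out 4-8 times larger —
the empirically expected ratio — without any separate tuning.

Because the GABA-A reversal (-60 mV) lies above the MSN resting range,
IPSP polarity depends on the postsynaptic baseline: cells resting below
-60 mV show depolarizing responses, cells held nearer threshold show
hyperpolarizing ones. The signed max/min amplitude rule (below) preserves
this voltage dependence.

### Operating point of the reduced tier

The reduced cell's input-frequency-to-output-rate curve is right-shifted
relative to the full model (a passive LIF cell lacks the regenerative
currents that amplify near-threshold drive). The experiment defaults
therefore match the *output* regime rather than the input frequency:
directional experiments drive MSNs at a summed 1400 Hz (tens-of-Hz output
for active cells), the rate-distribution contrast is read at ~1900 Hz
where the whole population is active, and FSIs are driven at a summed
300 Hz (~50 Hz output) or 600 Hz. The rate-curve sweep itself still covers
the 800-1100 Hz band. Synchronized FSI bursts are produced by gating each
FSI input train to 40 ms windows every 125 ms with an in-burst gain of
3.5, which places the synchronized mean FSI rate slightly *above* the
desynchronized one — so the finding that desynchronized FSIs suppress
more is conservative with respect to rate matching. In the synchronized
mode the input *trains* (glutamatergic and GABAergic) are bit-identical
across FSIs; output spikes are burst-synchronized but not bit-identical,
because each FSI's synapses occupy its own randomly assigned compartments.

## Measurement procedures

**IPSP extraction.** The network is simulated twice on identical inputs
with one inhibition kind toggled; exactly one designated presynaptic cell
is driven above threshold (a synchronized volley across its input
synapses in a 2 ms window, so its first spike time is known and the rest
of the recording is clean), while all other cells receive unique trains
holding them at varied subthreshold baselines (summed rates uniform over
150-750 Hz). For each recorded cell, the difference trace
`ON - OFF` over the 100 ms after the *first* presynaptic spike is taken;
the amplitude is whichever of the max or min has the greater absolute
value; identically zero differences are flagged excluded rather than
counted as zero-amplitude IPSPs.

**Double-exponential fit.** Each IPSP is fit with
`V = scale * (exp(-t/T1) - exp(-t/T2))` by Levenberg-Marquardt least
squares, initialized from the peak location and the late-decay log slope.
The form is symmetric under swapping T1/T2 with a sign flip, so fits are
reported with `T1 >= T2`. `R^2 = 1 - SS_res/SS_tot` (the convention is
ours; the source does not define one), and fits with `R^2 < 0.80` are
discarded. A one-sample z-test, `z = (mean - mu0)/(sd/sqrt(n))`, with the
open interval (-1.96, 1.96) flags equivalence of fitted time constants
with reference values. The sample size behind the published z-values is
not stated; inverting them suggests roughly 47-49 accepted fits, which we
record as an inference only.

**Peri-event statistics.** `perievent_histogram()` bins spike offsets
relative to events (right-closed bins; events near the recording edge are
included with truncated windows). `suppression_fraction()` counts spikes
of a cell subset in the (5, 30) ms post-event window in paired ON/OFF
rasters and reports `ON/OFF` remaining. `ensemble_spike_sd()` pools
offsets of ensemble-cell spikes relative to rhythm events over a
(0, 30) ms response window and returns the population (n-denominator)
standard deviation; the window covers the ensemble response, which peaks
well before 30 ms, while excluding the flat background later in the
125 ms rhythm period that would otherwise dominate the pooled sd.

## What the synthetic data do and do not show

All inputs are generated internally; there is no external data. The
generator reproduces the statistical structure the experiments need —
controlled rates, controlled pairwise synchrony, shared rhythmic
components — but not the burstiness, rate nonstationarity, or spatial
correlation structure of real corticostriatal input. Passing the
directional suite therefore shows that the *wiring rules plus passive
integration* are sufficient to produce the qualitative phenomena (ensemble
self-sharpening, asymmetric feedforward suppression, the sync/desync
contrast); it does not validate the quantitative magnitudes of the
full-biophysics model, which are reported in the literature and not
asserted here.

## Problem sizes and numerical choices

The package's own test and acceptance runs use: the full 2744-MSN network
for wiring statistics (construction only, a few seconds); the 512-MSN
network (the published control scale) for all simulation-based checks,
with 1-1.2 s of simulated time at dt 0.1 ms for directional experiments
and 250 ms at dt 0.025-0.05 ms for IPSP protocols. Degenerate inputs are
handled explicitly: empty event lists error in the histogram, zero
OFF-window spikes error in the suppression fraction, zero sample variance
errors in the z-test, optimizer non-convergence yields a rejected fit
rather than an error, and a designated presynaptic cell that never spikes
aborts the paired protocol.

## Known limitations

- No voltage-gated dendritic or somatic channels: no up/down-state
  bistability, no inward rectification, no spike-frequency adaptation.
  Absolute rates and IPSP kinetics are calibration products, not
  predictions.
- The GABA-A time constants produce fitted decay constants in the
  physiological range but are not fit to any specific voltage-clamp
  dataset.
- D1/D2 subtypes are not distinguished; FSI-FSI gap junctions are not
  modeled (their synchronizing effect is emulated by the identical-input
  condition).
- Output-spike synchrony in the identical-input FSI condition is
  burst-level, not spike-level (synapse placement differs per cell).
- The open boundary means edge cells are under-inhibited; statistics that
  pool over all cells inherit this heterogeneity by design.
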