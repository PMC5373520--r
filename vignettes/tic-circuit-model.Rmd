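---
title: "A firing-rate model of motor tic generation in the basal ganglia-cerebellar-thalamo-cortical loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A firing-rate model of motor tic generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(ticcircuit)
library(dplyr)
```

## The model

`ticcircuit` simulates the motor loop formed by the basal ganglia (BG),
cerebellum, motor thalamus and primary motor cortex (M1) as a network of
leaky-integrator units.  Each unit stands for a neural population; its
activation potential $u$ relaxes toward its input with time constant
$\tau$,

$$\tau \dot u = -u + I, \qquad
I_j = r_j + \sum_i w_{i \to j}\, a_i + n_j,$$

where $r_j$ is a resting potential, $w_{i \to j}$ are signed connection
weights (negative for GABAergic links), and $n_j$ is a fresh Gaussian
sample per unit per integration step.  The activation (population firing
rate) is a rectified, thresholded hyperbolic tangent remapped to the range
$[-400, 400]$:

$$a = \big[\,400 \tanh(u / 400) - \mathrm{thr}\,\big]^+ .$$

Activities are therefore bounded to $[0, 400]$ spikes/s-like units.  We
remap *both* axes of the tanh (unity gain near rest) so that potentials,
firing rates, the printed input pulse heights (17, 30, up to 900) and the
tic-classification threshold (40) all live on one scale; with an
output-only remap a pulse of height 30 would saturate every unit it
touches, which is inconsistent with the input magnitudes the protocol
prescribes.

The circuit comprises 135 units in three topographically matched action
channels: striatal D1- and D2-receptor populations (StrD1, StrD2, 3 units
each), subthalamic nucleus (STN), external pallidum (GPe) and the BG
output (GPi/SNr); two thalamic populations (ThBC receiving both BG and
cerebellar input, ThC receiving cerebellar input only); M1; a Marr-Albus
cerebellar microcircuit (3 mossy-fiber units, 100 granule cells, 1 Golgi
cell, 3 Purkinje cells, 3 dentate units); and one dopamine unit.  Channel
links are one-to-one; the STN projects diffusely (all-to-all) to both
pallidal stations, implementing the hyperdirect "stop everything" drive.
The subthalamo-ponto-cerebellar pathway is abstracted as a direct STN to
mossy-fiber connection, and the inferior-olive timing input as a direct
M1 to Purkinje link; cerebellar learning itself is out of scope.

```{r architecture}
net <- build_network(default_parameters())
net
head(connection_table(net), 8)
```

### Dopamine

Phasic dopamine is a leaky unit driven by a Gaussian burst through an
input gain; its potential is hard-clamped to $[0.01, 0.5]$
(`DA_MIN`/`DA_MAX`).  Striatal inputs are multiplied by
$b_{D1} + d_{D1} a_{DA}$ for the direct pathway and by
$(b_{D1} + d_{D1} a_{DA}) / (b_{D2} + d_{D2} a_{DA})$ for the indirect
pathway — multiplicative excitation versus multiplicative inhibition, with
the D1 factor in the numerator carrying the combined action of both
receptor families.  Under the calibrated coefficients the indirect-pathway
factor *falls* by roughly an order of magnitude as dopamine rises: StrD2
collapses during a burst, GPe is released, and the BG output loses part of
its tonic grip on the thalamus.

```{r da}
tr <- da_trajectory(pulse_spec(50, 0.020, center = 1))
c(peak = max(tr$u_da), at = tr$time_s[which.max(tr$u_da)])
```

### How a tic happens

At rest GPi/SNr fires tonically and clamps ThBC; M1 shows only noise.  A
dopamine burst (1 s into each trial) multiplies the striatal drive, StrD1
rises and StrD2 collapses, and the pallidal gate opens for a few hundred
milliseconds.  If — and only if — M1 simultaneously receives a cortical
input pulse strong enough to pass its activation threshold, the released
thalamo-cortical loop (ThBC to M1 and back, supported by the
cerebello-thalamic route MF → DN → Th) regenerates the seed into a
full-blown activation that saturates one M1 channel: a tic.  The winning
channel's STN output diffusely re-excites the pallidum and, through the
strong pallido-thalamic weight, crushes the competing channels
(winner-take-all); its own channel survives because thalamo-striatal
feedback keeps its StrD1 drive, and hence its pallidal inhibition, locked
in.  As dopamine decays the striatal gate closes and the activation
collapses, terminating the tic.  Either ingredient alone fails: without
dopamine the gate never opens (cortical pulses up to height 900 are shed
through the hyperdirect STN drive), and without cortical input nothing
seeds the loop, because the subthreshold cortical noise cannot pass the M1
activation threshold.

## The simulated-subject protocol

A subject is one 90-s continuous integration at $\Delta t = 1$ ms with ten
monitored 2-s trial windows separated by 7-s gaps (the first window opens
at 4 s, after the circuit has settled; the gap returns every area to its
stochastic baseline, which is what keeps trials independent).  Within each
window the dopamine burst (height 50, SD 0.020 s) and a cortical pulse
(height 17, SD 0.250 s), independently rescaled per channel by
Uniform(0, 1) draws, are centred 1 s in.  A trial is a TIC when the
time-averaged activity of at least one M1 unit over the window exceeds 40
(strictly).  We read the classification quantity as the per-unit *time
average* rather than the peak of the pooled trace: sustained
selection-driven activations yield averages far above 40 while brief
pulse-driven transients — however tall — do not, which is precisely the
distinction the conjunction and dose-response experiments require.

```{r session}
ses <- classify_trials(run_session(default_parameters(), seed = 42))
tidy(ses)
```

Cohorts derive per-subject seeds from a master seed by a counter scheme
(`subject_seed`), so every output is reproducible from one integer.

## Analyses

* **Peak table** (`peak_table()`): for every subject one randomly selected
  trial per state; per pooled area (Dorsal putamen = StrD1+StrD2, GPe,
  GPi, STN, Th = ThBC+ThC, M1, CbllCx = granule+Purkinje layers) the peak
  of the across-unit mean trace.  `area_state_anova()` fits
  `aov(peak ~ area * state)` with a Tukey HSD post hoc, significance at
  p < 0.001.
* **Onset latencies** (`latency_table()`): per subject, area traces are
  averaged over that subject's TIC trials and compared with M1 by
  cross-correlating first-differenced traces, Pearson-normalised at every
  lag.  The reported delay is the lag of the *dominant* correlogram peak
  by absolute correlation: areas that respond with a firing decrease (the
  winning channel's GPi) or biphasically (GPe) produce their strongest
  alignment as a negative peak at their lead, and taking the signed
  maximum instead would systematically miss them.  Positive delays mean
  the area precedes M1; ties break toward the smallest absolute lag.
* **Dose-response** (`dose_response()`): tic counts per subject across 17
  dopamine burst heights from 0 to 100, with brief cortical pulses whose
  height is drawn uniformly from (0, 900); `dose_response_anova()` tests
  the level effect.

```{r cohortsmall}
co <- run_cohort(default_parameters(), n_subjects = 6, master_seed = 301)
glance(co)
latency_table(co) |>
  group_by(area) |>
  summarise(delay_s = mean(delay_s))
```

With the shipped calibration the delays form two clusters: putamen, GPe
and GPi lead M1 by roughly 0.12 s (they move with the dopamine burst),
while STN, thalamus and cerebellar cortex move with M1 itself — the
aberrant activity is born in the striatum and propagates outward along
both the pallido-thalamic and the subthalamo-cerebellar routes.

## Parameters

All parameters live in one flat named vector (`default_parameters()`),
with declared bounds (`parameter_bounds()`).  Hand-set values fix the
operating points a BG action-selection circuit and a Marr-Albus cerebellum
need (tonic pallidal and Purkinje rates, noiseless cerebellar relay
layers, thresholds); the "starred" subset (`starred_parameters()` —
thalamo-cortical gains, cortical efferents, pallidal weights and resting
potentials, cerebello-thalamic and subthalamo-cerebellar weights, dopamine
amplitudes) is the part exposed to the automatic fitter.  **The shipped
values are a package calibration, not the original model's values**: the
reference parameter table of the source model is not available in
machine-readable form, so the defaults were calibrated — exactly as the
original ones were fitted — until the circuit reproduces the reported
system-level phenomena (conjunction requirement, winner-take-all, the
two-cluster latency pattern with a BG lead near 0.12 s, the
area-selective TIC/NO-TIC significance pattern, and a monotone dopamine
dose-response), and then frozen.

Notable numerical choices, each made once:

* Euler integration only, $\Delta t = 1$ ms, with $\Delta t < \tau$
  enforced at construction (smallest $\tau$ = 5 ms).
* Noise is one fresh draw per unit per step added to the input, not
  $\sqrt{\Delta t}$-scaled: noise SDs are defined at the protocol's fixed
  step, matching how the reference model states them.
* Synchronous update: every unit advances from the previous step's
  activations; no update ordering exists.
* The dopamine drive enters through a gain `w_da_in` chosen so that the
  tic-condition burst (height 50) saturates the clamp at 0.5 while the
  no-tic burst (height 1) barely moves the unit.
* The mossy-fiber-to-granule expansion is a hand-designed sparse code:
  each channel recruits nine strongly tuned granule units (under 10% of
  the layer) with weak mixed drive elsewhere, jittered from a fixed
  structural seed; the Golgi cell provides the global inhibition that
  keeps the code sparse under strong drive.
* Granule-to-Purkinje weights are hand-set per the selection scheme:
  zero for selectable channels, a fixed positive (inhibitory) magnitude
  otherwise.  All three channels are selectable by default.
* Ties in the cross-correlogram argmax break toward zero lag; the
  derivative is a plain first difference, no smoothing.

## Fitting and sensitivity

`make_reference_traces()` simulates the tic- and no-tic-condition trials
(no-tic condition: cortical height 30/SD 0.040 s, dopamine height 1/SD
0.600 s) and emits the pooled-area traces as a fitting target, enabling
closed-loop parameter recovery with no external data.  `fit_error()`
simulates the same two conditions under a fixed evaluation seed (common
random numbers, so the objective is deterministic) and returns the MSE
against the target normalised to (0, 1) by the MSE of an all-zero
prediction — a simple, monotone normalisation; the range endpoints are
clipped.  `genetic_fit()` minimises it with tournament selection (size 3),
blend crossover, bounded Gaussian mutation (SD 5% of each bound range) and
elitism, archiving every evaluation.  These operator choices are
conventional defaults, fully configurable, and not claimed to match the
original optimisation; the full-scale preset explores ~2500 candidates
over 300 generations, while the test-scale preset (population 20, 50
generations) already recovers the generating parameters to a normalised
error below 0.08 — the stopping quality the original fit used.
`sensitivity()` keeps the archive's first error quartile, min-max
normalises each parameter over its bounds and ranks by the standard
deviation of the normalised values, ascending: a parameter that good fits
agree on is a parameter the behaviour depends on.

## What the synthetic protocol does and does not show

The generator replaces two things that cannot be shipped: the in-vivo
recordings (its surrogate is the model's own trace set) and the original
fitted parameter vector (its surrogate is the package calibration).
Passing tests therefore demonstrate that the *mechanism* — DA-gated
disinhibition plus coincident cortical drive, resolved by hyperdirect
competition and echoed through the subthalamo-cerebellar route — yields
the reported phenomenology under a realistic calibration; they do not
validate the model against empirical firing rates, and the absolute trace
amplitudes should not be read as predictions for any particular animal.
Known limitations, inherited by design: no overt movement read-out, no
cerebellar or striatal plasticity, no dopamine action in STN, no limbic
loop; the dose-response saturates once the burst height pins the clamped
dopamine potential at its ceiling, so its upper levels differ only through
burst duration.

## Problem sizes

The package's own test suite runs the full reported designs where they are
cheap (40 simulated subjects for the cohort statistics; 40 subjects x 30
trials per level for the dose-response, the single most expensive
computation at roughly twelve minutes) and small parameterised cases
elsewhere.  A single 90-s subject session integrates 135 units for 90,000
steps in under a second with the compiled core.
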