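# ticcircuit

Motor tics — the sudden, involuntary movements of Tourette syndrome — are
classically blamed on excess striatal dopamine, but recordings show the
cerebellum and motor cortex lighting up in concert with the basal ganglia
around every tic. `ticcircuit` is a firing-rate (neural-mass) simulation of
that whole system, built for computational neuroscientists who want to study
*how* a dopamine burst and a coincident cortical activation conspire to
release a tic through basal-ganglia action selection, and what the recently
described subthalamo-ponto-cerebellar pathway contributes.

The model: 135 leaky-integrator units in three competing action channels —
striatum (D1/D2 populations), STN, GPe, GPi/SNr, a two-population motor
thalamus, M1, and a Marr-Albus cerebellar microcircuit (mossy fibers, 100
granule cells, Golgi, Purkinje, dentate) — plus a clamped dopamine unit.
Each unit obeys

    tau * du/dt = -u + I,      I_j = r_j + sum_i w_ij a_i + n_j,
    a = [ 400 tanh(u/400) - thr ]+

with GABAergic weights negative, one Gaussian noise draw per unit per step,
and dopamine multiplying the striatal inputs (excitatory on the direct
pathway, divisive on the indirect one). Tics are classified per 2-s trial:
TIC when some M1 unit's time-averaged activity exceeds 40.

On top of the circuit the package implements the full simulated-subject
experiment: 90-s sessions with ten trial windows, 40-subject cohorts,
tic classification, peak-amplitude ANOVAs (area x movement state, Tukey
post hoc), onset-latency estimation by cross-correlation of trace
derivatives, dopamine dose-response sweeps, genetic-algorithm parameter
fitting against reference firing-rate curves, and a quartile-filtered
sensitivity analysis of the fitting archive.

## A worked example

```r
library(ticcircuit)
library(dplyr)

# one simulated subject: a 90-s session with ten 2-s trials
ses <- run_session(default_parameters(), seed = 42) |> classify_trials()
tidy(ses)
#> # A tibble: 10 x 4
#>    trial label  m1_avg_max m1_peak
#>    <int> <chr>       <dbl>   <dbl>
#>  1     1 TIC         72.5    138.
#>  2     2 TIC         73.7    132.
#>  3     3 TIC         79.9    140.
#>  4     4 TIC         73.6    132.
#>  5     5 NO-TIC       4.80    26.5
#> # ... 10 rows in total, 8 TIC / 2 NO-TIC
```

`m1_avg_max` is the largest per-unit time-averaged M1 activity in the
window — above 40 the trial is a TIC; `m1_peak` is the peak of the pooled
(three-unit mean) M1 trace. In TIC trials a single cortical unit saturates
near 390 — a pooled peak near 130 — while the other two channels stay near
baseline (winner-take-all selection).

```r
# a cohort, and where the aberrant activity starts
co <- run_cohort(default_parameters(), n_subjects = 6, master_seed = 301)
latency_table(co) |> group_by(area) |> summarise(delay_s = mean(delay_s))
#> # A tibble: 7 x 2
#>   area          delay_s
#>   <chr>           <dbl>
#> 1 CbllCx        0.00933
#> 2 DorsalPutamen 0.109
#> 3 GPe           0.124
#> 4 GPi           0.124
#> 5 M1            0
#> 6 STN           0.0113
#> 7 Th            0.0195
```

Positive delays mean the area's onset precedes M1: the putamen and both
pallidal stations lead M1 by roughly 0.11-0.13 s, while STN, thalamus and
cerebellar cortex move together with the cortex — the tic is triggered in
the striatum and propagates outward. `plot_latency()`, `plot_peaks()`,
`plot_trial()` and `plot_dose_response()` draw the corresponding figures,
and `area_state_anova()` / `latency_anova()` / `dose_response_anova()`
reproduce the statistics.

The shipped parameter set is a package calibration (the original model's
parameter table is not available in machine-readable form); it is
documented in `?default_parameters` and the methods vignette
(`vignettes/tic-circuit-model.Rmd`), and a command-line front end lives at
`inst/cli/ticcircuit.R`.

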