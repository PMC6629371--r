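# spinedyn

Longitudinal dendritic-spine dynamics and astrocyte Sholl morphometry in R.

Chronic two-photon imaging tracks the same dendritic protrusions — spines
and filopodia — across imaging sessions spanning days to weeks. The raw
product of that workflow is an annotation table: one row per tracked
feature per session, with a manual present/absent/filopodia call.
`spinedyn` turns such tables into the standard structural-plasticity
statistics, at the animal level, and ships a fully specified synthetic
generator of such tables so every statistic can be verified against known
ground truth. It is written for experimenters analysing cranial-window
imaging data and for methodologists who want the analysis chain itself to
be testable.

## What it computes

**Two-session turnover.** Per mouse, spines are counted as eliminated,
formed or stable between sessions *a* and *b*, and

    TO = (N_elim + N_form) / (N_elim + N_form + 2 N_stable)

**Survival and the two-population stability model.** Per mouse, S(t) is
the fraction of day-0 spines *consistently* present through day t (a
reappearing spine stays dead for the curve). Pooled per-mouse curves are
fit by bounded least squares to the single-phase exponential decay

    S(t) = Sp + Si * exp(-t / tau)

with permanent fraction `Sp`, impermanent fraction `Si`, and
characteristic lifespan `tau` (days); both the generic 3-parameter fit and
the `Si = 1 - Sp` constrained fit are first-class. Day-0 spines are also
classified stable / recurrent / transient, and two genotypes' fits are
compared by the extra sum-of-squares F test for nested least squares.

**Counting statistics.** Filopodial fraction at first imaging, spine
density (spines/µm), and morphology-class fractions.

**Sholl morphometry.** SWC tracings in; intersections per concentric shell
(3D spheres or 2D projection), primary-branch count, longest-tree length
and total process length out.

**Simulation.** A seeded generator of whole cohorts: permanent/impermanent
spine kinetics with continuous lifetimes censored to the imaging schedule,
single-event recurrence, filopodia with fast turnover, Poisson formation
and optional observer misses. Defaults reproduce realistic adult
wild-type study conditions; every knob is documented in
`?simulation_config` and the methods vignette.

## Worked example

```r
library(spinedyn)

cfgs <- list(WT  = simulation_config(n_mice = 7, sp = 0.71),
             CKO = simulation_config(n_mice = 5, sp = 0.79, f0 = 0.12))
tracks <- simulate_cohort(cfgs, seed = 42)

count_turnover(tracks, 0, 7) |>
  dplyr::group_by(genotype) |>
  dplyr::summarise(mean_to = mean(ratio))
#>   genotype mean_to
#> 1 CKO        0.221
#> 2 WT         0.261

curves <- survival_curves(tracks)
fit_decay(curves[curves$genotype == "WT", ])
#> Single-phase exponential decay fit: S(t) = Sp + Si * exp(-t/tau)
#>   Sp  (permanent fraction)   0.6755
#>   Si  (impermanent fraction) 0.3248
#>   tau (lifespan, days)       5.577
#>   SS 0.0180853 on 53 df (56 points)

extra_sum_of_squares_f(curves[curves$genotype == "WT", ],
                       curves[curves$genotype == "CKO", ])
#> Extra sum-of-squares F test (shared vs separate decay fits)
#>   F(3, 90) = 145.0891, p = 2.326e-34
#>   SS null 0.183261 | SS alt 0.0314002
#>   group A: Sp = 0.676, tau = 5.58 | group B: Sp = 0.789, tau = 4.75
```

The mutant cohort, simulated with a higher permanent fraction, fits to
`Sp ≈ 0.79` against `0.68` in the wild type — the separate fits recover
the generating parameters, and the F test flags the group difference.
(Read the p-value with care: per-mouse survival points are serially
correlated, and the vignette quantifies how anti-conservative the pooled
F test is under the null.) Classification localises the difference to the
dynamic classes:

```r
classify_spines(tracks) |>
  dplyr::group_by(genotype) |>
  dplyr::summarise(dplyr::across(dplyr::starts_with("f_"), mean))
#>   genotype f_stable f_recurrent f_transient
#> 1 CKO         0.789      0.0744       0.137
#> 2 WT          0.677      0.122        0.201

arbor_metrics(generate_tree(n_primaries = 7, branch_prob = 0.45,
                            mean_segment_um = 18, seed = 4))
#>   n_primary_branches longest_tree_um total_length_um
#> 1                  7            130.            185.
```

`autoplot()` methods exist for survival curves and Sholl profiles;
`fit_decay()` and `extra_sum_of_squares_f()` return objects with
broom-style `tidy()` and `glance()` methods. `run_pipeline()` chains
simulate/load → turnover → survival → fits → comparison into one
reproducible, manifest-stamped output directory, and
`inst/cli/spinedyn.R` wraps the same functions as shell subcommands.

## Vignette

`vignettes/spine-dynamics-methods.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, the fitting
and geometry numerics, what the simulator does and does not emulate, and
known limitations — including the F-test calibration caveat mentioned
above.
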