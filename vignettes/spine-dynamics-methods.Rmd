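---
title: "Models and methods: longitudinal spine dynamics and Sholl morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: longitudinal spine dynamics and Sholl morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedyn)
```

# The measurement problem

Chronic two-photon imaging through a cranial window follows the same
dendritic protrusions — spines and filopodia — across days to weeks. Trained
observers score each tracked feature as *present*, *absent* or *filopodia*
at every imaging session, yielding a long-format annotation table: one row
per feature per session, labelled by mouse, genotype, age group and
dendrite. `spinedyn` consumes these tables (or simulates them) and computes
the standard structural-plasticity statistics at the animal level.

The imaging schedules built in (`default_schedule()`) are days
0, 1, 2, 7, 14, 21, 28, 42 for adults and 0, 1, 2 for juveniles, with day 0
the first imaging session. Ragged or custom schedules are supported; the
schedule of each mouse is inferred from its rows. A missing session row is
an error, never imputed: the tracking workflow forces an explicit
present/absent call at every timepoint, and silently imputing one would
corrupt the survival statistics below.

# Turnover, filopodial fraction, density, morphology

Between two sessions $a < b$, each analysable feature is **stable**
(present at both), **eliminated** (present at $a$, absent at $b$) or
**formed** (absent at $a$, present at $b$). The two-session turnover ratio
is

$$\mathrm{TO} = \frac{N_\mathrm{elim} + N_\mathrm{form}}
  {N_\mathrm{elim} + N_\mathrm{form} + 2 N_\mathrm{stable}},$$

0 for a static dendrite and 1 for complete replacement. Counts are summed
over all of a mouse's dendrites *before* the ratio is formed, so the animal
is the statistical unit; group summaries should average per-mouse ratios.

Whether features scored *filopodia* belong in a "spine" turnover count is
genuinely ambiguous in practice: presence/absence scoring covers all
protrusions, but turnover is usually reported for spines. Both readings are
first-class here. The default (`include_filopodia = FALSE`) excludes
features filopodial at $a$ from the eliminated/stable counts and features
filopodial at $b$ from the formed count; `include_filopodia = TRUE` treats
any non-absent status as presence. The same flag, with the same meaning,
runs through survival and classification.

The **filopodial fraction** is the proportion of all features present at
the first session that were scored filopodia. **Spine density** is spines
per micrometre of traced segment. **Morphology fractions** tabulate manual
mushroom/intermediate/filopodia scores into per-group fractions summing
to 1. None of these involves modelling; they are counting, and the tests
treat them as such.

# Survival curves and the two-population decay model

For each mouse, the survival fraction at scheduled day $t$ is

$$S(t) = \frac{\#\ \text{day-0 spines consistently present to } t}
  {\#\ \text{day-0 spines}}.$$

*Consistently* is the load-bearing word and the most error-prone reading in
this analysis: a spine absent at any session is dead for the purpose of
$S(t)$ from that session onward, **even if it reappears later**.
Reappearance is captured by the classification below, never by the curve.
Consequently $S(0) = 1$ and $S$ is non-increasing, both enforced and
property-tested. Spines first observed after day 0 never enter the curve;
day-0 filopodia are excluded by default as above.

Day-0 spines partition into three classes: **stable** (observed at every
session), **recurrent** (absent at some session, observed again later) and
**transient** (absent and never seen again). A brute-force oracle written
independently from these rules, enumerated over every possible per-spine
status sequence, pins both the curve and the classification in the tests.

Pooled per-mouse curves are fit to the single-phase exponential decay

$$S(t) = S_p + S_i\, e^{-t/\tau},$$

where $S_p$ is the permanent (plateau) fraction, $S_i$ the impermanent
fraction and $\tau$ (days) the characteristic lifespan of impermanent
spines. Two modes are provided because published fits of this model rarely
state which was used:

* the default three-parameter fit ($S_p$, $S_i$, $\tau$ all free), matching
  a generic plateau-plus-span one-phase decay as commercial software fits
  it; and
* a constrained fit with $S_i \equiv 1 - S_p$ (`constrain_s0 = TRUE`),
  motivated by $S(0) = 1$ holding by construction.

"Pooling" likewise has two readings; the default concatenates all per-mouse
$(t, S)$ points unweighted (curves, not spines, are the unit), and
`weight_by_n = TRUE` weights each point by its curve's day-0 spine count.

## Fitting numerics

The sum of squares is minimised under box constraints
($S_p, S_i \in [0,1]$, $\tau \in (0, 10\,t_{\max}]$) by multi-start
L-BFGS-B: starts at $S_{p,0} = \min S$, $S_{i,0} = 1 - S_{p,0}$ and
$\tau_0 \in \{t_{\max}/4,\ t_{\max}/2,\ t_{\max}\}$, best residual sum of
squares winning at a relative tolerance of $10^{-8}$, followed by one
tightly-converged polish from the winner. A quasi-Newton minimiser was
chosen over `nls()` because zero-residual inputs (noiseless curves, used to
verify exact inversion to $10^{-6}$) are a supported case, not an error.
Degenerate input — all $S$ values identical, e.g. $S \equiv 1$ — makes
$\tau$ unidentifiable and raises an error rather than returning an
arbitrary parameter.

# Comparing groups: the extra sum-of-squares F test

Two genotypes are compared by nested least squares: the null model fits one
shared $(S_p, S_i, \tau)$ to both groups' pooled points, the alternative
fits each group separately, and

$$F = \frac{(SS_\mathrm{null} - SS_\mathrm{alt}) /
  (df_\mathrm{null} - df_\mathrm{alt})}{SS_\mathrm{alt} / df_\mathrm{alt}},
  \qquad SS_\mathrm{alt} = SS_A + SS_B,\quad
  df_\mathrm{alt} = df_A + df_B,$$

with the p-value from the upper tail of
$F(df_\mathrm{null} - df_\mathrm{alt},\ df_\mathrm{alt})$. When both
groups fit perfectly ($SS_\mathrm{alt} = 0$) the statistic is reported as
infinite with $p = 0$ and a degeneracy flag.

## A calibration caveat the package makes measurable

The F test treats every pooled point as carrying an independent residual
degree of freedom. Per-mouse survival points do not satisfy this: all of a
mouse's points are computed from the same few hundred spines, so their
deviations from the true curve are strongly serially correlated — a cohort
of five mice contributes roughly five independent curve-level deviations,
not forty independent residuals. Monte Carlo on the package's own generator
(identical generative parameters in both groups, 5 + 5 mice of 250 spines)
shows the pooled-curve F test rejecting at far above its nominal 5% level,
even though the identical machinery is correctly calibrated when fed
independent Gaussian residuals. Users should read small p-values from this
test as evidence ranking, not as calibrated error rates, unless their
design breaks the within-mouse correlation. The test suite asserts the
nominal-size property and reports its failure rather than hiding it;
statistical power at a realistic effect (permanent fractions 0.71 vs 0.79,
7 vs 5 mice) is essentially 1 under the same conditions.

# The synthetic spine-kinetics generator

`simulation_config()` + `simulate_mouse()`/`simulate_cohort()` generate
cohorts with known ground truth. The model, per mouse:

* **Day-0 pool.** `n_features0` features (default 250, the typical
  analysed count per animal; 150 is the accepted minimum and validation
  warns below it). A fraction `f0` are filopodia; the rest are spines.
* **Two-population kinetics.** Each day-0 spine is permanent with
  probability `sp`, else impermanent with an exponential lifetime of mean
  `tau` days. The lifetime clock is continuous and observation is censored
  to the schedule: a spine dying on day 9 of the adult schedule is last
  seen on day 7. This is the generative inverse of the decay model above,
  so $\mathbb{E}[S(t)] = sp + (1 - sp)e^{-t/\tau}$ exactly, which the tests
  check against closed form at Monte-Carlo precision.
* **Recurrence.** A dead impermanent spine reappears once with probability
  `p_rec`, after a single-session gap, with a fresh exponential lifetime
  and no further recurrence. One reappearance keeps the recurrent class
  well defined; recurrence never touches $S(t)$, by the consistently-present
  rule.
* **Filopodia.** Day-0 filopodia survive each session-to-session step
  independently with probability `p_f`; once gone they stay gone.
* **Formation.** New features arise as a homogeneous Poisson process at
  `lambda` expected features per day per 100 day-0 features, with the same
  permanent/impermanent fate from their formation time. Formed features
  feed turnover's $N_\mathrm{form}$ but never survival or classification
  (those analyse day-0 spines only).
* **Observation noise.** Each truly present observation is independently
  mis-scored absent with probability `p_miss` (default 0). This is how the
  package demonstrates that observation noise inflates the recurrent class
  — a property of the scoring process worth knowing, not an empirical claim
  about any dataset.
* **Determinism.** All randomness flows from one integer seed;
  per-mouse sub-seeds are derived arithmetically from the cohort seed, so
  cohorts reproduce byte-for-byte through `write_track_table()`.

Defaults are the wild-type adult study conditions wherever a measured value
exists: adult schedule, 250 features, `sp = 0.71` (0.79 for the mutant
comparison cohort), `f0 = 0.15` adult / 0.25 juvenile. No measured values
exist for the impermanent lifespan, formation rate, recurrence probability
or filopodium persistence, so these were fixed once at realistic values:
`tau = 5` days (most impermanent cortical spines gone within two to three
weeks), `lambda = 5` (chosen analytically so that juvenile two-day turnover
lands near 0.10–0.15 with formation roughly balancing elimination),
`p_rec = 0.35` (recurrent spines a visible minority of the dynamic pool)
and `p_f = 0.5` (filopodia turn over much faster than spines). An optional
Beta-distributed per-mouse `sp` (`sp_kappa`) adds animal-level
heterogeneity for robustness tests; it is off by default.

What the generator does **not** emulate: dendrite geometry and spatial
clustering of dynamics, spine-to-filopodium interconversion, activity- or
experience-dependent kinetics, observer drift across sessions, and loss of
imaging fields over weeks. Tests passing on this generator therefore
validate the *statistical pipeline* — not the biology of any particular
dataset.

# Sholl morphometry

`read_swc()` parses standard 7-column SWC tracings (single root, validated
parent references, no cycles); the root is the soma centre. For shells of
radius $r = k \cdot \texttt{shell\_step}$ (default 10 µm, matching the
granularity at which astrocyte Sholl profiles are usually displayed;
configurable), each straight segment contributes

* 1 intersection when its endpoints straddle the shell,
* 2 when both endpoints lie outside but its closest approach to the soma
  dips inside (exact for straight segments), and
* 0 otherwise.

Shells are spheres by default (`mode = "3d"`); `mode = "2d"` projects onto
the XY plane for effectively planar brightfield tracings, and the two agree
exactly on planar input. The profile ends at the first radius beyond the
arbor's maximal extent. A dense-sampling oracle (0.01 µm steps, counting
sign changes of distance minus radius) pins the implementation on random
trees, and rigid rotations/translations leave profiles and lengths
unchanged to $10^{-6}$.

Scalar measures: primary branches are the root's children; total process
length is the sum of all segment lengths; one "tree" per primary branch is
the subtree it roots (including the soma-to-child segment) and the longest
tree is the maximal per-tree sum — the subtree-total reading used by common
tracing software. A per-primary path-length reading would be a different
statistic; only the subtree total is computed here.

`generate_tree()` grows reproducible random arbors with ground-truth length
bookkeeping for the oracle tests; denser branching stochastically enlarges
the area under the Sholl profile, which is rank-tested.

# Problem sizes used by the checks

The package's own verification runs at sizes chosen to make Monte-Carlo
error small relative to the tolerances asserted: parameter recovery and
closed-form agreement use 50 simulated mice of 300 spines; F-test size and
power use 1000 and 100 replicate cohorts at 5 + 5 and 7 + 5 mice of 250
spines; oracle equivalence enumerates all $2 \times 3^4$ per-spine status
sequences over five sessions and 100 random trees. The acceptance script
reruns the same computations end to end from a supplied seed.

# Known limitations

* The decay fit reports no parameter uncertainties; the pooled design's
  correlation structure (above) would make naive standard errors
  misleading. A mouse-level bootstrap is the honest route and is left to
  the user.
* Coordinates are stored and round-tripped but unused: no automatic
  identity matching across sessions is attempted — scoring identity is the
  annotator's job upstream.
* The morphology classifier is the human; the package only tabulates.
* Kaplan–Meier-style censoring machinery is deliberately absent: the decay
  model above, fit to interval-censored presence calls, is the analysis
  this pipeline implements.
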