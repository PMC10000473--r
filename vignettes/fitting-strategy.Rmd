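---
title: "Staged fitting and validation of many-parameter physiological models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged fitting and validation of many-parameter physiological models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiofit)
```

## The problem

Structured physiological models — cardiorespiratory models in particular —
routinely carry hundreds of parameters, while a cardiopulmonary exercise
test yields on the order of ten observed variables at a handful of workload
levels. Fitting every parameter at once is both ill-posed and clinically
meaningless. `physiofit` implements a staged strategy: classify parameters
by their role, screen the plausible candidates for identifiability and
sensitivity, select small disjoint sets for three sequential optimization
stages, fit each stage with a bound-constrained CMA-ES under a relative
root-mean-square cost, and validate the result with prediction-error and
transient metrics.

Everything is exercised end to end on **MiniCR**, a compact
cardiorespiratory demo model bundled with the package, together with a
synthetic-cohort generator that provides experimental-style datasets with
known ground truth.

## Parameter roles

Every model parameter is declared with exactly one of five roles:

* **time constants** — shape the transient response only;
* **conversion parameters** — fixed unit equivalences (e.g. the 863 mmHg
  factor of the alveolar air equations);
* **covariates** — simulation conditions recorded with the data (inspired
  gas fractions, barometric pressure, resting metabolic rates);
* **initial values** — integrator initial states;
* **gains and thresholds** — parameters that modulate or saturate model
  mechanisms.

Because the strategy targets steady-state predictions, time constants,
initial values and conversions are discarded up front; covariates are
*standardized* (pinned to the dataset's recorded values) and only the
gain/threshold pool remains as fitting candidates. Parameters that must not
be modified for the simulated population (in MiniCR, the baseline pulse
pressure `PP0`) carry an `excluded` flag and never enter any candidate set.

## The MiniCR demo model

MiniCR keeps the subsystem structure and nonlinearity classes of full-scale
cardiorespiratory exercise models — controller saturation, an exponential
hypoxic chemoreflex, hyperbolic alveolar gas exchange — at desk scale. A
stimulus level is a pair (VO2, VCO2) in L/min. The ventilation controller
is a scalar fixed point in alveolar ventilation VA:

    VA = max(VA_min, Gc (PACO2 - Bc) + Gp exp(-PAO2 / Kp)
                     + Gm dv (1 + Gm2 dv)),      dv = VCO2 - VCO2_rest

with the alveolar gas pressures given by `PACO2 = PICO2 + 863 VCO2 /
(eff_gas VA)` and `PAO2 = PIO2 - 863 VO2 / (eff_gas VA)`. The drive is
strictly decreasing in VA, so the fixed point is unique; it is solved by
bracketed bisection to 1e-10 with a Newton polish (iteration cap 200). The
breathing pattern (BF, VE, VT, TI), the cardiovascular block (HR, CO and
the systemic pressures PS/PM/PD with muscle-pump, respiratory-pump and
vasodilation exercise mechanisms) and first-order transients (one time
constant per subsystem block: 90 s respiratory, 90 s cardiovascular, 300 s
gas exchange) complete the model. Nominal values are chosen inside textbook
physiological ranges so a healthy adult at rest gives HR ≈ 70 bpm, PACO2 ≈
40 mmHg and VE ≈ 8.6 L/min; they live in one versioned registry
(`minicr_model()$registry`) so all tests are deterministic.

Because the transients are exact first-order relaxations between
steady states, the package integrates them with the exact exponential
update rather than a numerical ODE solver; there is no discretization
error beyond the sampling grid.

The second-order gains (`Gm2`, `hr_sat`, `kCO2`, `phi2`) describe the
curvature of the exercise responses (ventilation accelerating toward the
anaerobic threshold, heart rate and cardiac output flattening at high
intensity). They share mechanism/activity tags with their first-order
siblings, which keeps the stimulus-related selection stage meaningfully
populated after the disjointness rules.

## Stimulus protocols

The fitting protocol applies three consecutive, equidistant, incremental
steps — rest, intermediate exercise, anaerobic threshold (VCO2 0.30 / 0.65
/ 1.00 L/min) — each 3000 s long; steady-state values are the signal
average over the last minute of each level. Validation uses eight
equidistant VCO2 steps from 0.3 to 1.0 L/min, with each subject's data
truncated at their anaerobic threshold (the model describes aerobic
exercise only).

## Screening

Two complementary techniques are evaluated on a grid of stimulus levels
and parameter perturbations. The perturbation grid realizes "five
variations uniformly distributed over ±5%" as {−5%, −2.5%, 0, +2.5%, +5%}:
the zero variation is the nominal reference (the sensitivity weighting
1/|h| is undefined at h = 0), and the four nonzero points form the
variation index.

**Subset selection.** For each (level, variation) pair a forward-difference
Jacobian of the residuals (cohort mean minus simulation) with respect to
the candidates is decomposed by SVD. The numerical rank ρ is the number of
singular values above ε times the largest; ε defaults to 1e-6, the square
root of the optimizer's function-evaluation termination tolerance. The
parameter ordering comes from QR with column pivoting applied to the
singular-value-weighted right singular vectors Σ<sub>ρ</sub>V<sub>ρ</sub>ᵀ
— equivalently, pivoted QR of the rank-ρ approximation of the Jacobian.
The weighting matters: the unweighted V<sub>ρ</sub>ᵀ has unit-norm columns
whenever ρ equals the candidate count, which would make the pivot order
arbitrary; the weighted form makes the first pivot exactly the
maximum-norm Jacobian column, and the test suite checks this against an
exhaustive-search oracle. The parameter at pivot position p receives the
normalized singular value σ<sub>p</sub>/σ<sub>1</sub> (positions beyond
the available singular values receive 0), and the per-(level, variation)
assignments are aggregated by root-mean-square over levels first, then
variations, into a single score Z<sub>j</sub>.

**Sensitivity analysis.** The relative steady-state sensitivity
s<sub>ijlk</sub> = |ΔY/Y| · 1/|h| is computed one parameter at a time, RMS
aggregated over variations, normalized within each (variable, level) slice
and weighted by the nominal model's prediction-error share P<sub>ik</sub>
at that slice; a second normalization and error weighting P<sub>i</sub>
across variables yields per-variable scores s<sub>ij</sub> and the total
score s<sub>j</sub>. The error weights are constructed so that they sum
exactly to one over levels and over variables (for the per-variable
weights this requires reading the total-error normalizer as the mean of
the per-variable errors; the alternative reading would break the
normalization). A dataset that happens to match the nominal model exactly
would make the weights 0/0; the package defines that limit as uniform
weights so the invariant is preserved.

Derivatives use forward differences with a relative step of 1e-6 (absolute
floor 1e-9); central differences serve as the independent oracle in the
tests, not as the implementation.

## Selection

Four approaches produce the fitting plan:

1. **Standardization** pins every covariate to the dataset value and
   marks it fixed.
2. **Base set**: all parameters whose Z<sub>j</sub> exceeds ε, plus a walk
   of the s<sub>j</sub> ranking in descending order that admits a
   parameter only if its subsystem is not yet covered, stopping when every
   subsystem with candidates is covered.
3. **Specific set**: one parameter per variable. Candidates exclude the
   base set, parameters of unrelated subsystems (relatedness is a
   model-declared controller↔system adjacency, not inferred) and
   parameters whose error-weighted sensitivity for the variable is below
   1e-6 — that floor keeps out parameters whose apparent sensitivity is
   fixed-point solver noise, such as an inactive saturation bound. The
   qualitative rule "high sensitivity for the variable of interest and low
   for the remaining ones" is made operational as the score
   s̃<sub>ij</sub> − max over unrelated variables of s̃<sub>i′j</sub>,
   with s̃ normalized to [0, 1] within each variable. A parameter serves
   at most one variable; conflicts go to the higher score and the loser
   takes its next candidate. Variables that exhaust their candidates are
   left unassigned with a warning.
4. **Stimulus-related set**: per (mechanism, regulatory activity) pair,
   one tagged parameter not taken by the earlier stages; several
   qualifying parameters are ranked by s<sub>j</sub>.

The three fitted sets are pairwise disjoint by construction and the
package asserts it. Reported reduction percentages use
100·(1 − n/total), rounded to one decimal with ties away from zero.

## Fitting

The cost is the mean over variables of the RMS relative error across
stimulus levels:

    CF = (1/I) Σ_i sqrt( (1/K) Σ_k ((yexp_ik - ysim_ik) / yexp_ik)^2 )

evaluated against the across-subject mean at each level of the three-level
protocol. Evaluation ranges default to ±30% of the nominal value, with
per-parameter literature-style overrides accepted as configuration (e.g. a
respiratory-elastance-like range of −70%/+30%); absolute bounds are
`nominal·(1 + fraction)` with the orientation fixed so bounds stay ordered
for negative nominals.

The optimizer is a (μ/μ_w, λ) CMA-ES written for this package, with
weighted recombination, cumulative step-size adaptation and rank-one plus
rank-μ covariance updates. Its configuration follows the standard
parameterization for this problem class: function-value termination
tolerance 1e-12, tolerance on x of 1e-3, iteration cap 100·N², population
size 4 + floor(3 ln N), initial coordinate step 0.2·(UB − LB) and 10
restarts with a budget of 500 function evaluations per restart (a global
budget of 500 would be unusable next to an N²-scale iteration cap).
Optimization runs in coordinates scaled to [0, 1] over the bound range.
Box constraints are handled by projection repair — candidates are clipped
into the box before evaluation and the repaired point enters the updates —
so every reported value is feasible and the best-ever candidate is
reported, never the last. Restarts are local: each re-centres on the
best-ever point with a halved initial step size, and the tolerance on x is
read relative to the restart's initial step so later restarts refine
further. All randomness is governed by one seed per stage, derived from
the master seed by fixed offsets.

The three stages run sequentially — base, specific, stimulus-related —
with everything fitted earlier (and the standardized covariates) frozen
and the not-yet-fitted parameters at their nominals. Because each stage
starts from the previous stage's result and keeps its best-ever candidate,
the cost is non-increasing across stage boundaries.

A known property of this greedy staging, visible in the package's own
recovery experiments, is cross-stage compensation: when the cohort truth
differs from the nominals in a later stage's parameters, the earlier stage
partially absorbs those residuals with its own parameters (for example,
rescaling cardiac-output gains to absorb a resistance offset through their
product), and later stages cannot fully undo the frozen result. Fitted
values should therefore be read as the stage-constrained optimum, not as
unbiased parameter estimates; the prediction error still improves
monotonically, which is the strategy's target.

## Validation

* **Prediction error**: per variable, the median over all surviving
  (subject, level) pairs — a joint median, not a median of medians — of
  the absolute relative error against the single cohort-level simulation;
  PE is the mean over variables, in percent. The median is used because
  the errors of physiological data are typically non-normal.
* **Percent change from rest**: transient traces normalized to their
  pre-step value.
* **Settling time**: time from stimulus onset until the response enters
  and permanently stays inside a ±5% band around its final value ("final
  entry" semantics, implemented as a suffix scan and tested against a
  brute-force oracle; an overshooting trace that re-exits the band is
  timed from its final entry). A final value numerically at zero falls
  back to a band of 5% of the step magnitude, with a warning.
* **Stage comparison**: paired two-sided Wilcoxon signed-rank tests
  between consecutive stages' per-subject PEs, flagged at 0.05 and 0.01;
  the test is skipped with a warning below five subjects. The Wilcoxon
  test is chosen for the same non-normality reason as the median.

## The synthetic-cohort generator

`generate_cohort()` emulates a cohort of exercise tests: each subject's
true parameters are the cohort truth with multiplicative lognormal
inter-subject variation (applied to gain/threshold parameters only, since
covariates and conversions are shared conditions), observations carry
multiplicative lognormal measurement noise (physiological variables are
positive and their errors scale with magnitude), and each subject receives
an anaerobic threshold drawn uniformly over the window spanned by the
6th–8th levels of the eight-step protocol (never below the first exercise
level for shorter protocols). Both noise factors have mean exactly one, so
zero CVs reproduce the cohort-truth simulation bit-for-bit. One master
seed is expanded into fixed per-subject stream offsets, so enlarging a
cohort never reshuffles the earlier subjects. Defaults are 10%
inter-subject CV and 5% measurement CV.

What the generator does *not* emulate: breath-by-breath or beat-by-beat
signals, missing data, drift within a level, or structural mismatch
between the data-generating system and the model family. Passing recovery
tests on these cohorts therefore demonstrates the machinery's correctness
under the model's own assumptions, not robustness to model misspecification
in real recordings.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at desk
scale: cohorts of 5–20 subjects, three fitting levels, eight validation
levels, the 26-gain MiniCR registry, and the Table-style optimizer budget
of 500 evaluations per restart with 10 restarts per stage. These sizes
were chosen as representative of the method's behaviour while keeping
every experiment deterministic and fast; the screening grid, tolerances
and optimizer settings are the defaults described above, unchanged across
all experiments.

Tie-breaks are deterministic throughout: rankings use stable sorts (ties
keep registry order), the specificity contest resolves equal scores in
variable order, and all random draws are seeded.

## Worked example

```{r example, eval = FALSE}
library(physiofit)

model <- minicr_model()
protocol <- minicr_protocol3()

# synthetic cohort with known ground truth
dataset <- generate_cohort(model, NULL, protocol, n_subjects = 10,
                           noise_model(0.05, 0.03), seed = 1)

# screen, select, fit
screening <- screen_parameters(model, dataset)
plan <- build_selection_plan(model, dataset, screening)
fit <- run_three_stage_fit(model, dataset, plan, seed = 2)
fit$cf_path

# validate on the eight-step protocol, truncated at each subject's AT
val <- truncate_at_AT(generate_cohort(model, NULL, minicr_protocol8(),
                                      10, noise_model(0.05, 0.03),
                                      seed = 1))
report <- validate_model(model,
                         list(nominal = NULL,
                              fitted = fit$fitted_values), val)
report
```

## Known limitations

* The demo model is a stand-in with the same interface as a full-scale
  cardiorespiratory model, not a reproduction of one; absolute outputs are
  plausible, not validated against human data.
* The greedy stage structure bounds parameter-recovery accuracy (see
  above); joint refitting of all selected parameters is out of scope.
* Screening is local (finite differences around the nominal); variance-
  based global sensitivity is a non-goal.
* Time-resolved sensitivities are not computed: the strategy is built
  around steady-state fitting, and transient characteristics enter only
  through the validation metrics.
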