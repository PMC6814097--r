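---
title: "Methods: continuous-time multi-state modelling of long-term-care transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous-time multi-state modelling of long-term-care transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcmarkov)
```

## The model

`ltcmarkov` models an older person's pathway through levels of formal
long-term care as a continuous-time Markov chain on four ordered states:

1. **Non-user** — no formal aged care,
2. **HACC** — home and community care, entry-level support at home,
3. **RAC** — permanent residential aged care,
4. **Death** — absorbing.

The default structure allows the six forward moves 1→2, 1→3, 1→4, 2→3,
2→4 and 3→4 and no reverse moves: once a person has entered a level of
care they do not return to a lower level, so the process is progressive.
The chain is governed by a generator matrix \(Q\) whose off-diagonal
entry \(q_{ij}\) is the instantaneous intensity (events per year) of
moving from state \(i\) to state \(j\), with \(q_{ii} = -\sum_{j \ne i}
q_{ij}\). Transition probabilities over a duration \(t\) follow from the
matrix exponential, \(P(t) = \exp(tQ)\), and the memoryless property
makes contributions of disjoint observation intervals independent.

Covariates act proportionally on each intensity:
\[
q_{ij}(z) = q_{ij}^{(0)} \exp\!\big(\beta_{ij}^{\mathsf T} z\big),
\]
so \(\exp(\beta)\) is a hazard ratio specific to one transition.
Covariates are *time-fixed at baseline* in this implementation. The
formulation would admit piecewise-constant time-dependent covariates (a
subject's generator would then change at covariate-change times), and
`build_generator()` is the single extension point where that would be
added, but it is not implemented: the cohorts this package emulates
measure covariates once, at baseline. Each transition carries its own
coefficient vector; nothing constrains a covariate's effect to be shared
across transitions, mirroring a report with one hazard-ratio column per
transition.

All times are in years, with time 0 the common baseline for every
subject. A common time origin is an assumption, not a theorem: in a
calendar-entry cohort subjects could in principle be staggered, but with
time-fixed covariates and a time-homogeneous generator only durations
matter, so the choice is immaterial to the likelihood.

## Observation types and the likelihood

Longitudinal care data mix three kinds of information, and the panel
likelihood multiplies the matching terms per consecutive observation
pair (subject held state `from` at the earlier time):

* **snapshot** — the state is known at the two endpoints only:
  contribution \(P_{\text{from},\text{to}}(\Delta t)\). Used for survey
  waves and for administrative censoring.
* **exact_transition** — the move is dated exactly and the subject is
  known to have held `from` throughout:
  \(\exp(-q_{\text{from}}\Delta t)\, q_{\text{from},\text{to}}\), the
  competing-risks density, where \(q_{\text{from}}\) is the total exit
  rate.
* **exact_death** — death is dated exactly but the state immediately
  beforehand is unknown:
  \(\sum_{r \ne \text{Death}} P_{\text{from},r}(\Delta t)\,
  q_{r,\text{Death}}\), which integrates over the unobserved pre-death
  state and equals \(\tfrac{d}{dt}P_{\text{from},\text{Death}}(t)\) at
  \(\Delta t\).

**Matching the observation type to the information content matters.**
When every care entry is exactly recorded (the administrative-record
situation the default `"exact"` simulation scheme emulates), the state
before death *is* known — it is the last recorded state, held since that
record, because any further move would itself have been recorded. The
correct death term is then the competing-risks density, and
`observe_cohort()` therefore types deaths as `exact_transition` under
the exact scheme. Using the unknown-pre-death sum on such data is not
merely conservative, it is a misspecified likelihood: the sum credits
probability to pre-death pathways that the (absent) records exclude, and
in our checks this inflated the RAC→Death intensity and deflated the
direct death intensities by many standard errors. The `exact_death`
convention is the right one — and the default — for the panel schemes,
where moves after the last survey wave are genuinely unobserved; it
remains available everywhere via `observe_cohort(..., death_obs =
"unknown")` for sensitivity analysis.

Maximisation is by BFGS on the unconstrained scale (log baseline
intensities, raw coefficients), started from crude rates (observed
direct events per person-year at risk; for fully dated data these are
already near the maximum). The covariance is the inverse of the
observed information, obtained by central finite differences of the
log-likelihood at the optimum; convergence additionally requires the
numerically differentiated gradient to be negligible relative to the
log-likelihood's magnitude. A structurally allowed transition with no
observed events is reported as a boundary diagnostic
(`ltc_boundary_warning`): its rate drifts towards zero and its standard
error is meaningless. A singular information matrix is flagged and the
covariance withheld rather than silently inverted.

Interval estimates use the conventional 1.96 normal quantile at the 95%
level. Derived quantities get first-order delta-method intervals with a
range-respecting link: log scale for rate ratios, sojourn times and
other positive quantities, logit scale for probabilities, identity
otherwise. The gradient of the derived map is computed by central
differences, so any differentiable scalar functional of the parameter
vector can be interval-estimated with `delta_method_ci()`.

## Numerical choices

* **Matrix exponential.** `transition_probability_matrix()` uses a
  degree-13 Padé approximant with scaling and squaring on the full
  matrix. That choice is robust to the near-repeated eigenvalues that
  break eigendecomposition methods (two states with similar total exit
  rates). The progressive structure (upper-triangular \(Q\), hence
  triangular \(P(t)\)) is exploited only as a test invariant, never in
  the computation.
* **Likelihood inner loop.** Evaluating many \(P(t)\) under one
  generator dominates fitting cost, so the likelihood groups subjects by
  covariate pattern and, per pattern, uses the spectral form
  \(P(t) = V e^{\Lambda t} V^{-1}\) vectorised over all required
  durations — after verifying that the eigendecomposition reconstructs
  \(Q\) to 1e-9. If that check fails (defective or ill-conditioned
  \(Q\)), it falls back to per-duration scaling-and-squaring. Both
  routes are cross-checked against each other and against an independent
  stiff-ODE integration of the forward equations \(dP/dt = PQ\) in the
  test suite.
* **Overflow guard.** A linear predictor with \(|\log q^{(0)} +
  \beta^{\mathsf T} z| > 30\) raises an error naming the transition
  rather than silently saturating `exp()`; during optimisation such
  proposals are rejected with a large objective value.
* **Ties and degenerate input.** Tied observation times within a
  subject are a data error, never silently reordered; zero-length
  intervals are rejected; an observed move of probability zero yields
  \(-\infty\) with a diagnostic naming the subject and interval.
* **Quadrature.** `total_length_of_stay()` integrates
  \(P_{\text{start},\text{target}}(t)\) by adaptive quadrature
  (relative tolerance 1e-10) over a finite horizon, and uses the
  fundamental matrix \((-Q_{TT})^{-1}\) of the transient class for an
  infinite horizon.

## Calibrated defaults of the synthetic cohort

The restricted linked cohort that motivates the package is not publicly
deposited, so `default_true_model()` generates stand-in cohorts whose
*generating* parameters are calibrated from published marginal
summaries; the truth file written alongside simulated data labels them
as such.

* Non-user: total exit rate \(1/7.95\) per year (published mean stay),
  split across HACC, RAC and Death by the next-state distribution
  implied by the published transition-rate ratios 11.08 (HACC vs RAC)
  and 7.72 (HACC vs Death), giving
  \(q_{12} = 0.10312,\; q_{13} = 0.00931,\; q_{14} = 0.01336\).
* HACC: total exit \(1/5.04\), split .63/.37 between RAC and Death:
  \(q_{23} = 0.12500,\; q_{24} = 0.07341\). (A narrative figure of 4.9
  years also circulates for this stay; the tabulated 5.04 with its
  confidence interval is taken as authoritative.) The .63/.37 split is
  the published probability pair itself; splitting instead by the
  published ratio 1.69 would give 0.12465/0.07376 — identical at the
  2-decimal precision of the sources.
* RAC: \(q_{34} = 1/2.51 = 0.39841\).

Two internal-consistency facts anchor this calibration and are asserted
in the tests: the implied next-state probabilities reproduce the
published .82/.07/.11 and .63/.37 at two decimals, and
\(\exp(-10/7.95) = 0.284\) reproduces the published 10-year probability
of remaining a non-user (.28). The published table also lists a
RAC-vs-Death rate ratio of 1.44 for the non-user exits; from the other
two ratios this equals \(11.08/7.72\), i.e. the larger-over-smaller
ordering (the literal \(q_{13}/q_{14}\) is its reciprocal, 0.70) — the
package reports the honest ratio and the consistency check compares the
ratio of ratios.

Baseline covariates are drawn independently: age uniform on [75, 82]
years (so the median is close to the published 78; `age_c` = age − 78 is
provided for centred use), and binary indicators at the published
prevalences — non-major-city residence 0.567, widowed 0.459, income
difficulty 0.256, arthritis 0.488, heart problem 0.191, diabetes 0.096,
asthma 0.133, falls with injury 0.123. Independence is a simplification:
the source publishes only marginals, and no joint distribution is
asserted. Covariate effects are off by default (all \(\beta = 0\)), so
the defaults describe a homogeneous cohort whose marginal behaviour
matches the published summaries. Two effect presets supply known truth
for recovery studies: `"hr15"`, a single binary covariate with hazard
ratio 1.5 on the 1→2 transition — the minimal configuration in which
effect recovery and interval coverage can be scored — and `"published-hr"`,
the full published hazard-ratio matrix with age entered as the centred
`age_c` (so the calibrated baselines remain those of a 78-year-old at
the indicator reference).

Simulation draws one exponential waiting time per allowed exit of the
current state and takes the earliest (competing risks — identical in law
to total-rate-plus-multinomial, with simpler invariants), truncating at
the 10-year administrative horizon. A master seed derives one stream per
subject, so cohorts are reproducible and order-independent. There is no
random loss to follow-up by default, no survey non-response, no
sampling weights, and no exclusion cascade; these belong to the design
of a real study, not to the probabilistic model under test.

**What passing tests do and do not show.** The generator produces
exactly Markov trajectories with exponential sojourns, independent
covariates and uninformative censoring. Tests against it verify that
the estimation machinery is correct *under the model's own assumptions*
— they cannot detect, in real data, non-Markov dependence on history
(for instance dementia progressively raising RAC risk, which is
deliberately absent here), duration-dependent intensities, informative
censoring, or covariate effects that vary over time.

## Evaluation profile and reporting conventions

Derived summaries from a covariate model are evaluated at the reference
profile — every covariate at 0 — unless a profile is supplied; supplied
values override the reference entry-wise. With uncentred age this
reference is an extrapolation, which is why the generator's effect
presets use centred age; fits of user data may prefer `age_c`
likewise. Display rounding follows the reporting convention of the
field: probabilities, ratios and years to two decimals.

"Average length of stay" is read as the **mean sojourn time**
\(1/(-q_{ii})\) — the single reading under which the published 7.95-year
non-user stay and the published .28 ten-year stay probability are
mutually consistent. The windowed alternative, expected total time in a
state over a horizon \(\int_0^T P_{1j}(t)\,dt\), is provided separately
as `total_length_of_stay()` for sensitivity analysis; the two differ
whenever a state can be entered late or re-entered.

## Problem sizes used in the checks

The test suite exercises desk-scale cohorts (tens to hundreds of
subjects) for unit behaviour, and study-scale runs for the statistical
checks: recovery of the six baseline intensities and of a known hazard
ratio at n = 5000 with ten replicate cohorts for interval coverage;
simulator fidelity at n = 50000 (closed-form occupancy and next-state
distribution within three Monte-Carlo standard errors); and
observed-versus-expected prevalence self-consistency at n = 10000 with
a 2% ceiling on the maximum normalised discrepancy. These sizes were
chosen to make three-standard-error bands decisive for the quantities
under test.

## Known limitations

* Time-homogeneous intensities: no age-as-timescale or calendar trends;
  the 10-year window of the emulated design keeps this tolerable, but
  longer horizons would want a time-varying baseline.
* Time-fixed covariates; no frailty or random effects.
* Progressive-by-default: reversible structures are representable and
  computed correctly, but none of the calibration, presets or reports
  are tuned for them.
* No hidden-Markov layer: observed states are taken as true states
  (no misclassification).
* The prevalence comparison is a plot-style diagnostic, not a formal
  goodness-of-fit test.
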