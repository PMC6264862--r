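---
title: "Stratifying children from binary symptom diaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying children from binary symptom diaries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diarystrat)
```

## The problem

Prospective paediatric cohorts often collect daily diaries in which
parents tick, for each of about ten symptoms (cough, cold, wheeze,
eczema, fever, ...), whether the symptom was present that day. Over a
three-year follow-up this yields, per child, a long multivariate binary
signal with strong seasonality, multi-day illness episodes, staggered
enrolment dates, and dropout. The scientific goal served by this
package is methodological: turn such diaries into representations on
which standard unsupervised models can stratify children, and fit those
models.

Two representations are built:

* **Shape-based.** Diaries are aligned on the calendar so that signals
  can be compared point by point, then summarized to monthly symptom
  proportions, giving a children x symptoms x 36-months tensor.
* **Pattern-based.** Each day's symptom combination is encoded as a
  binary string ("110" = first two symptoms present, third absent);
  a diary-year is reduced to the counts of these patterns — a
  bag-of-patterns that ignores time ordering entirely.

The shape branch feeds non-negative matrix factorization (on the
matricized tensor) and INDSCAL (on pointwise dissimilarities); the
pattern branch feeds latent Dirichlet allocation. The package also
contains a full synthetic-cohort generator, because the original
clinical diaries are not publicly deposited: the generator is the
canonical input source for tests and worked analyses.

## The synthetic cohort generator

`simulate_cohort()` generates each symptom of each child as a two-state
Markov chain. On day $d$ of the calendar year the probability of a new
episode starting is

$$p^{\text{on}}_{m}(d) = \operatorname{logit}^{-1}\!\big(\mu_m + s_{c m}
  + A_m \cos(2\pi (d - \phi_m)/365.25) + \kappa E_d\big),$$

and an ongoing symptom persists with probability $p^{\text{stay}}_m$.
Here $\mu_m$ is the baseline onset log-odds, $A_m$ and $\phi_m$ the
seasonal amplitude and peak day, $s_{cm}$ the shift contributed by the
child's latent class $c$, and $E_d$ a shared latent infection-episode
chain (itself seasonal) that couples cough, cold and fever with
strength $\kappa$, producing realistic co-occurring multi-day episodes.

Choices worth making explicit:

* **Seasonality is driven by calendar day, not age.** That is the
  premise under which calendar alignment is the right correction; age
  effects are deliberately absent so that what the shape branch aligns
  is exactly what the generator varies.
* **Default prevalences.** The cold chain is calibrated so its periodic
  stationary prevalence (computable exactly with
  `seasonal_prevalence()`) peaks near 30% of days in mid-January and
  falls to about 5% in summer; cough is similar, eczema is persistent
  ($p^{\text{stay}} = 0.97$) and nearly aseasonal, pneumonia is rare.
  These are round numbers in the range reported for symptom diaries in
  young children, not fits to any particular cohort.
* **Latent classes.** Three phenotypes with *directional* contrasts:
  respiratory-dominant (cough/cold/wheeze onset raised by 1.0–1.8
  log-odds), eczema-dominant (+2.5 on eczema), and
  febrile/gastrointestinal (+1.2–1.8 on fever, gastric, ear infection).
  An early design with a "mild" class that simply lowered all
  log-odds was discarded: a class that differs only in overall
  magnitude loads on the same components as its high-burden
  counterpart, so no score-argmax clustering can recover it, and such a
  cohort cannot serve for recovery testing. Directional phenotypes are
  also the scientifically interesting case for stratification.
* **Missingness.** Applied after symptom generation and independently
  of it: a daily dropout hazard with spikes at half-year ages (182,
  365, ..., 1095 days; parents tend to quit at round ages or after
  scheduled visits) plus short random gaps. The default hazard
  (`base_hazard` 4e-5, `spike_hazard` 0.013) is calibrated so about 10%
  of children have left by age 2.5 years. Because dropout never reads
  the symptom states, burden and diary length are uncorrelated by
  construction — tests verify $|r| < 0.1$ — which mirrors the
  missing-at-random diagnostic the analysis itself performs.
* **Stationary starts.** Every chain (symptoms and the episode
  process) is initialised from its stationary law evaluated at the
  enrolment day rather than from the healthy state. Symptoms do not
  reset when a child enters a study, and an all-healthy start would
  bias the first weeks of every diary downward — enough to induce a
  spurious burden-length correlation in short diaries.
* A missing day is a *present row with all symptoms `NA`*, never an
  absent row, so diary length and missingness stay separable; gap days
  in files are re-materialized on read. Leap days are simulated and
  counted as February days.

What the generator does **not** emulate: age-dependent maturation
(e.g. wheeze declining over years), between-year severity differences,
reporting artifacts (weekend effects, backfilling), partially missing
days, or any dependence of dropout on symptoms. Tests passing on this
cohort therefore demonstrate correctness of the pipeline's mechanics
and recoverability under the stated model — not robustness to those
real-data phenomena.

## Inclusion rules

A month-slot is acceptable when its calendar month was observed on at
least (days-in-month − 15) fully recorded days. A diary enters the
shape representation iff all 36 slots are acceptable (`shape_inclusion()`);
it is `complete` if no day at all is missing. For the pattern branch
each participation year (slots 1–12, 13–24, 25–36) becomes one
diary-year row iff all twelve of its slots are acceptable, and years
are included *prefix-wise*: a later year cannot enter once an earlier
year has failed. The per-year rule deliberately reuses the per-month
tolerance — no separate definition of "sufficient data" exists for the
pattern branch, and reuse keeps the two strata nested (every
shape-included diary contributes exactly three rows). A consequence of
assigning days to their true calendar months is that a child enrolled
late in a month has a partial, hence unacceptable, first month; with a
three-year window roughly half of the enrolment dates are compatible
with full inclusion, which is the main driver of the inclusion counts
on simulated cohorts.

## Calendar alignment (shape branch)

`assign_slots()` formalizes cut-and-reposition: the $i$-th
chronological occurrence of calendar month $\mu$ in a diary maps to
slot (relative year $i$, month $\mu$). For a 36-month diary this is a
bijection onto the 36-slot grid regardless of enrolment month (tested
exhaustively over all twelve), and repositioning merely permutes
months — values are unchanged, serial ordering across years is
sacrificed. Days falling in a fourth occurrence of a month (the tail
of a diary enrolled mid-year) are dropped. Monthly proportions divide
by *observed* days, not calendar days, so that up to 15 tolerated
missing days bias the estimate as little as possible; a slot with no
acceptable data is `NA` and excluded upstream. Matricization is
symptom-major (column $(m-1)T + t$); the order is a labelling
convention only.

## The models

**NMF.** `fit_nmf()` minimises $\|\check X - U V'\|_F^2$ with the
classical multiplicative updates, $\varepsilon = 10^{-12}$ in the
denominators to avoid zero-locking, convergence when the relative SSE
change drops below `tol` (1e-6 by default), and the best of 25
uniform(0,1) restarts (per-start seed = seed + start) retained. The
objective is provably non-increasing under these updates and the test
suite asserts the trace every iteration; agreement with an independent
alternating-NNLS oracle from the same initialisation is verified to
1e-8 on random instances. Scale indeterminacy is fixed by unit-maximum
columns of $V$. `rank_sweep()` reports, per rank $r$, the explained
variance and its increment over rank $r-1$ — interpreted per model,
not per component, as the components are not orthogonal. For an
all-zero matrix explained variance is defined as 1 to keep the scree
well-defined.

**INDSCAL.** `build_dissimilarity()` forms
$d_{ii'l} = |x_{itm} - x_{i'tm}|$ for condition $l = (m-1)T + t$
(absolute difference by default; squared as an option — the
convention is not settled and the choice is exposed).
`fit_indscal()` fits $d_{ii'l} \approx \sum_r a_{ir} a_{i'r} c_{lr}$
by the practical coupled-ALS strategy: both object modes are updated
by unconstrained least squares, sign-aligned, averaged and re-imposed,
then each row of $C$ is solved by non-negative least squares. Only the
condition mode is constrained non-negative; child coordinates may take
either sign. The averaging step means monotonicity of the SSE is not
guaranteed in exact arithmetic, but on all tested instances the trace
is non-increasing to 1e-10. The rowwise NNLS shares one normal matrix
$(A'A) \circ (A'A)$ across all $L$ conditions, so it is solved exactly
by enumerating active sets (unique KKT point; verified against
`pracma::lsqnonneg`, which remains the fallback for many components).
Columns of $A$ are normalised to unit norm with the (squared) scale
moved into $C$.

**LDA.** Each diary-year is a document whose tokens are its daily
patterns; the all-zero "healthy" day emits no token (Table-style
frequency matrices list only symptomatic patterns; a flag restores the
healthy pattern for sensitivity analyses). `fit_lda_gibbs()` runs a
collapsed Gibbs sampler (compiled inner loop, R's RNG for exact seed
reproducibility) with full conditional
$p(z_i = k) \propto (n_{jk}^- + \alpha)(n_{kg}^- + \eta)/(n_k^- + G\eta)$.
Defaults: $K = 4$, $\eta = 0.1$, $\alpha = 50/K$, 10000 sweeps with
2000 burn-in, every 10th retained. Point estimates are means of
Rao-Blackwellized draws; because averaging can mix label-switched
states, single-last-draw estimates are returned alongside. The
hyperparameters are, by default, re-estimated along the chain by a
symmetric-Dirichlet fixed-point step every 50 sweeps (`hyper_update =
FALSE` gives exact-prior runs); the estimator behind the reported
weights is exposed via the `estimator` argument of `top_terms()`
since either convention is defensible.

## Problem sizes and budgets

The worked analyses and the end-to-end default (`default_run_config()`)
use 300 simulated children; the NMF sweep keeps the full 25 restarts
over ranks 1–8, while INDSCAL runs 2 restarts with at most 250 ALS
sweeps and LDA runs a 1500-sweep chain with 300 burn-in. These sizes
were chosen so a complete run finishes in minutes on a single core
while leaving every qualitative feature (scree levelling, component
interpretation, topic separation) intact; module-level defaults retain
the full settings. Recovery tests use smaller planted instances (20–240
children or 200 documents) where ground truth makes sharp assertions
possible.

## Known limitations

* The inclusion rules assume daily-resolution, contiguous diaries; no
  imputation is offered, and nonignorable dropout is only diagnosed
  graphically (burden vs length), not modelled.
* INDSCAL's coupled-ALS is the standard practical algorithm, not a
  certified-monotone symmetric factorization; pathological inputs could
  in principle produce transient SSE increases.
* Averaged LDA posteriors are meaningful only while the chain stays in
  one labelling; for short chains on weakly separated corpora prefer
  the last-draw estimator.
* The alternative calendar alignment that keeps empty leading/trailing
  positions, year-of-measurement covariates, multi-day patterns and
  sub-year stratification of the frequency matrix are out of scope.
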