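# diarystrat

Stratification of young children from daily binary symptom diaries.

Paediatric cohort studies often ask parents to record, every day for
up to three years, whether each of ~10 illness symptoms (cough, cold,
wheeze, eczema, fever, ...) was present. The result is, per child, a
long multivariate 0/1 signal with strong winter-peaked seasonality,
multi-day illness episodes, staggered enrolment dates and dropout.
`diarystrat` is for methodologists and epidemiologists working with
such diaries: it turns them into two analysable representations and
fits three unsupervised stratification models, all implemented from
scratch in the package.

**Representations**

* *Shape-based*: diaries are centred on the calendar and
  cut-and-repositioned (the segment before a 1 January moves twelve
  months later, cascading), then summarized to monthly symptom
  proportions — an `I x M x 36` tensor `X̄`, matricized to `X̌`
  (`I x 36M`) for two-way analysis. Diaries qualify when every month
  has at most 15 missing days.
* *Pattern-based*: each day's symptom combination becomes a binary
  code (`"110"` = cough + cold, no wheeze); each qualifying diary-year
  becomes a row of counts over the observed pattern vocabulary — a
  document-term matrix `F` in which healthy days emit nothing.

**Models**

* `fit_nmf()` — non-negative matrix factorization of `X̌` by
  multiplicative updates (`X̌ ≈ U Vᵀ`, `U, V ≥ 0`), best of 25
  restarts, with the additional-explained-variance scree over ranks
  1–8 (`rank_sweep()`).
* `fit_indscal()` — INDSCAL on the tensor of pointwise between-child
  dissimilarities `d_{ii′l} = |x_{itm} − x_{i′tm}|`
  (`d_{ii′l} ≈ Σ_r a_{ir} a_{i′r} c_{lr}`, condition weights `C ≥ 0`),
  by coupled alternating least squares.
* `fit_lda_gibbs()` — latent Dirichlet allocation on `F` by collapsed
  Gibbs sampling (compiled inner loop; defaults K = 4, η = 0.1,
  α = 50/K, 10000 sweeps / 2000 burn-in, hyperparameters updated along
  the chain), with `top_terms()` for topic interpretation.

Because real clinical diaries of this kind are not publicly deposited,
the package ships a first-class synthetic cohort generator
(`simulate_cohort()`): seasonal two-state Markov chains per symptom,
three latent phenotypes (respiratory, eczema, febrile/gastro), a
shared infection-episode process coupling cough/cold/fever, and
burden-independent dropout with half-year hazard spikes. Ground truth
comes along for recovery testing.

## Worked example

The `analysis/` scripts run the complete study on a 300-child
simulated cohort (`Rscript analysis/01_simulate.R`, then `02`–`07`).
Abbreviated output of an actual run:

```
Simulated 300 diaries (39-1096 days; 89% reach the full 1096 days).
<inclusion> 300 diaries: 0 complete, 156 shape-included (<= 15
  missing days/month in all 36 months), 476 pattern diary-years
Tensor: 156 children x 10 symptoms x 36 month slots.
Mean cold proportion: January y1 0.45 vs July y1 0.11 (seasonality preserved).

Explained variance by rank:        # NMF scree
  rank explained_variance additional_ev
1    1              0.534         0.534
2    2              0.639         0.105
3    3              0.659         0.020
4    4              0.672         0.012
Component 2: cough (0.67), cold (0.56), wheeze (0.31)
Component 3: eczema (0.85), cough (0.22), cold (0.20)

3-component INDSCAL: EV 54.2% after 55 ALS sweeps.
Component 3 top symptoms: eczema (59.587), cough (9.924), cold (9.000)

239 distinct patterns over 476 diary-years (of 2^10 = 1024 possible).
Top five patterns per topic:
      Topic 2               Topic 4
rank1 Cough (0.26)          Eczema (0.55)
rank2 Cold (0.19)           Cough + Eczema (0.11)
rank3 Cough + Cold (0.18)   Cold + Eczema (0.11)
```

Reading it: about half the cohort survives the 15-missing-days rule in
all 36 aligned months; the cold curve keeps its winter peak after
alignment; the NMF scree levels off after ~3 components whose loadings
separate the respiratory and eczema phenotypes; INDSCAL finds one
general-prevalence component plus discriminative ones; and LDA's
topics are directly readable as symptom-combination profiles, one per
planted phenotype plus a mixed respiratory topic. A single call
`run_pipeline(default_run_config(seed = 1), "results/run")` produces
the same artifacts in one go, and `report_run()` renders the figures
from the CSVs alone.

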