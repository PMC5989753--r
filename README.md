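# ebmstage

Event-based modelling of Alzheimer's-related cognitive decline, with
cross-sectional staging and group comparison — built for cohorts of adults
with Down syndrome assessed on a battery of 16 cognitive and
informant-rated outcomes, and exercised end-to-end on synthetic cohorts
with a known ground truth.

## The problem and the model

Adults with Down syndrome carry an exceptionally high genetic risk of
Alzheimer's disease, but measuring decline is hard: baseline ability varies
with premorbid intellectual-disability (ID) level, floor effects are
common, and cohorts are cross-sectional snapshots of people at very
different points of progression. The event-based model (EBM) treats
progression as a fixed sequence in which biomarkers (here, test and
questionnaire scores) transition from a *normal* to an *abnormal*
distribution, and infers that sequence from a single cross-section.

For biomarker *i* with measurement *x_ij* on participant *j*, two-component
mixture models supply `P(x|E_i)` (abnormal) and `P(x|¬E_i)` (normal). The
data likelihood of an event sequence *S* marginalises each participant's
unknown stage *k*:

    P(X|S) = Π_j Σ_{k=0..I} Π_{i≤k} P(x_{S(i)j} | E_{S(i)})
                            Π_{i>k} P(x_{S(i)j} | ¬E_{S(i)})

The pipeline:

1. **Imputation** — participants who attempted but could not understand a
   task score zero (worst recorded latency for reaction time);
   questionnaire items missing up to 15% per domain are imputed with the
   nearest integer to the completed-item mean.
2. **Residualization** — scores are regressed on ID level in the young-adult
   (YA, 16–35, pre-decline) group only; those coefficients residualize
   everyone, removing baseline-ability differences without removing decline.
3. **Mixtures** — per biomarker, a semisupervised two-component KDE mixture
   initialised from the YA / older-adult (OA, ≥36) split.
4. **Ordering** — greedy ascent plus Metropolis MCMC over permutations
   maximises `P(X|S)`; positional variance diagrams (PVDs) summarise MCMC
   and bootstrap uncertainty.
5. **Staging** — each participant gets the maximum-likelihood stage 0..16.
6. **Comparison** — Mann–Whitney U tests compare stage distributions:
   YA vs OA, dementia vs none (within OA), and APOE4 vs APOE2/APOE3
   (within age group, APOE 2:4 carriers omitted).

The synthetic-cohort generator is a first-class module: it draws cohorts
with a latent true event sequence, per-participant stages, truncated
score distributions calibrated to the battery's published YA/OA summaries,
ID-level offsets, questionnaire missingness and task non-engagement, so
every downstream stage is testable against ground truth.

## Worked example

```r
library(ebmstage)
sim <- generate_cohort(cohort_config(seed = 1, separation = 2))
fit <- run_ebm_pipeline(sim$cohort, seed = 1, n_iter = 30000, burn_in = 3000)
print(fit)
```

```
Event-based model fit
  participants: 283  biomarkers: 16
  log-likelihood: -15348.209
  maximum-likelihood event sequence (earliest first):
    1. tower_of_london
    2. ied_stages
    3. obj_mem_immediate
    ...
    16. nepsy_car_motorbike
```

The fitted sequence here exactly matches the generator's latent ordering
(Kendall tau 1.0), and assigned stages track latent stages at Spearman
rho 0.96. The group contrasts recover the planted structure:

```r
print(fit$contrasts, digits = 3)
```

```
                     contrast group n_a n_b     U        p      direction
1                    YA_vs_OA   all 164 119 18192 6.70e-38       OA later
2  dementia_vs_none_within_OA    OA  54 110  5896 9.90e-25 dementia later
5 APOE4_vs_APOE2_within_group    OA  33  19   418 4.56e-02    APOE4 later
6 APOE4_vs_APOE3_within_group    OA  33  96  2488 9.79e-07    APOE4 later
```

`U` is the Mann–Whitney statistic for the first-named group; small `p` with
"OA later" means older adults are staged significantly later than young
adults. The APOE contrasts within the YA group are non-significant, as
expected for a pre-decline group.

## Command line

```sh
Rscript inst/cli/ebmstage.R run-all --seed 1 --out results/run1 --n-boot 100
```

Subcommands `simulate`, `preprocess`, `fit`, `bootstrap`, `stage`,
`compare`, `run-all`; every run writes a manifest (seed, config hash,
versions) next to its outputs. Cohorts are plain CSV (schema: demographic
columns, `score_<biomarker>` and `eng_<biomarker>` columns; `NA` for
missing — see `?generate_cohort`).

## Vignette

`vignettes/event-based-staging.Rmd` documents the model assumptions, the
anchored semisupervised mixture refinement, what the synthetic generator
does and does not emulate, numerical choices, and known limitations.
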