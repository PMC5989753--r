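---
title: "Event-based staging of cognitive decline: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based staging of cognitive decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebmstage)
```

## The model and its assumptions

The event-based model (EBM) assumes disease progression is a single fixed
sequence of *events*, each event being one biomarker's transition from its
premorbid ("normal") distribution to an "abnormal" one. A participant at
stage $k$ has experienced exactly the first $k$ events of the sequence.
Given per-biomarker densities $P(x\,|\,E_i)$ and $P(x\,|\,\neg E_i)$, the
likelihood of a sequence $S$ marginalises every participant's unknown
stage:

$$P(X|S) \;=\; \prod_{j=1}^{J} \sum_{k=0}^{I}
  \Big[\tfrac{1}{I+1}\Big]
  \prod_{i \le k} P\!\big(x_{S(i)j}\,|\,E_{S(i)}\big)
  \prod_{i > k} P\!\big(x_{S(i)j}\,|\,\neg E_{S(i)}\big)$$

Assumptions worth keeping in mind: one common ordering for the whole
population (no subtypes); cross-sectional exchangeability (age enters only
through the YA/OA design labels, not as a progression clock); and
conditional independence of biomarkers given the stage. The uniform stage
prior $1/(I+1)$ is constant in $S$, so the maximum-likelihood ordering is
identical with or without it; `stage_prior = FALSE` recovers the bare
sum-of-products form.

Staging uses the same machinery per participant:
$\hat k_j = \arg\max_k \prod_{i\le k} P(x_{S(i)j}|E) \prod_{i>k}
P(x_{S(i)j}|\neg E)$, computed in log space, ties broken toward the
smaller stage (conservatively favouring "no decline"). A missing biomarker
contributes the uninformative pair $P(x|E)=P(x|\neg E)$, which makes the
participant's likelihood invariant to where that biomarker sits; everyone
is stageable, including participants who completed almost nothing (they are
flagged).

## The anchored semisupervised mixture fit

Each biomarker's two components are Gaussian-kernel densities over the
ID-level residuals, initialised from the YA/OA labels and refined by
alternating responsibility/refit steps until the mean absolute
responsibility change drops below `1e-4` (at most 200 steps).

Three structural choices stabilise this fit, and all three exist because a
two-component mixture of *free-form* KDEs is not identifiable from the
marginal alone. In fact the relabelling iteration leaves the implied
marginal $w f_E + (1-w) f_{\neg E}$ exactly equal to the pooled KDE at
every step, so there is no likelihood being optimised — stability has to
come from the refinement's design:

* **One pooled bandwidth per biomarker** (Silverman's rule on the full
  sample), shared by both components. Component-specific bandwidths
  recomputed from the evolving weights degenerate when a component's mass
  concentrates on a few points, producing spiky or washed-out density
  ratios.
* **Monotone responsibilities.** Each update is projected (pool-adjacent-
  violators) onto responsibilities monotone in the score: the probability
  of being abnormal may not recover toward the healthy side. This is the
  unimodality constraint expressed in the only scale-free way available to
  a nonparametric component.
* **Premorbid-range anchors.** The model defines an event as a transition
  outside the premorbid range, which supplies two label anchors: the YA
  *core* (inside a Tukey-style fence on the declining side) keeps
  responsibility 0, and any score beyond that core's declining-side extreme
  keeps responsibility 1. YA values beyond the fence stay free — they may
  be genuinely declined controls, and hard-anchoring them makes the fit
  fragile to control contamination (mislabelling 10% of the disease group
  as controls moves the abnormality posterior by less than 0.01 on average
  in the packaged smoke test). When no observation lies beyond the core —
  typical when a task floor pools controls and patients at one value — the
  declining-side extreme of the disease group seeds the abnormal component
  instead; otherwise that component collapses onto the pooled density and
  the biomarker silently loses all ordering information. Anchors are
  applied after the monotone projection so that premorbid participants
  sitting at a task floor do not drag the projected curve down.

The fitted mixture weight is reported but never fed back multiplicatively
without the anchors; it is the anchor structure that prevents the
rich-get-richer drift in which one flexible component absorbs the sample.

## Search, sampling, and uncertainty

The ordering search runs greedy ascent (best pairwise swap to a local
optimum, 10 random restarts) followed by a Metropolis chain whose proposal
swaps two uniformly chosen positions (default 100&nbsp;000 iterations,
10&nbsp;000 burn-in; the study-scale problem of $I=16$, $J=283$ runs in
seconds through the compiled likelihood). On every small instance checked
against exhaustive enumeration the combination attains the global optimum,
and replicate-level audits at study scale found no case where a larger
budget improved the result.

The MCMC positional variance diagram uses the chain's *current state* at
each post-burn-in iteration, so sequences are weighted by dwell time;
accepted-states-only summaries are available (`accepted_only = TRUE`), and
on our instances both look alike because the acceptance decision dominates
dwell time.

Bootstrap uncertainty resamples participants with replacement (stratified
by age group so the mixture initialisation never loses a group), re-runs
preprocessing, mixtures and search per replicate, and summarises replicate
maximum-likelihood sequences as a PVD. Replicate chains default to
20&nbsp;000 iterations — the greedy fit already sits at the optimum, and
the audit above applies. Note the bootstrap PVD is the *stricter*
uncertainty estimate: replicate orderings typically differ from the
full-data sequence by adjacent-position swaps, and an exact-position
diagonal penalises each swap twice. At the generator's strong-separation
regime the diagonal mass sits around 0.7–0.8 at $n_\text{boot}=25$, below
the in-sample MCMC diagonal.

## What the generator emulates, and what it does not

`generate_cohort()` draws YA/OA cohorts (defaults 119/164) with a latent
uniformly-random true sequence, latent stages (YA at 0 with a 5% leak; OA
uniform over 0..16), and scores from truncated Gaussians whose pre-event
parameters match the battery's published YA means/SDs. The post-event
location is `pre + separation × 2 × (OA − YA mean)`: under a uniform OA
stage distribution roughly half the OA group is past any given event, so
the published OA mean is close to an equal mixture and the factor 2
back-solves the post-event component. `separation = 1` is that calibration;
`separation = 2` is the "strong separation" regime used in validation.
ID-level offsets (+0.5 / 0 / −1 pre-event SDs on the healthy side for
mild/moderate/severe) are applied to direct tests before truncation,
deliberately non-linear in the ordinal coding so residualization is
realistic rather than exact. Dementia labels follow a logistic in stage
(midpoint 12, slope 1.5, giving the published ~26% OA prevalence), and the
APOE4 group receives a +5-stage shift, chosen once as a plausible strong
effect; published analyses report direction, not magnitude. Floors arise naturally
from truncation — fewer than 1% of YA floor on delayed object memory, as
in the study population.

Not emulated: longitudinal follow-up, mosaicism, age as a continuous
severity gradient within groups, item-level questionnaire structure (the
generator emits domain totals; the 15% item rule is exercised on
synthetic item vectors), and any correlation between biomarkers beyond
that induced by the shared stage. A green recovery test therefore
establishes that the pipeline inverts its own generative assumptions at
realistic sizes and noise — not that the clinical sequence reported for
any real cohort is correct.

## Numerical choices

* Densities are clipped below at `1e-12` before entering likelihoods;
  products are computed as sums of logs throughout.
* ID level is coded ordinally (mild = 1, moderate = 2, severe = 3) for the
  residual regression, matching its monotone severity semantics; dummy
  coding is available (`coding = "dummy"`).
* Questionnaire imputation rounds half away from zero (a mean of 2.5
  imputes 3).
* The SRT "poorest score recorded" is taken over the whole cohort, not
  the participant's age group.
* Residualization happens after performance-score imputation, so imputed
  zeros are adjusted for ID level like any other score.
* Mann–Whitney `U` uses midranks; p-values come from the tie-corrected
  normal approximation with continuity correction, with the exact null
  distribution substituted for tie-free groups when
  $n_a n_b \le 400$. Two-sided p-values are reported and no
  multiple-testing correction is applied across the contrasts.
* Serialized mixture fits store doubles at 17 significant digits, which
  round-trips IEEE values exactly.

## Known limitations

* Stage-16 censoring: participants past every event and those well past
  the last few are indistinguishable; the top stage accumulates mass.
* Heavily floored biomarkers carry little ordering information once both
  groups pool at the floor; the premorbid-extreme anchor keeps them
  late-and-uninformative rather than misplaced, but their fitted position
  is wide.
* The bootstrap PVD diagonal understates ordering quality when adjacent
  events are genuinely exchangeable; read it together with the replicate
  Kendall taus.
* The conditional-independence assumption is violated by any
  stage-independent correlation between outcomes of the same instrument
  (e.g. the two KBIT-2 subscales); the generator does not model this, so
  the tests do not probe it.
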