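---
title: "Methods: sequence and rate analysis of collective escape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence and rate analysis of collective escape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockescape)
```

# The scientific problem

When a bird flock is chased by an aerial predator, its members coordinate
into discrete, nameable patterns of collective escape: collective turns,
compacting, splits, dives, merges, blackening, flash expansions, cordons and
wave events. Field experiments with a remotely piloted robotic falcon (and a
conventional drone as a non-raptor control) make such chases repeatable: each
chase is a trial with known covariates — target species, predator type,
chase duration, the proportion of the chase spent in active pursuit or
attack ("chasing intensity"), approach altitude class, the operator — and an
event log of timed predator acts and escape patterns.

`flockescape` implements the statistical chain such an experiment needs:

1. **Descriptive summaries**: per-chase escape counts and per-minute rates,
   per-cell chase counts and mean durations, and the within-chase
   composition of escape types.
2. **Sequence analysis**: which escape pattern tends to follow which
   predator act or escape pattern, tested against a fixed-margin permutation
   null.
3. **Rate models**: Poisson mixed models of per-chase escape counts with
   Type-II Wald tests, marginal means and Tukey contrasts; an
   altitude-binned rate model; a pooled two-sample comparison of robotic and
   wild-falcon chases.
4. **A synthetic generator** with known ground truth, so every stage can be
   validated end to end without field data.

# The follow rule and the transition matrix

An event B *follows* an event A when B's onset lies in the half-open window
`(0, w]` seconds after A's onset, within the same chase; the default window
is `w = 5` s. Simultaneous onsets are not transitions — with onsets coded
from video at fixed frame times, ties carry no order information, so we
ignore them rather than break them arbitrarily.

Two pairing conventions are implemented because the verbal rule admits both:

* `all_pairs` (default): every ordered pair inside the window counts. This
  is the literal reading of "displayed within an interval of 5 s".
* `next_event`: each antecedent is paired only with the first eligible event
  after it, the stricter lag-sequential convention.

The convention in force is carried in every output. Only predator *attacks*
enter the matrix among predator acts, as antecedents by default: pursuit and
not-chasing describe chase phases that are already summarised by chasing
intensity, and an escape pattern "causing" a later attack is not a
hypothesis the matrix is built to test (a configuration flag admits attacks
as subsequents for completeness). Transitions are counted per chase and
pooled within a species x predator-type panel.

# The fixed-margin permutation null

Whether a transition count is large is judged against tables that preserve
both margins — how often each antecedent fired, and how often each
subsequent occurred — but are otherwise random: the multiple-hypergeometric
distribution, sampled by Patefield's algorithm (AS 159). Cells are filled
row-wise, each drawn from its exact conditional hypergeometric distribution
given the margins still unallocated, with log-factorial weights; margins are
exact in every draw. The sampler is compiled (Rcpp) and is validated in the
test suite against two independent routes: exhaustive enumeration of all
tables with small totals under the closed-form probability
$P(a) = \frac{\prod_i r_i!\ \prod_j c_j!}{N!\ \prod_{ij} a_{ij}!}$, and the
distribution of an independent implementation of the same algorithm
(`r2dtable`).

Per cell, with $G$ null tables at or above the observed count and $L$ at or
below it, the two-tailed Monte-Carlo p-value is

$$p = \min\!\left(1,\ \frac{2(\min(G, L) + 1)}{n_{\mathrm{null}} + 1}\right),$$

the add-one form that keeps $p > 0$ and is standard for Monte-Carlo
permutation tests. The default ensemble size is 100 000 tables; the
heavier validation suites in this package run at 10 000, which bounds the
attainable p at $2 \times 10^{-4}$ — ample for screening transitions at
$\alpha = 0.05$.

Two deliberate choices:

* **The null is conditioned per panel**: each species x predator matrix is
  tested against its own margins, not pooled margins, because the question
  is about sequential structure *within* a panel's observed behavioural
  budget.
* **No multiplicity correction by default**, matching the per-transition
  reporting convention of the field; Benjamini–Hochberg is available and
  flagged in all outputs when used. Note that BH at $\alpha = 0.05$ is
  stricter than it may look: on p-values (0.001, 0.04, 0.04, 0.9) only the
  first survives, since $0.04 > \tfrac{3}{4} \times 0.05$.

## Calibration of the discrete two-tailed test

The doubled-tail Monte-Carlo p-value on integer counts is *valid but
conservative*: $P(p \le \alpha)$ is at most $\alpha$ and strictly below it
for cells whose conditional distribution is coarse. Our validation suite
quantifies this under the generator's own study conditions (a starling
panel with roughly 560 pooled transitions over 90 cells, most of them
rare): the pooled rejection rate at $\alpha = 0.05$ under the null is about
0.012 overall, rising monotonically with the cell's null mean — about 0.005
for cells with null mean below 1 and about 0.046 for cells above 20 —
and never exceeding the nominal level. A test that a *continuity-assuming*
two-sided envelope around exactly 5% holds is therefore expected to fail
low on such matrices, and the corresponding check in the acceptance suite
documents precisely that: the test errs only on the safe side. Flagged
transitions are, if anything, under-reported; none are spurious beyond the
nominal rate.

# The Poisson mixed model of escape counts

Per-chase escape counts are modelled as Poisson with log link:

$$\log \mathbb{E}[y_i] = \mathbf{x}_i^\top\beta + u_{\mathrm{chase}(i)} + v_{\mathrm{operator}(i)},$$

with fixed effects for species (reference: corvids), predator type
(reference: drone), chasing intensity (a proportion), chase duration
(seconds) and a multi-species-flock flag, plus the two-way interactions
species x intensity, species x predator and predator x intensity; and
random intercepts for operator and for chase. The chase intercept is
*observation-level* (one count per chase): it is specified as a random
effect in its own right and doubles as the standard device absorbing
extra-Poisson variation. Estimation is maximum likelihood with the Laplace
approximation (`lme4::glmer`); with no random intercepts the model reduces
to the ordinary Poisson regression MLE, a reduction the test suite checks
against an independent direct maximisation of the likelihood to within
1e-6.

Further choices worth stating:

* **Duration as covariate, not offset.** A covariate with coefficient
  around 0.004 per second says escape *counts* grow sub-proportionally with
  chase length, which an offset would force to proportionality. The offset
  variant exists (`offset_duration = TRUE`) as a sensitivity analysis.
* **Covariates on their natural scale** (seconds, proportion), so
  coefficients read directly as per-second and per-unit-intensity log-rate
  changes.
* **Overdispersion** is assessed on the fixed-effects-only fit — the
  observation-level intercept would otherwise absorb exactly the variation
  being tested — as the Pearson statistic over residual degrees of freedom,
  with an upper chi-squared tail test.
* **Term tests** are Type-II Wald chi-squared (via `car::Anova`):
  multi-level factors are tested jointly, each term after the others at its
  level, which is the convention matching the reported per-term
  chi-squared/p layout.
* **Model pruning** ("best model") removes, in a single pass, every
  interaction whose Type-II p is at or above 0.05, then refits; main
  effects are never removed. Single-pass (rather than stepwise re-testing
  after each removal) is a deliberate, reproducible choice: it is
  deterministic given the full fit and matches the one-significant-
  interaction pattern this analysis is typically applied to. The audit
  trail of removals is part of the result.
* **Marginal means and contrasts** (via `emmeans`): factor-level means on a
  balanced reference grid with covariates at their observed means,
  back-transformed to expected escapes per chase, with delta-method
  standard errors; all pairwise link-scale contrasts with z-ratios and
  Tukey (studentized-range) family-wise adjustment — the conventional post
  hoc default when the adjustment is not otherwise specified.

## The altitude analysis

To ask whether approach altitude (high: above 50 m; low: below) changes the
escape rate *after* flight initiation, each chase with known altitude class
is cut into 20-second bins (`[(b-1) \cdot 20, b \cdot 20)`; the final
partial bin keeps its true width), and bin counts are modelled as Poisson
on altitude class and bin index with a chase-level random intercept and a
`log(width)` offset. The offset makes partial bins contribute through their
real exposure: doubling all widths with counts fixed shifts the intercept
by exactly $-\log 2$ and leaves the altitude term untouched, a property the
suite verifies. The random-effect structure (a chase intercept) is an
assumption — bin counts within a chase share that chase's idiosyncrasies —
stated here because nothing in the source analyses pins it down.

## The robotic-vs-wild-falcon comparison

Starling per-chase escape counts under the robotic falcon versus wild
falcon hunts are compared with Student's pooled-variance two-sample t-test.
The pooled form is used because the reported degrees of freedom
($n_a + n_b - 2$; 67 for groups of 23 and 46) identify it — Welch degrees
of freedom would generally differ — and a Welch variant is available.

# The synthetic generator

`simulate_dataset()` draws chase covariates, per-chase random effects and
within-chase event streams with fully known ground truth. Its defaults *are*
the study conditions of the motivating field campaign, and are not tuned
thereafter:

* design cells: robotic falcon 15/20/8/23 chases on
  corvids/gulls/lapwings/starlings; drone 19/19/18 with no lapwing chases;
* durations log-normal with predator-type means of about 70 s (robotic
  falcon) and 132 s (drone), log-scale sd 0.6; chasing intensity
  Beta(2, 2); a 0.15 probability of a multi-species flock (mixed corvid and
  gull flocks occur; the exact share is a realistic choice, not a reported
  value); two operators;
* rate coefficients equal to the campaign's fitted values (intercept 0.778;
  gulls -1.390, lapwings -0.932, starlings 0.353; robotic falcon 1.002;
  intensity 0.483; duration 0.00441 per second), with interaction and
  multi-species coefficients — for which no fitted values exist — at 0;
  observation-level sd `sqrt(0.1808)` and operator sd `sqrt(8.481e-8)`,
  the square roots of the reported variances;
* attacks as a Poisson process at 2 per minute scaled by chasing intensity;
  escape events as a Poisson count with the model-implied mean, spread
  uniformly over the chase;
* escape labels drawn from a baseline kernel following the observed
  qualitative ordering (turns 0.56, compacting 0.24, splits 0.11, all other
  patterns below 6%), tilted by log-odds enrichments when the *most recent*
  event within the follow window matches an enrichment's antecedent.
  Default enrichments: attack -> flash expansion (+2), flash expansion ->
  split (+2), compacting -> collective turn (+1), the qualitative sequence
  structure reported in the field. The most-recent-antecedent rule keeps
  the ground truth analytically simple; it is weaker than tilting on every
  antecedent in the window.
* altitude classes randomised 1:1 for robotic-falcon chases with a default
  altitude effect of 0 (none was detected in the field).

One global seed drives a per-chase seed sequence, so a dataset is
reproducible as a whole and each chase independently regenerable.

**What the generator does and does not emulate.** It reproduces the
*statistical* structure the analyses consume: Poisson count structure with
observation-level heterogeneity, covariate-dependent rates, and pairwise
sequential enrichment over an independence kernel. It does not simulate
flocking itself — no positions, no self-propelled particles, no
within-chase nonstationarity (the escape rate is flat over a chase), no
behavioural bouts or refractory periods, and event labels depend on at most
one antecedent. Passing tests therefore demonstrate that the estimators
recover the truth *under this model*, not that real flocks satisfy the
model.

# Numerical choices and degenerate inputs

* Permutation p-values are bounded below by `1/(n_null + 1)`; direction is
  `over`/`under` by comparison with the null mean, `none` on exact
  equality.
* The sampler's conditional CDF inversion uses a ratio recurrence from the
  support's lower end, in log-factorial form; margins are validated
  (non-negative integers, equal sums) before any draw. A zero margin forces
  its row or column to zero in every table; `n_null = 0` is a valid empty
  ensemble.
* GLMM convergence uses `nloptwrap` (BOBYQA) with lme4 defaults
  (log-likelihood changes below about 1e-8 at convergence); non-convergence
  is flagged on the returned object, never silent. Rank-deficient designs
  abort naming the aliased columns — notably species x predator when one
  species lacks chases under one predator, in which case the pipeline
  requests only estimable interactions.
* The standard error of a single observation is reported absent (`NA`), not
  0; chases with no escape events are excluded from composition shares (a
  share of nothing is undefined) and reported.
* Events at exactly the chase's end fall in the final altitude bin; an
  event at exactly the follow-window edge is a transition.

# Problem sizes used in validation

The validation suites are sized to establish each property with modest
Monte-Carlo error while staying quick on one core: sampler goodness-of-fit
at 10 000 draws per margin set; permutation-null calibration over 200
replicate matrices at 10 000 null tables each; planted-enrichment power
over 100 seeded replicates of 50 chases; parameter recovery over 150
replicates of a balanced 400-chase design (with per-coefficient bias
bounds and coverage pooled across coefficients, where per-coefficient
coverage at these replicate counts would be dominated by binomial noise);
altitude type-I error over 200 and power over 60 replicates. The acceptance
script re-runs the same computations from scratch at these sizes.

# Known limitations

* The permutation test's conservativeness on sparse cells (above) means low
  power for rare transitions; pooling chases into panels is the main
  defence, and `next_event` pairing sharpens interpretation but discards
  counts.
* The Laplace approximation can bias variance components slightly downward
  with one observation per random-effect level; the recovery suite bounds
  the consequence for fixed effects (log-scale bias below 0.05) but the
  OLRE variance itself is recovered less precisely.
* Type-II Wald tests assume the usual asymptotics; for very small panels
  the likelihood-ratio variant (available through `car::Anova` on the
  underlying fit) is preferable.
* The pipeline's robotic-vs-wild-falcon stage needs wild-falcon chases in
  the same event-log format; wild hunts lack chasing-intensity and operator
  covariates, which is why that comparison is a two-sample test rather than
  a term in the mixed model.
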