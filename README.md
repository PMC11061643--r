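# flockescape

Statistical analysis of **collective escape behaviour in bird flocks chased
by an artificial aerial predator** — a remotely piloted robotic falcon, with
a conventional drone as control and wild peregrine-falcon hunts as a
comparison group. The package is written for quantitative ethologists
running such chase experiments: each chase is a trial with covariates
(species, predator type, duration, chasing intensity, approach altitude,
operator) and an ethogram-coded event log of timed predator acts (attack,
pursuit, not chasing) and escape patterns (collective turn, compacting,
split, dive, merge, blackening, flash expansion, cordon, wave event).

It implements the full analysis chain:

* **Ethogram data model** — CSV readers/writers with validation
  (`read_events()`, `read_chases()`, `validate_dataset()`, a BORIS-style
  importer), per-chase escape counts and per-minute rates, cell summaries
  and within-chase escape-type composition.
* **Sequence analysis** — behaviour B *follows* A when its onset falls in
  the half-open window $(0, w]$ s after A's onset ($w = 5$ by default),
  within the same chase. `build_transitions()` pools the ordered-pair
  counts per species x predator panel; `permutation_test()` judges each
  cell against $n_{\mathrm{null}}$ random tables with the observed row and
  column margins, drawn from the multiple-hypergeometric distribution by
  Patefield's algorithm (AS 159, compiled), with the two-tailed
  Monte-Carlo p-value
  $p = \min\bigl(1,\; 2(\min(G,L)+1)/(n_{\mathrm{null}}+1)\bigr)$,
  where $G$ and $L$ count null tables at or above / at or below the
  observed cell.
* **Rate models** — Poisson log-link mixed model of per-chase escape
  counts, $\log \mathbb{E}[y_i] = \mathbf{x}_i^\top\beta + u_{\text{chase}(i)} +
  v_{\text{operator}(i)}$, with an observation-level chase intercept;
  Type-II Wald term tests, overdispersion check, interaction pruning,
  estimated marginal means with Tukey pairwise contrasts; a 20-s-binned
  altitude model with `log(width)` offset; and the pooled-variance
  two-sample robot-vs-wild-falcon comparison.
* **Synthetic generator** — `simulate_dataset()` draws chase metadata and
  within-chase event streams with known ground truth (Poisson rate
  structure for counts, a baseline escape-pattern kernel tilted by
  configurable antecedent enrichments for sequences), so the whole chain is
  testable end to end.
* **Pipeline** — `run_pipeline()` executes every stage, writes CSV
  artefacts and a manifest with seed and config hash; a thin shell wrapper
  lives in `inst/scripts/run_pipeline.R`.

## Worked example

```r
library(flockescape)

sim <- simulate_dataset(seed = 7)   # field-campaign-shaped synthetic data
sim
#> synthetic chase dataset: 122 chases, 1212 events (983 escapes), seed 7

tm <- build_transitions(sim$events, sim$chases,
                        species = "starlings", predator_type = "robotfalcon")
permutation_test(tm, n_null = 10000, seed = 3)
#> permutation test of transition counts — starlings x robotfalcon
#> null: 10000 fixed-margin tables; correction: none; alpha = 0.05
#> 4 transition(s) deviate from the null:
#>              from              to observed null_mean null_sd p_two_tailed
#> 1 flash_expansion           split        9     2.186   1.373       0.0002
#> 2      compacting collective_turn       84    69.359   4.867       0.0038
#> 3          attack collective_turn       10    17.215   2.660       0.0138
#> 4 flash_expansion      compacting        0     4.069   1.761       0.0210
#>   adjusted_p direction
#> 1         NA      over
#> 2         NA      over
#> 3         NA     under
#> 4         NA     under
```

The generator plants flash-expansion-after-attack, split-after-flash and
turn-after-compacting enrichments; the test recovers the planted
over-representations (`flash_expansion -> split` observed 9 against a null
mean of 2.2) and flags the compensating under-representations that fixed
margins force elsewhere.

```r
d   <- escape_count_table(sim$events, sim$chases)
fit <- fit_poisson_glmm(d, rate_model_spec(
         interactions = c("species:chasing_intensity",
                          "predator_type:chasing_intensity")))
best <- prune_to_best_model(fit)
estimated_marginal_means(best$fit, "species")
#> estimated marginal means of species (response scale; balanced grid, covariates at means)
#>      level emmean     se
#>    corvids  8.012 0.7683
#>      gulls  1.786 0.2447
#>   lapwings  4.302 0.9081
#>  starlings 11.030 0.9854
```

The marginal means are expected escapes per chase on a balanced reference
grid (covariates at their means); `pairwise_contrasts()` adds Tukey-adjusted
z-ratios for all species pairs.

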