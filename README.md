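# nmphsim

A rate-coded neural-network simulator for studying how *competition
between memories* reshapes their neural representations, under the
nonmonotonic plasticity hypothesis (NMPH).

## The science

When two memories share structure (similar colors, a shared associate,
overlapping scenes), recalling one tends to reactivate the other. The
NMPH proposes that what happens next depends on *how strongly* the
competitor reactivates, following a U-shaped rule on the coactivity of
each connected unit pair:

* **low** coactivity → no change,
* **moderate** coactivity → the connection is *weakened*,
* **high** coactivity → the connection is *strengthened*.

A network equipped with this one rule, k-winners-take-all (kWTA)
inhibition and a late-trial inhibitory oscillation (whose trough lets
competitor units "pop up" moderately) reproduces a family of puzzling
experimental findings:

* **Repulsion with moderate similarity** — color memories assigned
  similar (2/6-overlap) colors drive their neural patterns *apart*
  (differentiation) and bias recalled colors away from each other,
  while identical or dissimilar colors leave patterns unchanged, and
  high overlap (3/6–5/6) pulls them *together* (integration).
* **Asymmetry** — the second-studied pairmate does the moving; the
  first anchors.
* **Abruptness and anticorrelation** — when differentiation happens it
  is rapid and ends with *anticorrelated* patterns, so the distribution
  of final pattern correlations across runs is bimodal.
* **Learning-rate boundary** — a low learning rate abolishes
  differentiation but not integration.
* **Shared associates** — pairing two scenes with the *same* face
  differentiates the scenes' representations; different faces do not.
* **Curriculum effects** — blocked vs. interleaved schedules trade
  places as the differentiating condition as the inhibitory
  oscillation's amplitude changes.

The package implements the full simulator (settling dynamics,
tie-tolerant kWTA, oscillation, running-average coactivity traces,
U-shaped updates), network builders for the three paradigms above,
tidyverse-native analysis tools (within-pair correlation,
center-of-mass color report, run classification, MDS visualization) and
a command-line interface. See the `methods` vignette
(`vignettes/methods.Rmd`) for equations and calibration notes.

## Worked example

Simulate the color-similarity paradigm at the critical 2/6 overlap:

```r
library(nmphsim)

exp <- run_experiment("chanales", condition = 2,
                      n_runs = 4, n_epochs = 8, seed = 42)
exp
#> <nmph_experiment> chanales / condition 2: 4 runs x 8 epochs (lrate 1)

classify_runs(exp)[, c("run", "label", "onset_epoch",
                       "baseline", "final", "asymmetry")]
#> # A tibble: 4 × 6
#>     run label          onset_epoch baseline  final asymmetry
#>   <int> <chr>                <int>    <dbl>  <dbl> <chr>
#> 1     1 differentiated           1    0.242 -0.149 pairmate2
#> 2     2 differentiated           2    0.242 -0.149 pairmate2
#> 3     3 integrated               2    0.242  1.000 pairmate2
#> 4     4 differentiated           8    0.242 -0.175 both
```

Three of four runs differentiate — their pairmates' hidden patterns end
*anticorrelated* (final ≈ −0.15) — and one integrates (final ≈ 1), the
bimodal signature. Condition-level means with Student-t confidence
intervals:

```r
agg <- aggregate_runs(experiment_metrics(exp))
dplyr::filter(agg, metric == "within_pair_correlation", epoch %in% c(0, 8))
#> # A tibble: 2 × 9
#>   study    condition lrate epoch metric                       n  mean  ci_lo ci_hi
#>   <chr>    <chr>     <dbl> <int> <chr>                    <int> <dbl>  <dbl> <dbl>
#> 1 chanales 2             1     0 within_pair_correlation      4 0.242  0.242 0.242
#> 2 chanales 2             1     8 within_pair_correlation      4 0.132 -0.789 1.05
```

`autoplot(exp)` plots the correlation trajectories;
`lrate_sweep()` and `osc_sweep()` scan the learning rate and
oscillation amplitude; `build_chanales()` / `build_favila()` /
`build_schlichting()` expose the networks directly for unit-level work
with `run_trial()`.

## Command-line interface

The `exec/nmph` script drives the same machinery:

```sh
nmph run --study chanales --condition 2 --runs 10 --epochs 8 \
     --seed 7 --out results/
nmph analyze --in results/
nmph sweep lrate --study chanales --condition 2 --values 0.1,0.5,1 \
     --out sweeps/
nmph plot --in results/ --out results/correlation.png
```

`nmph run` writes per-epoch snapshots, per-run metrics, aggregates,
run classifications, the fully resolved configuration (JSON) and a log
with per-run seeds.

## Reproduction

Full-scale acceptance battery (50 runs × 20 epochs per condition, all
three paradigms; ~10–15 min on one CPU), run against the *installed*
package:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

writes the main computed quantities (mean center-of-mass distance
changes and correlation changes per overlap, differentiated fractions,
color errors, onset epochs, the Favila and Schlichting contrasts) as
JSON. The same quantities are asserted, criterion by criterion, in
`tests/testthat/test-acceptance.R`:

```r
Sys.setenv(NOT_CRAN = "true")
testthat::test_dir("tests/testthat")
```

Most criteria pass; the deviations that remain (the group-level 2/6
color repulsion, the anchored pairmate's color drift, the asymmetry
majority, and onset latency) are real model residuals, kept as honest
failing expectations and documented in the vignette's "Calibration"
section.
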