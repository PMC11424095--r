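---
title: "Model methods and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the simulator's equations, the conventions the
implementation commits to beyond the fixed parameter sets in
`study_config()`, and the calibration of those conventions in the
default configurations.

# Architecture

Each network has four rate-coded layers:

* **category** — a small input layer whose middle unit is clamped on for
  every stimulus; it biases the hidden layer toward the stimulus family.
* **item** — one input unit per pairmate; exactly one is clamped on per
  trial and is the only cue that distinguishes the pairmates.
* **hidden** — the representational layer whose within-pair pattern
  correlation is the model's main outcome measure.
* **output** — in the color-similarity study, a 50-unit topographic ring
  read out as a center-of-mass "color"; in the associate/curriculum
  studies, a small face/object layer.

Projections carry a weight matrix in `[0, 1]`, a direction-specific
multiplicative scale (`fwd`, `bwd`), and the five parameters of the
U-shaped learning rule.  Structured prior knowledge (pairmate units,
topographic one-to-one mappings, ring neighborhoods) is pre-wired at
weight 0.99; all remaining weights are drawn uniformly from the
projection's weight range.

# Settling dynamics

A trial is 200 synchronous cycles.  On each cycle, for every layer:

1. **Net input.** For receiver $j$,
   $\eta_j = g \sum_{p} s_p \frac{\sum_i w_{ij} a_i}{n_p} + g\, c\, x_j$
   where the sum runs over incoming projections $p$ with scale $s_p$ and
   sender count $n_p$, $c$ is the layer's clamp gain and $x_j$ the
   clamped external input.  $g$ is a single global gain (`net_gain`, see
   Calibration).
2. **Inhibition.** Tie-tolerant kWTA computes a baseline conductance
   between the $k$-th and $(k{+}1)$-th ranked values of
   $\eta - \theta$ (position set by the kWTA point), admitting up to
   `k_max` units whose drive ties the $k$-th within `target_diff`.
3. **Oscillation.** From cycle 125 the inhibition is multiplied by
   $1 + \mathrm{osc}\,\sin(2\pi (t - 125)/75)$: one raised half-wave,
   then a trough that lets weakly supported "competitor" units pop up.
   The oscillation is applied on training trials only.
4. **Activation.** $a_j \leftarrow a_j + \mathrm{dt}\,(f(\eta_j - \theta
   - g_i) - a_j)$ with the XX1 function
   $f(x) = \gamma [x]_+ / (\gamma [x]_+ + 1)$.

Running averages of each unit's activity are updated every cycle at
super-short, short, and medium time constants; the medium trace
$\mu$ is end-of-trial weighted, so the oscillation trough (cycles
125–200) dominates it.

# Learning

At the end of every training trial, each connected pair $(i, j)$ gets a
coactivity $\kappa_{ij} = \mu_i \mu_j$, and the weight moves by the
U-shaped function of $\kappa$: zero below `dthr`, dipping to
`drev_mag` at `drev`, back to zero at `thrp`, and rising to `dmax_mag`
at $\kappa = 1$; changes are scaled by the learning rate and weights are
clipped to `[0, 1]`.  Low coactivity leaves a connection alone, moderate
coactivity weakens it, high coactivity strengthens it.

This single rule produces all the phenomena the package simulates.
During the first pairmate's trial the trough pops the competitor's
unique units up moderately; their coactivity with the shared units falls
in the dip and those connections are severed, while
competitor–competitor coactivities stay below the dip and survive.  On
the competitor's own next trial, the severed shared units stay silent,
the inhibition budget admits fresh units, and the competitor's
representation relocates — differentiation.  With higher stimulus
overlap the pop-up is strong enough that coactivities land beyond the
dip and connections strengthen instead — integration.

# Conventions the fixed parameters leave open

The fixed parameter sets in `study_config()` determine the layer
geometry (`k`, `k_max`, kWTA point, tie tolerance, oscillation
amplitude, XX1 gain, clamp gains), the projection weight ranges and
scales, and the five U-shape parameters per projection.  They do not
fix:

* the **net-input normalization** — this package averages each
  projection's contribution over its full sender count ($1/n_p$ above);
* the **activation threshold** $\theta$ — the offset subtracted from net
  input both in the kWTA ranking and in the activation function.

Both are calibrated per study in `study_config()` and nowhere else.

# Calibration

The global `net_gain` compensates for the sender-averaged normalization:
with 50-unit layers and ~6 active senders, raw averaged net inputs are
roughly an order of magnitude weaker than the drive the fixed
XX1 gains expect, so `net_gain` is set in the 2–2.5 range per study (a
single directional constant; it scales every projection identically).

The per-layer activation thresholds place three events correctly
relative to the fixed drive scales.  Because the kWTA conductance is
computed from the same $\eta - \theta$ ranking, a uniform threshold
shift cancels at baseline; what $\theta$ controls is the *depth of the
oscillation trough* for that layer (the absolute drop is proportional to
the inhibition it scales), i.e. how hot that layer's competitors pop up.

For the color-similarity study (`study_config("chanales")`):

* **item** $\theta = -0.16$: the competitor item's pop-up reaches
  ~0.3, so its coactivity with the *shared* hidden units lands inside
  the item→hidden dip on the first trial (severed) while its coactivity
  with the competitor's *own* hidden units stays below the dip
  (spared).  Deeper thresholds push the own-item coactivity into the
  dip at overlaps 3–5/6 and destroy the attraction regime; shallower
  ones leave the shared links intact and the pairmates integrate.
* **hidden** $\theta = 0.15$: damps the hidden trough so the
  competitor's hidden pop-up lands inside the hidden–hidden dip
  (competitor–shared severed, competitor–competitor spared) and so the
  established pairmate does not fully re-ignite during the competitor's
  later trials.
* **output** $\theta = 0.09$: low enough for the output ring to
  participate in the pop-up (it seeds the hidden ignition through the
  back-projection), high enough that the established pairmate's color
  units do not drag the network back into its attractor on every
  competitor trial.  Below ~0.05 every run integrates; above ~0.12 the
  pop-up disappears and nothing differentiates.

The associate (`favila`) and curriculum (`schlichting`) studies use the
same logic with their own fixed oscillation amplitudes; only their
item/category thresholds and `net_gain` differ.

## Known residual deviations

With the fixed parameter sets held constant and only the conventions above free, the
calibrated model reproduces the qualitative overlap curve, the
anticorrelated/bimodal end states, the low-learning-rate boundary and
the curriculum-by-oscillation interactions, but four quantitative
details of the target phenomena are not reproduced and are recorded as
failing expectations in the acceptance tests:

* the 2/6-overlap center-of-mass repulsion is not significant at the
  group level (the moved pairmate's color often fails to re-bind to new
  ring units, because a single one-to-one topographic connection cannot
  clear the wide hidden→output dip at the calibrated output threshold);
* the anchored pairmate's color drifts into the vacated region instead
  of staying put;
* in about half of the differentiated runs the anchored pairmate's
  hidden pattern relocates after a transient retrieval failure, diluting
  the "pairmate 2 moves" asymmetry;
* differentiation onset is most often epoch 2–4 rather than epoch 1.

# Reproducing the shipped results

```{r}
library(nmphsim)
exp <- run_experiment("chanales", overlap = 2, n_runs = 50,
                      n_epochs = 20, seed = 1)
classify_runs(exp)
```

The full acceptance battery is `scripts/acceptance.R`:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
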