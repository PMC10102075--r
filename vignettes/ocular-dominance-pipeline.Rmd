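---
title: "Quantifying ocular dominance from eye-specific spike recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ocular dominance from eye-specific spike recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odpipe)
```

## The analysis problem

During the critical period, closing one eye (monocular deprivation, MD)
shifts the eye preference of neurons in mouse binocular primary visual
cortex (bV1) toward the open eye; different recovery regimens — binocular
recovery (BR), reverse occlusion (RO), BR followed by undisturbed sleep or
by sleep deprivation — reverse that shift to different degrees. The
standard way to quantify the shift from extracellular recordings is:

1. present phase-reversing gratings (8 orientations plus a blank screen)
   to each eye in a randomly interleaved schedule, 8 presentations of 10 s
   per stimulus (80 s of exposure per eye and stimulus);
2. for each sorted unit, compute per-stimulus mean firing rates, the
   per-eye maximal evoked rate at the preferred orientation (C for the
   contralateral eye, I for the ipsilateral eye), the mean evoked rate
   across orientations, and the spontaneous (blank-screen) rate;
3. drop non-visually-responsive units (spontaneous rate above maximal
   evoked rate) and duplicate units detected on adjacent electrodes;
4. compute the ocular dominance index `ODI = (C - I) / (C + I)`, bin it
   onto the 7-point ocular dominance scale, and summarize each animal by
   its contralateral bias index
   `CBI = [(n1 - n7) + 2/3 (n2 - n6) + 1/3 (n3 - n5) + N] / 2N`;
5. compare groups with the usual suite: Kolmogorov–Smirnov on ODI
   cumulative distributions, one-way ANOVA with Tukey HSD on per-animal
   CBI, Kruskal–Wallis with Dunn post hoc or Mann–Whitney on firing rates,
   unpaired t-tests for two-group contrasts.

In parallel, visually driven activity is quantified anatomically: cFos+
and parvalbumin (PV)+ cell bodies are counted per cortical layer in bV1
sections (with primary auditory cortex, A1, as an activity-invariant
control region) and reported as densities averaged over 3–4 sections per
animal.

Raw recordings for such studies are typically not deposited, so the
package pairs the analysis with a seedable synthetic-data generator that
emulates the six experimental conditions. Every stage of the pipeline is
exercised and tested against that generator; the generator itself is
first-class, tested code.

## The generative model

`build_schedule()` produces the presentation clock: contiguous,
non-overlapping epochs under the half-open convention `[start_s, end_s)`,
each (eye, stimulus) pair appearing exactly `n_reps` times in a seeded
random interleaving.

`build_population()` draws units hierarchically: animals of equal size,
cell type Bernoulli(fs_fraction), cortical layer, shank and electrode
index, a waveform half-width from a type-specific truncated normal, and a
preferred orientation uniform over the stimulus set.
`simulate_spikes()` then makes each unit a piecewise-homogeneous Poisson
process: within an epoch showing orientation $\theta$ to eye $e$, the rate
is

$$r = b + g_e \exp\{\kappa[\cos(2(\theta - \theta_\mathrm{pref})\cdot\pi/180) - 1]\},$$

i.e. baseline plus an eye-specific peak gain scaled by a von Mises bump on
the doubled orientation angle (period 180°), normalized to 1 at the
preferred orientation so that `g_e` is exactly the peak evoked gain. Blank
epochs evoke the baseline alone. Spike counts per epoch are Poisson and
independent; times are uniform within the epoch. No refractory period or
adaptation is modeled — the pipeline consumes only rate statistics, for
which the per-epoch counts are sufficient.

### Default parameters and why

| Parameter | Default | Rationale |
|---|---|---|
| epoch duration × reps | 10 s × 8 | the standard 80 s per stimulus design |
| orientations | 8 (0–157.5° in 22.5° steps) | standard grating battery |
| RS baseline / NR peak gains | 1 Hz; contra 8, ipsi 4 Hz | ~2:1 contralateral bias of normal mouse bV1 |
| MD multipliers | contra ×0.5, ipsi ×1.8 | deprived-eye depression plus spared-eye potentiation |
| RO multipliers | contra ×0.8, ipsi ×1.4 | partial recovery, intermediate between NR and MD |
| BR / BR+Sleep | NR gains | complete recovery |
| BR+SD | MD-like gains | sleep deprivation blocks recovery |
| FS gains and baseline | 3× RS | fast-spiking interneurons fire several-fold faster |
| fs_fraction | 0.18 | FS units are roughly 15–20% of stable recordings |
| tuning κ | 2 | moderate orientation selectivity; tuning width is rarely reported, so this is an acknowledged stand-in |
| half-widths | FS ~ N(0.22, 0.03) ms, RS ~ N(0.50, 0.07) ms, truncated at 0 | produces the bimodal half-width/rate clusters used for subclass discrimination |
| n_animals × units | 5 × 48 | five mice per group with ~200+ responsive units per group, the scale of such cohorts |

The gain magnitudes are generative stand-ins: absolute firing rates,
tuning widths and effect sizes are not printed in enough detail to copy,
so the defaults were chosen once to reproduce the *direction and ordering*
of the condition effects (NR ≈ BR ≈ BR+Sleep > RO > MD ≈ BR+SD in
contralateral bias) and are exposed in `condition_config()` rather than
hidden.

Cell maps are homogeneous Poisson point processes per layer with the
depth bands (µm below the pia) L2/3 100–300, L4 300–400, L5/6 400–700 and
a 1 mm-wide counted field, three sections per animal. PV+ cells are drawn
at a condition-invariant intensity; each PV cell is cFos+ with a
co-activation probability; cFos+/PV− cells are drawn at the residual
intensity so the marginal cFos density matches the configured table. The
layer-2/3 cFos intensity in bV1 carries the condition effect; A1 is
identical across conditions by construction, which is what makes it a
control.

### What the generator does not emulate

Phase-reversal dynamics within an epoch (the 1 Hz reversal is not
modeled), spike waveforms and spike sorting, refractoriness, bursting,
adaptation, inter-unit correlations, behavioral state, and any spatial
structure in the cell maps beyond layer membership. Passing tests
therefore demonstrate that the *analysis operations* are correct and that
parameters of this generative family are recovered — not that the
pipeline is robust to sorting artifacts or non-Poisson firing in real
recordings.

## Numerical and design choices

- **Half-open epochs.** A spike at exactly `end_s` belongs to the next
  epoch or to none. This makes the epoch partition exact: no spike is
  counted twice.
- **Spontaneous rate** is pooled across both eyes' blank presentations. A
  blank screen carries no eye-specific content, and pooling halves the
  estimator's variance. (Whether the original analyses pooled or kept
  per-eye blanks is not stated; this is our documented choice.)
- **Preferred orientation** is the argmax of the 8 orientation rates,
  per eye, with ties broken toward the lowest orientation — deterministic
  and order-independent.
- **Responsiveness** excludes a unit only when spontaneous rate is
  *strictly* greater than the best evoked rate over both eyes; a tie is
  retained. Units with zero evoked response in both eyes are excluded
  separately ("zero evoked") because their ODI is undefined.
- **Duplicate removal.** Units on the same shank within one electrode of
  each other whose spike trains match one-to-one within 0.1 ms (the scale
  of sampling-clock jitter) are treated as one neuron; the lowest
  electrode index survives, ties broken by unit id, and transitive chains
  collapse to a single survivor.
- **7-point scale bin edges.** The printed scale does not say which class
  owns a boundary value such as ODI = 0.15. We use left-closed/right-open
  intervals ascending in ODI with the top interval `[0.75, 1]` closed:
  the seven classes then partition `[-1, 1]` exactly and boundary behavior
  is deterministic. ODI is always computed from per-eye *maximal*
  (preferred-orientation) rates, never mean rates.
- **RS/FS classification.** The conventional expert cut through the
  half-width/rate scatter is formalized as two-cluster k-means on
  standardized half-width and standardized `log(1 + rate)` (the log tames
  the right skew of rates), with a fixed-seed 25-start initialization so
  the partition is reproducible. FS is the narrow-waveform cluster; if
  that cluster does not also have the higher mean rate the labels stand
  but a consistency warning is raised, since real populations can violate
  the secondary criterion. Cluster separation is verified by one-way
  MANOVA (Wilks' Λ with its F approximation), applied to the feature
  matrix directly, or to its first three principal components when a
  wider waveform-feature matrix is supplied. No fixed half-width threshold
  is imposed.
- **Statistical suite.** The t-test is the classical pooled-variance
  unpaired test (df = n₁ + n₂ − 2). Dunn's post hoc z-tests use the
  tie-corrected rank variance and Bonferroni adjustment — the most common
  Dunn convention — switchable via `p_adjust`. Mann–Whitney uses the
  normal approximation with tie and continuity corrections. The
  Kolmogorov–Smirnov p-value is asymptotic. Omnibus ANOVA on groups that
  are all constant is refused (zero within-group variance) rather than
  reported as an infinite F; a zero-pooled-variance t-test with equal
  means returns p = 1 with a note.
- **Densities** are counts over counted area on 2-D projected point
  patterns — no stereology — and per-animal values are arithmetic means of
  section densities, which equals pooled-count/pooled-area only when all
  section areas are equal (the tests document the difference).

## Worked example

```{r pipeline}
cfg <- condition_config("MD", n_animals = 3, n_units_per_animal = 30,
                        seed = 42)
ds <- simulate_experiment(cfg)
res <- analyze_od_experiment(ds)
res$filter$summary
res$animals
```

Group comparison of ODI distributions against a normally-reared cohort:

```{r stats}
nr <- analyze_od_experiment(
  simulate_experiment(condition_config("NR", n_animals = 3,
                                       n_units_per_animal = 30, seed = 43))
)
ks_two_sample(nr$records$odi, res$records$odi)
anova_tukey(list(NR = nr$animals$cbi, MD = res$animals$cbi))
```

Cell-type classification and cFos densities:

```{r celltypes}
feats <- class_features(ds$units, res$rates)
classify_units(feats)

maps <- simulate_cellmaps(cfg)
d <- animal_average(layer_density(maps$cells, maps$areas))
head(d)
```

## Verification strategy and problem sizes

The test suite checks every formula-level identity directly (ODI bounds
and antisymmetry, the 7-class partition of `[-1, 1]`, CBI against an
independently coded evaluation of the same published expression on 1000
random count vectors, the 84.4% = 222/263 responsive-fraction
arithmetic), and checks every stochastic stage against an independent
oracle: binomial bounds for cell-type draws, Poisson moments for epoch
counts and rate estimates (8 × 10 s design, 1000 units), brute-force
pairwise counts for Mann–Whitney U, a grid evaluation of
$\sup|F_a - F_b|$ for K-S, a hand-coded rank-sum formula for
Kruskal–Wallis, and null simulations (1000 replicates per test) whose
type-I error must stay within 3.5–6.5% at α = 0.05. Parameter recovery is
checked end to end: 50 replicate six-condition experiments at the default
cohort size must reproduce the CBI ordering
NR ≈ BR ≈ BR+Sleep > RO > MD ≈ BR+SD, duplicate injection must be removed
with full recall and no false removals against 1 ms-jittered decoys, RS/FS
recovery must reach 95% on 1000 units, and the A1 control's omnibus
rejection rate must stay near its nominal α across 150 replicate map
sets. These sizes were chosen so the whole suite runs in a few minutes on
one core while keeping Monte-Carlo error well inside the asserted bands.

## Limitations

- The generator's effect sizes are stand-ins; quantitative agreement with
  any particular recorded cohort is out of scope, and only orderings and
  formula-level constants are asserted.
- The pipeline starts at sorted spike times; spike sorting, waveform
  template matching and burst metrics are out of scope.
- Only two cell classes are modeled (no SST/VIP typing).
- Co-labeling is point coincidence on synthetic maps; pixel-level
  colocalization coefficients are not computed.
- The K-S p-value is asymptotic and mildly conservative at small n; for
  n ≥ ~100 per group (the regime used here) its size is within the
  calibrated band.
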