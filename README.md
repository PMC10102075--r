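# odpipe

Quantification of ocular dominance in mouse binocular visual cortex (bV1)
from extracellular spike recordings under eye-specific grating
stimulation, written for visual-neurophysiology labs analyzing
monocular-deprivation (MD) and recovery experiments — and for anyone who
needs a tested, seedable reference implementation of the classical
ocular-dominance metrics.

## What it computes

Each unit's per-stimulus firing rate is the spike count over the pooled
80 s of presentation (8 × 10 s epochs, half-open `[start, end)`). From
the per-eye maximal evoked rates C (contralateral) and I (ipsilateral)
at each eye's preferred orientation:

- **Ocular dominance index**: `ODI = (C − I) / (C + I)` ∈ [−1, +1];
  +1 means driven exclusively by the contralateral eye.
- **7-point OD scale**: ODI binned as [0.75, 1] → class 1, [0.45, 0.75) →
  2, [0.15, 0.45) → 3, [−0.15, 0.15) → 4 (binocular), [−0.45, −0.15) → 5,
  [−0.75, −0.45) → 6, [−1, −0.75) → 7.
- **Contralateral bias index** per animal:
  `CBI = [(n1 − n7) + 2/3(n2 − n6) + 1/3(n3 − n5) + N] / 2N` ∈ [0, 1],
  where `nx` is the number of neurons in OD class x and `N = Σ nx`.

Around those metrics the package provides the full analysis pipeline:
epoch rate tables, response summaries, the visual-responsiveness filter
(spontaneous > maximal evoked ⇒ excluded), adjacent-electrode duplicate
removal, regular-spiking vs fast-spiking classification from waveform
half-width and firing rate (with a MANOVA cluster-separation check),
layer-resolved cFos/PV cell-density quantification with an A1 control
region, and the statistical suite the field uses (two-sample
Kolmogorov–Smirnov, one-way ANOVA + Tukey HSD, Kruskal–Wallis + Dunn,
Mann–Whitney, unpaired t-tests). A synthetic-data generator emulates the
six experimental conditions (NR, MD, BR, RO, BR+Sleep, BR+SD) so every
stage is testable without raw recordings.

## Worked example

```r
library(odpipe)

cfg <- condition_config("MD", n_animals = 3, n_units_per_animal = 30,
                        seed = 42)
ds  <- simulate_experiment(cfg)    # schedule, spikes, units, cell maps
res <- analyze_od_experiment(ds)   # dedup -> rates -> filter -> ODI -> CBI

res$animals
#> # A tibble: 3 × 11
#>   animal_id condition    n1    n2    n3    n4    n5    n6    n7     N   cbi
#>   <chr>     <chr>     <int> <int> <int> <int> <int> <int> <int> <int> <dbl>
#> 1 MD_a01    MD            0     0     0     1    29     0     0    30 0.339
#> 2 MD_a02    MD            0     0     0     0    30     0     0    30 0.333
#> 3 MD_a03    MD            0     0     0     0    30     0     0    30 0.333
```

After MD the simulated units sit in OD class 5 (ipsilateral-biased) and
the per-animal CBI is ≈ 0.33 — the spared-eye shift. A normally-reared
cohort recovers CBI ≈ 0.67 (contralateral bias), and the group tests
separate the two:

```r
nr <- analyze_od_experiment(simulate_experiment(
  condition_config("NR", n_animals = 3, n_units_per_animal = 30,
                   seed = 43)))

ks_two_sample(nr$records$odi, res$records$odi)
#> <ks_two_sample>
#>   D = 1
#>   p = 0

anova_tukey(list(NR = nr$animals$cbi, MD = res$animals$cbi))
#> <anova_tukey>
#>   F = 3.204e+04
#>   df = 1, 4
#>   p = 5.843e-09
```

Cell-type classification on the same recording:

```r
classify_units(class_features(ds$units, res$rates))
#> <RS/FS classification>
#> # A tibble: 2 × 4
#>   label half_width_ms overall_rate_hz     n
#>   <chr>         <dbl>           <dbl> <int>
#> 1 FS            0.236            4.55    14
#> 2 RS            0.495            2.54    76
#>   separation: Wilks lambda = 0.003594, p = 4.64e-107
```

The FS cluster is narrow-waveform and fast-firing, ~16% of units, and the
two clusters are strongly separated — the standard verification before
analyzing the populations separately.

`run_experiment(cfg, dir)` writes the dataset as CSVs
(`schedule.csv`, `spikes.csv`, `units.csv`, `cellmaps.csv`,
`cellmap_areas.csv`) plus a YAML manifest, and `read_experiment(dir)`
reads them back; reruns with the same config are byte-identical.

See `vignettes/ocular-dominance-pipeline.Rmd` for the generative model,
parameter defaults, and every numerical convention (bin edges, tie
breaks, duplicate tolerance, degenerate-input handling).

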