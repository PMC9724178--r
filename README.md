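# ktrdyn

Single-cell analysis of nuclear p53 levels and MAPK kinase activity from
multi-channel time-lapse movies.

Different stresses can drive nearly identical p53 dynamics yet opposite
cell fates; telling dying from surviving cells requires following p53
together with parallel kinase signalling in the same cells. Kinase
translocation reporters (KTRs) make kinase activity imageable: the
reporter leaves the nucleus when phosphorylated, so the
cytoplasmic-to-nuclear intensity ratio

```
C/N(t) = mean KTR over cytoplasmic ring / mean KTR over nucleus
```

is a per-frame, per-cell activity readout. `ktrdyn` implements the full
chain from movie to statistics, for movies acquired every 8 min over
24 h with an H2B nuclear marker, a KTR channel, and tagged p53:

1. **Segmentation** of nuclei from H2B (Gaussian pre-smooth, Otsu
   threshold with a 0.5 correction factor, hole fill, watershed split,
   min-area filter).
2. **Tracking** by the overlap method with a 50-px maximum match
   distance; greedy, deterministic, no gap closing.
3. **Death flagging**: first frame with nuclear area *and* H2B mean both
   below 50% of the track median, sustained to track end (cells round up
   and lose fluorescence at death).
4. **Quantification**: nuclear p53 mean; C/N ratio over a cytoplasmic
   ring made by growing the nuclear mask 5 px and subtracting nuclei
   (contested pixels to the nearer centroid); three-window moving-mean
   smoothing.
5. **Pulse features**: local maxima with topographic prominence above
   `theta = 0.5 * (median peak - median basal)` calibrated per cohort;
   pulse count, amplitude, timing, full-width-at-half-prominence
   duration, max C/N and its timing, trapezoidal integrated level.
6. **Fate statistics**: dying vs surviving comparison of second-pulse
   timing (two-tailed Welch t-test), one-way ANOVA for condition
   comparisons, z-score standardisation, per-frame mean ± SD summaries.

A synthetic-data module (`simulateCohort()`, `renderMovie()`) generates
ground-truthed traces and movies with the same statistical structure —
pulsatile/sustained/oscillatory/rising dynamics, reporter translocation
with conserved total, random-walk motion, death events — so every stage
is testable without any external data.

## Worked example

Simulate the default two-fate cohort at reduced size, run the whole
pipeline, and compare second-pulse timing between fates:

```r
library(ktrdyn)

cfg <- runConfig(nDying = 6, nSurviving = 6, seed = 11)
res <- runPipeline(cfg)

res$threshold
#> ProminenceThreshold [cohort]: theta = 0.2119 (median basal 0.5889,
#>   median peak 1.013, n = 12)

res$stats
#>            feature                    test statistic       pValue meanDying
#> 1 secondPulseTimeH Welch t-test (2-tailed) -5.875781 0.0001865804  5.977778
#>   meanSurviving nDying nSurviving
#> 1      9.355556      6          6

res$trackingAccuracy
#> [1] 1
```

Reading the output: the cohort-calibrated minimum pulse prominence is
0.21 C/N units (half the span between the cohort's median pre-treatment
C/N and median peak C/N). Dying cells re-activated their kinase at
5.98 h on average versus 9.36 h in surviving cells — the generating
means are 6 h and 10 h — and the two-tailed Welch t-test rejects equal
timing at p = 1.9e-4. Every tracked frame was assigned to the correct
ground-truth cell. With `outDir=` the run also writes `traces.csv`,
`features.csv`, `pulses.csv`, `stats.csv`, `population_summary.csv`, a
wide trace matrix, and a `manifest.json` holding the seed and full
configuration, from which the run is reproducible.

A command-line front end with `simulate` and `run` subcommands is in
`inst/scripts/ktrdyn.R`:

```sh
Rscript inst/scripts/ktrdyn.R run --seed 1 --out runs/demo
```

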