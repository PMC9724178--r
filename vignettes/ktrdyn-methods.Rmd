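---
title: "Quantifying p53 and MAPK reporter dynamics in single cells"
author: "ktrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying p53 and MAPK reporter dynamics in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktrdyn)
```

## The measurement problem

Cells mount different fate programs — death, cycle arrest, survival —
under stresses that can produce nearly identical p53 expression dynamics.
Resolving what distinguishes the fates requires following *both* p53 and
parallel kinase signalling in the same cell over time. Two reporters make
that possible in live-cell imaging:

* **Nuclear p53 level**: a fluorescently tagged p53 measured as the mean
  intensity over the nucleus, delineated by a constitutive H2B marker.
* **MAPK activity** (ERK, JNK, or p38): a kinase translocation reporter
  (KTR) that is exported from the nucleus when phosphorylated by its
  target kinase. Activity is read out ratiometrically as the
  **C/N ratio** — mean cytoplasmic over mean nuclear reporter intensity.

`ktrdyn` implements the full analysis chain for such movies: nuclear
segmentation, overlap tracking, ring-based C/N quantification, pulse
detection with a cohort-calibrated prominence threshold, and statistical
comparison of dynamic features between dying and surviving cells. Because
raw experimental movies are large and not generally redistributable, the
package includes a first-class synthetic data generator with exact ground
truth, so that every stage — and the pipeline end to end — is verifiable.

## Measurement model

### Acquisition geometry

Frames are acquired every 8 minutes for 24 hours (181 frames). Frame 1 is
the untreated baseline; the stimulus is added between frames 1 and 2, so
frame $k$ corresponds to $t = (k-1)\,\Delta t$ hours post-treatment. Each
condition aims for at least 40 analysed cells.

### Segmentation and tracking

Nuclei are segmented per frame from the H2B channel with a standard
recipe: Gaussian pre-smooth ($\sigma = 1$ px), global Otsu threshold,
hole filling, optional distance-transform watershed for touching nuclei,
and removal of regions under 80 px. Two deliberate choices:

* **Threshold correction 0.5.** On a dark background with bright nuclei,
  Otsu's threshold lands near half the nuclear intensity. A nucleus that
  has dimmed below 50% — precisely the morphology of a cell rounding up
  at death — would vanish from the mask before the death event could be
  placed. Halving the threshold keeps such nuclei for the collapse frame
  while remaining far above background noise.
* **Border regions** are kept but flagged; ring quantification simply
  clips at the image edge.

Linking between consecutive frames uses the overlap rule with a distance
cap: candidate pairs share at least one pixel **or** lie within 50 px
centroid-to-centroid; assignment is greedy by descending overlap, ties
broken by ascending centroid distance and then by label order, each label
matched at most once. Both candidate routes are admitted because a
fast-moving nucleus can lose pixel overlap while remaining unambiguous
within the cap. There is no gap closing: a track whose label finds no
match is closed as lost, and a division split opens a new track for the
second daughter.

### Death flagging

Dying cells round up and lose fluorescence. The automated flag places the
death at the first frame where nuclear area *and* H2B mean both fall
below 50% of the track's median, sustained through the end of the track;
a transient dip that recovers is not a death. The 50%/50% thresholds are
configurable and were chosen to match the rendered death phenotype.

### C/N quantification

Each nuclear mask is grown by 5 px (Euclidean disk structuring element)
and the nuclei subtracted, producing a perinuclear cytoplasmic ring. A
pixel contested by two rings is assigned to the nearer nucleus centroid,
so no pixel is counted twice; pixels inside any nucleus are never ring
pixels. The C/N ratio is the mean KTR intensity over the ring divided by
the mean over the nucleus; an empty ring or non-positive nuclear mean
marks the frame invalid rather than erroring. Nuclear p53 is the plain
mean over the nucleus. No background subtraction, flat-field, or
bleaching correction is applied.

Traces are smoothed with a centred three-window moving mean
($n-1, n, n+1$); at trace boundaries the window shrinks to the available
frames, and invalid frames are excluded from windows and stay invalid.
Downstream features are computed on the smoothed series, keeping one
canonical trace for both plots and features; the raw series is always
retained alongside (both are emitted, since reasonable analyses could use
either).

### Pulse detection

Activity pulses are local maxima whose **topographic prominence** — the
peak value minus the higher of the two minimal valleys separating it from
higher terrain or the trace ends — reaches a cohort-calibrated threshold

$$\theta \;=\; \tfrac12\,(\mathrm{median\ peak} - \mathrm{median\ basal}),$$

where *basal* is each cell's frame-1 (pre-treatment) value and *peak* is
each cell's trace maximum, medians taken across all cells of the
condition and $\theta$ floored at zero. Reading "peak expression of all
cells" as the *median of per-cell maxima* is one of two defensible
interpretations; the alternative (the single global maximum) is available
via `peakSummary = "global_max"`. Detection is invariant to adding a
constant to the whole cohort, since $\theta$ shifts identically.

Boundary conventions: endpoints are never peaks, so a monotone rise
terminating at the final frame is *not* counted as a pulse (rising
dynamics are treated as non-pulsatile); a plateau of equal values is one
peak at its middle frame. Pulse duration is the full width at half
prominence, linearly interpolated between frames — for an isolated
Gaussian pulse this equals its FWHM. Per-cell features are the pulse
count over the acquisition, maximum value and its timing, the basal
value, and the trapezoidal integral of the smoothed trace over valid
frames (value·hours); sustained single-peak kinases such as p38 run
through the same detector, with max and time-of-max as the reported
summary.

### Fate statistics

Cells are stratified by presence of a death annotation. The timing of the
second detected pulse (cells with ≥ 2 pulses) is compared between dying
and surviving cells with a two-tailed Welch t-test (pooled variance
optional); condition-level feature comparisons use one-way fixed-effects
ANOVA. Population summaries report the per-frame mean and sample
($n-1$) SD over valid cells. Z-score standardisation uses the sample SD.
No multiple-testing correction is applied by default. Degenerate inputs
are handled explicitly: identical data across groups give $F = 0$,
$p = 1$; zero-variance t-tests report the mean difference with an
undefined statistic; groups with fewer than two qualifying cells skip the
comparison with a warning.

## The synthetic data generator

The generator emulates the statistical structure the analysis assumes,
not the optics of a particular microscope.

**Traces.** A trace is baseline + Gaussian pulses (parameterised by peak
time, amplitude, FWHM) + linear ramp, with multiplicative lognormal noise
(expression variability) and additive Gaussian noise (measurement) applied
afterwards. Model kinds cover the observed phenomenology: pulsatile
(JNK/ERK-like, 1–3 pulses), sustained single peak (p38-like), oscillatory
(low-dose p53; the oscillation period is a free parameter, default 5.5 h,
as no period is prescribed for this cell system), rising (high-dose p53),
and flat. An elevated-baseline option reproduces ERK's largely
cytoplasmic reporter under growth-factor signalling.

**Reporter geometry.** Kinase activity $a \ge 0$ maps to a cytoplasmic
reporter fraction $f(a) = a/(1+a)$ — a saturating monotone map consistent
with bounded nucleocytoplasmic shuttling; total reporter is conserved.
Cells are rendered as a nuclear disk plus cytoplasmic annulus, each
compartment's amount spread uniformly over its pixels, so the true C/N
ratio is analytic: $a \cdot A_\mathrm{nuc}/A_\mathrm{cyto}$ with the
compartment pixel areas. Channels: H2B (uniform nuclear disk), KTR
(nucleus + annulus), p53 (nuclear disk at the p53 trace value).

**Motion.** Nuclei random-walk with a per-frame step SD, reflected inside
a home box around the start position — adherent epithelial cells wander
locally rather than diffusing across the field. This also guarantees the
non-overlap the grid layout establishes.

**Death.** At the death frame the nucleus shrinks to 0.65× radius at 0.4×
intensity (visibly rounded up and dimmed, still detectable for exactly
one frame so the death can be placed); from the next frame radius is
0.45× and intensities 5% — within two frames the radius has shrunk by
more than half and fluorescence dropped below 10% of pre-death. Death
always falls strictly after the cell's last generated pulse.

**Two-fate scenario.** The default cohort emulates lethal oxidative
stress: every cell pulses once shortly after treatment
(~N(0.6 h, 0.1 h)); dying cells re-activate early
(second pulse ~N(6 h, 1.5 h)) and die 1.5–3 h after it, while surviving
cells re-activate late (~N(10 h, 1.5 h)); nuclear p53 rises monotonically
in all cells. 40 cells per fate group, 8-min frames over 24 h, laid out
across as many 256×256 fields as needed (36 cells/field at the default
spacing). All scenario parameters are recorded in the cohort object and
the run manifest.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: photobleaching, uneven illumination, 3-D
optics and defocus, segmentation-defeating nuclear shapes, cell division,
migration beyond the home box, and contact between touching cells beyond
tangent disks. Results on real movies additionally depend on segmentation
quality in ways the phantom cannot probe.

## Numerical choices and edge cases

* Smoothing uses shrinking windows at the boundaries — no padding or
  extrapolation.
* Integration uses the trapezoidal rule on the smoothed series over valid
  frames; cells dying early integrate over their valid window and are
  identifiable by their `nValidFrames`.
* Prominence scans stop at strictly higher terrain, so equal-height twin
  peaks each measure their prominence across the shared valley.
* An empty or constant frame segments to an empty mask with a warning; an
  empty ring or zero nuclear mean invalidates the frame, not the run.
* Tracks are kept if they span ≥ 75% of the movie or end in a flagged
  death having started within the first 5% of frames.
* All randomness flows through a single seed; reruns with the same
  configuration and seed are byte-identical, and the caller's RNG state
  is never disturbed.

## Problem sizes used in the checks

The packaged checks exercise the full acquisition geometry (181 frames,
256×256 px, 40+40 cells for the end-to-end fate recovery) and scale the
remaining suites to sizes that keep the whole battery fast: 200 simulated
traces for pulse recovery, 1,000 random traces for the prominence-oracle
comparison, a 9-cell/12-h drift benchmark for tracking, and an 8-cell/6-h
cohort for the byte-identity rerun.

## Known limitations

* The C/N measurement inherits a geometry-dependent scale
  ($A_\mathrm{nuc}/A_\mathrm{cyto}$): absolute C/N values are comparable
  within a geometry, and the cohort-relative prominence calibration is
  what makes pulse detection robust to it.
* With the 0.5 threshold correction and 1-px pre-smoothing, masks extend
  ~1 px beyond the true nucleus under noise; this biases C/N slightly
  upward but consistently, and cancels in the calibrated detection. On
  noiseless images with pre-smoothing disabled, masks are pixel-exact.
* The death flag needs the collapse to be sustained; a cell dying in the
  last two frames of a movie is flagged only if its collapse frames are
  segmentable.
* Greedy overlap linking is not globally optimal; for the motion regime
  of adherent cells it agrees with exhaustive assignment (tested), but
  dense fast-moving cultures would need a global matcher.
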