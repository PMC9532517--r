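---
title: "Methods: threshold-mask synapse quantification and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-mask synapse quantification and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neuroquant)
```

## The quantification model

Structural synapses in cultured neurons are scored by marker apposition: a
post-synaptic marker (e.g. PSD95) and a pre-synaptic marker (e.g.
Synapsin I) imaged in separate channels, overlaid on a cell-fill channel
that delineates the dendrite of the neuron under study. neuroquant
implements this as a mask pipeline:

1. **Projection.** Z-stacks are collapsed by per-pixel maximum intensity
   (`max_project()`); all masks are computed on the projected image.
2. **Adaptive threshold.** For each channel the binary mask is
   `I > mean(I) + k * SD(I)`, both moments over all pixels of that image;
   `k = 2` for marker channels and `k = 1` for the cell-fill channel
   (`threshold_spec()` defaults). The threshold adapts per image, which
   makes the mask — and everything downstream — invariant under positive
   affine intensity maps, so acquisition gain and offset do not matter as
   long as no pixel saturates. We use the population SD and a strict
   inequality; both are configurable (`sd_kind`) and recorded in the
   result, since either convention is defensible and they differ only at
   machine precision on real images.
3. **Colocalization.** Triple colocalization is the literal pixelwise
   conjunction of the three masks; any shared pixel colocalizes (no minimum
   overlap fraction). A dual mode conjoins the two marker masks only, for
   marker/marker assays.
4. **Objects and the size rule.** Connected components (8-connectivity,
   standard for puncta; configurable) of the conjunction are puncta; a
   component is retained only if its size is strictly below 10 μm. "Size"
   we interpret as area-equivalent diameter (`2 * sqrt(area / pi)`), with a
   max-Feret option, since the assay's size measure is not standardized.
   `min_area_px` (default 1, i.e. no lower bound) is exposed for noise
   suppression.
5. **Density.** `count / dendrite length` in μm, the length taken from the
   trace — the trace contributes only the denominator, never a mask.

## Tracing and Sholl

Interactive tracing tools are replaced by a skeleton-based stand-in: the
largest connected component of the cell-fill mask is thinned (Zhang–Suen,
followed by a sequential simple-point pass with the Yokoi connectivity
number, which removes the 2-pixel staircase residue Zhang–Suen is known to
leave), branches are extracted as polylines from the skeleton's pixel
graph, diagonal steps count √2 pixels, terminal spurs shorter than 2 μm and
junction fragments shorter than 3 pixels are pruned, and the soma is the
center of the maximal disk inscribed in the mask (distance-transform
maximum). On synthetic tubes this measures length within ~2% of ground
truth; its only downstream uses are the density denominator and Sholl, both
robust to that error. SWC import/export is provided for external traces.

Sholl profiles count exact segment–circle crossing events on rings of 10 μm
spacing around the soma: a polyline segment whose endpoint distances to the
soma straddle a radius contributes one crossing; a vertex exactly on the
ring counts once. Exact crossing counting was chosen over ring-mask pixel
counting to avoid resolution artifacts, and is validated against a
dense-sampling oracle (0.01 μm steps) in the test suite. Group comparison
pools per-ring counts and applies the two-sample K–S test (asymptotic
p-value), alongside per-radius means ± SEM for plotting.

## Spine morphometry stand-in

The reference spine tools are closed-source with unpublished thresholds, so
results on real data are comparative, not bit-matching. The stand-in works
in 2D projection: the shaft is the trace dilated to the local shaft radius
(distance transform along the trace); protrusions are components of mask
minus shaft that touch the shaft. Each protrusion gets an axis along the
outward normal at its base (a base-to-tip axis tilts toward corner pixels
and corrupts widths), a length along that axis, a width profile in 1-pixel
bins smoothed with a 3-bin running mean (single-bin extrema carry ±1 pixel
quantization, intolerable against a 1.1 head/neck ratio rule), a head width
(maximum over the distal half), and a neck width (minimum between 20% of
the axis and the head position — the basal 20% is excluded because the
shaft-dilation bite narrows those bins and would fake a neck on stubby
spines). Protrusions longer than 5 μm are discarded as non-spines.

Classification defaults follow the common geometric heuristic: length
> 3 μm → filopodium; head/neck > 1.1 and head > 0.35 μm → mushroom;
length/head > 2.5 → thin; else stubby. Every constant lives in
`spine_rules()` and is recorded; manual reclassification is supported
through an `override` column. Filopodia are reported but excluded from
total spine density by default.

## Behavior scoring

Exploration is proximity-only: a sample explores an object when the nose is
strictly closer than 2 cm to the object *boundary* (center distance minus
object radius — the boundary convention matches ethological practice;
configurable), ties go to the nearer object, and the readout is the
percentage of exploring time per object. Body orientation is not used —
a documented limitation, since some video-scoring pipelines gate on
head direction. Session comparisons build the session × object cell table
and use one-way ANOVA with Fisher's LSD on the pooled residual variance.

## Statistics

- `welch_t()`: unequal-variance t with Welch–Satterthwaite df, two-tailed.
  Zero-variance input is flagged rather than an error (t = 0, p = 1 for
  identical groups).
- `anova_dunnett_t3()`: one-way ANOVA F, then comparisons against the
  control by Welch-type t with per-pair Welch df; adjusted p-values from
  the studentized maximum modulus distribution, whose CDF is evaluated by
  numerical integration over the chi scale variable (`integrate`,
  rel.tol 1e-9). The adjusted p is floored at the unadjusted p. Monte-Carlo
  validation (10,000-rep null, familywise error ≤ 0.06 at nominal 0.05) is
  part of the test suite, as is the reduction of the r = 1 case to the
  two-sided t probability.
- `anova_tukey()`: ANOVA + Tukey HSD via the studentized range.
- `ks_two_sample()`: exact ECDF max gap, asymptotic p (ties are expected in
  count data; the exact-p refusal warning is suppressed deliberately).
- `normalize_bands()`: per-sample target/loading ratio, fold change over
  the control-group mean (control mean ≡ 1); normalization is per table,
  with a batch column left to the caller.
- `percent_change()`: `100·(mean_b − mean_a)/mean_a` with first-order error
  propagation for its SEM.

Significance is judged at α = 0.05 throughout; p-values are two-tailed.

## What the simulator emulates — and what it does not

`generate_neuron_image()` renders: a random binary tree of straight
segments from a central soma (sufficient geometry for density and Sholl
testing); a cell-fill tube of 0.5 μm radius with a 4 μm soma disk; puncta
as isotropic Gaussian spots (σ = 0.2 μm, peak 4000 over a background of
200) — every true synapse contributes a spot to both marker channels offset
by at most 0.1 μm, and each channel receives 0.3/μm of channel-specific
distractors; Poisson shot noise plus Gaussian read noise (SD 20) after
rendering; 16-bit output at 0.1 μm/pixel, matching a 60× confocal regime
(the acquisition default is 1024 × 1024; tests and the acceptance script
use 512 × 512 fields, i.e. ~51 μm of view and ~200 μm of skeleton, as their
standard problem size). A 3-slice stack mode exercises projection.

Two generator rules make the ground truth exact rather than approximate.
First, rendered puncta keep a minimum center separation (default 1 μm,
five PSF sigmas): puncta are simulated as optically resolvable objects, and
densities requiring closer packing are rejected with a packing-bound error
rather than silently rendering unresolvable blobs. Second, the two
channels' distractors keep that separation from each other, so a
zero-density image contains exactly zero colocalized pairs — chance
coincidence would otherwise make "known-zero truth" false at the rate of
random overlap. Distractor overlap with a true pair is allowed; it merges
into the existing object and cannot change the colocalized count.

The simulator does **not** emulate: depth-dependent PSF or 3D optics,
deconvolution, uneven illumination, autofluorescence structure, spine-
bearing dendrite geometry (the spine module has its own fixture generator
with rectangle-plus-disk protrusions), or biological variability in puncta
brightness. Passing tests therefore demonstrate correctness of the
quantification given resolvable, calibrated input — not robustness to
optical artifacts real images may carry.

The spine fixture draws segment spine counts with a 5% CV around their
planned mean — a deliberate, realistic within-culture variability, chosen
once; the behavioral fixture plans dwell times directly, and the band-table
fixture uses lognormal multiplicative noise whose normalized group means
converge to the prescribed values.

## Numerical choices and degenerate inputs

- Coordinates: 0-based pixel grid, origin at the top-left pixel center,
  physical μm = index × pixel size; all geometry downstream of IO is in μm.
- Thresholding a constant image gives an empty mask (SD 0, strict
  inequality), not an all-true one.
- `max_project()` on 2D input warns and returns it unchanged; projection is
  idempotent and commutes with monotone intensity maps.
- Component labeling builds the 8-neighbor pixel graph and delegates
  component extraction to igraph; a brute-force flood fill is the test
  oracle, never the implementation.
- Welch t with both variances zero: flagged degenerate (p = 1 or 0 by mean
  equality) instead of erroring; Fisher's LSD with zero residual variance
  likewise.
- Dunnett T3 p-values are clipped to [unadjusted p, 1].
- Image writing quantizes to the declared bit depth; the TIFF round trip is
  bit-exact (verified in tests). Channel roles and calibration travel in a
  JSON sidecar because baseline TIFF tags cannot carry them portably.
- Determinism: every stochastic entry point takes an explicit seed and
  restores the caller's RNG state; rerunning a pipeline configuration
  reproduces output files byte for byte.

## Problem sizes

Default test and acceptance problem sizes were chosen to exercise every
code path at full fidelity while keeping a complete run in minutes on one
CPU: 512 × 512 synthetic fields (10 images per condition for density
recovery), 64 × 64 masks × 100 instances for oracle equivalence, 20 random
trees for Sholl, 15 spine segments per group, and 10,000-replicate null
simulations for test calibration.

## Known limitations

- Tracing is a stand-in: no Rayburst sampling, no 3D, no branch-order
  statistics; junction geometry at the soma is approximate (soma-internal
  skeleton fragments contribute ~1% length).
- Spine geometry is measured in 2D projection with a perpendicular-
  protrusion bias; tilted spines are foreshortened.
- Colocalization is binary mask overlap; intensity-correlation measures
  (Pearson, Manders) are out of scope.
- The K–S p-value is asymptotic; with heavily tied count data it is
  approximate (the D statistic itself is exact).
- Behavior scoring has no orientation gating and no habituation analytics.
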