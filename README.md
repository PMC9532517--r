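# neuroquant

Quantification pipeline for excitatory-synapse imaging studies in cultured
hippocampal neurons. The package reimplements, as tested and reusable R
code, the image-quantification and scoring procedures used to ask whether a
perturbation (e.g. an shRNA knockdown) changes synapse and dendritic-spine
density:

- **Synapse density per μm of dendrite.** Each channel of a multi-channel
  confocal image is binarized at a per-image adaptive threshold — the mean
  pixel intensity of the entire image plus *k* standard deviations (*k* = 2
  for the marker channels, *k* = 1 for the cell-fill channel). Synapses are
  the connected components of the triple mask conjunction
  `puncta_A ∧ puncta_B ∧ cell_fill` (pre-/post-synaptic markers on the
  labeled dendrite) whose area-equivalent diameter is strictly below 10 μm,
  and density is `count / dendrite length`. A dual (two-marker) mode covers
  marker/marker colocalization assays.
- **Dendrite tracing and Sholl analysis.** A skeleton-based stand-in tracer
  (Zhang–Suen thinning plus topological cleanup) measures dendritic length
  and extracts branch polylines; Sholl profiles count exact segment–circle
  crossings on concentric 10 μm rings around the soma, compared between
  groups with the two-sample Kolmogorov–Smirnov test.
- **Spine morphometry (stand-in).** Protrusions along a traced dendrite are
  measured (length, head width, neck width) and classified
  thin/stubby/mushroom/filopodium by a configurable geometric rule set, with
  densities per μm and per class.
- **Spatial object-recognition scoring.** Nose-point trajectories are scored
  with the standard rule — a sample counts as exploration when the nose is
  strictly closer than 2 cm to the object boundary — and summarized as
  percentage of exploring time per object, compared by one-way ANOVA with
  Fisher's LSD.
- **Densitometry and statistics.** Western-blot band tables are normalized
  to a loading control and expressed as fold change over the control group;
  the statistical battery provides Welch's t, one-way ANOVA with Dunnett's
  T3 (studentized maximum modulus, Welch degrees of freedom) or Tukey's HSD,
  and the two-sample K–S test.
- **Synthetic ground truth.** `sim_config()` / `generate_neuron_image()`
  render confocal-like three-channel neuron images (Gaussian-PSF puncta,
  Poisson + Gaussian noise, 16-bit) with known skeleton length and known
  colocalized-puncta density, plus trajectory and band-table generators, so
  every stage of the pipeline is testable end to end without external data.

## Worked example

```r
library(neuroquant)

cfg <- sim_config(image_shape = c(512L, 512L), true_density = 0.25,
                  seed = 42L)
sim <- generate_neuron_image(cfg)
sim$truth$skeleton_length
#> [1] 214.4375

cell_mask <- threshold_mask(sim$image$channels$cell_fill, k = 1)
trace <- trace_dendrites(cell_mask, pixel_size = sim$image$pixel_size)
trace
#> <dendrite_trace> 12 branches, total 216.1 um (traced)

quantify_image(sim$image, trace)
#> <punctaresult> 54 puncta on 216.1 um of dendrite
#>   density: 0.2499 per um  (triple colocalization)
```

The simulator placed `round(0.25 × 214.4) = 54` colocalized puncta pairs on
a 214 μm skeleton; the full assay — adaptive thresholds, triple mask
conjunction, component labeling with the 10 μm size rule, traced-length
denominator — recovers all 54 on a traced length within 1% of truth, i.e. a
density of 0.2499/μm against a ground truth of 0.25/μm.

Group comparisons use the same battery as the assay, e.g.:

```r
rep <- anova_dunnett_t3(list(control = c(0.22, 0.25, 0.27, 0.24),
                             kd1 = c(0.55, 0.58, 0.52, 0.56),
                             kd2 = c(0.44, 0.47, 0.49, 0.45)))
```

A configuration-driven orchestration (`run_config()` + `run_pipeline()`,
stages `simulate`, `quantify`, `sholl`, `spines`, `behavior`, `stats`,
`report`) writes CSV/JSON artifacts stamped with the configuration hash;
`inst/cli/neuroquant.R` is a thin command-line wrapper over the same
functions.

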