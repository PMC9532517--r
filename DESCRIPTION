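Package: neuroquant
Title: Synapse Density, Sholl, Spine and Behavior Quantification for
    Fluorescence Neuron Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Threshold-mask quantification of excitatory synapse density from
    multi-channel fluorescence microscopy: per-image adaptive (mean + k*SD)
    thresholding, triple- and dual-channel colocalized puncta detection with a
    size cutoff, and density per micrometer of traced dendrite. Includes
    skeleton-based dendrite tracing with Sholl intersection profiling,
    stand-in dendritic spine morphometry and classification, spatial
    object-recognition exploration scoring from nose-point trajectories,
    western-blot densitometry normalization, and the accompanying statistical
    battery (Welch t, one-way ANOVA with Dunnett's T3 or Tukey post hoc,
    Fisher's LSD, Kolmogorov-Smirnov). A synthetic-data module generates
    confocal-like three-channel neuron images, trajectories and band tables
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
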