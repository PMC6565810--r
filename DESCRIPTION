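Package: sleepmodes
Title: Eigenmode Neural-Field Modelling and Envelope Connectivity of Infant Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sleep-state-dependent reorganization of large-scale
    cortical networks in newborn infants. Solves Laplace-Beltrami eigenmodes of a
    cortical surface mesh by linear finite elements, simulates parcel-level neural
    activity as a noisy superposition of amplitude-modulated eigenmodes, estimates
    orthogonalized amplitude-envelope functional connectivity with an
    edge-reliability mask and global normalization, tests network contrasts with
    the network-based statistic (permutation FWER) and spectral effect-size
    fingerprints over log-spaced carrier-by-amplitude filter banks, fits
    per-subject mode weights by moment matching with two-step noise estimation,
    and performs mixed-design ANOVA, partial correlations with FDR control and
    hemispheric-asymmetry tests. Includes a synthetic-cohort generator so the
    whole pipeline runs end-to-end without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
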