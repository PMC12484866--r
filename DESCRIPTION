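Package: ivmatch
Title: Image-Varifold Measures and Diffeomorphic Matching for Spatial Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Represents spatial-omics data and labeled anatomical atlases as
    weighted particle measures carrying feature distributions (image
    varifolds) and matches them across scales and modalities.  Provides
    reproducing-kernel varifold inner products and norms, geodesic shooting
    under Hamiltonian particle dynamics (LDDMM) with space and mass momenta,
    cross-modality matching with latent per-region feature laws and a
    Kullback-Leibler prior, censored (partial-volume) matching with planar
    or learned spatial support weights, optimization-based scale-space
    particle resampling with K-means and grid baselines, mutual-information
    scoring of spatially variable features, and rigid alignment of section
    stacks.  Seeded synthetic phantom generators allow the full pipeline to
    run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
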