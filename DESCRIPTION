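Package: minfluxr
Title: Single-Molecule MINFLUX Structural and Tracking Analysis
Version: 0.1.0
Authors@R: person("minfluxr", "developers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Analysis pipeline for 3D MINFLUX single-molecule localization
    data of trimeric membrane channels: localization table IO (CSV/TSV and
    Imspector MAT exports), refractive-index z correction and trace quality
    filters, two-step DBSCAN clustering with spherical Gaussian-mixture
    refinement of fluorophore positions, identification of isolated trimers
    and their 3D interblade distances, gap-truncated trajectory building with
    weighted mean-squared-displacement diffusion fits over microscopic and
    macroscopic lag windows, the associated statistical comparisons
    (Kolmogorov-Smirnov, variance F test, bootstrap median confidence
    intervals, Kruskal-Wallis with Dunn post hoc), and a two-channel STED
    colocalization branch (ROI masking, in-ROI Pearson/Spearman correlation,
    puncta FWHM). A synthetic-data generator emulates DNA-PAINT MINFLUX
    scenes, Brownian tracking data and two-channel images so the full
    pipeline is testable without raw microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
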