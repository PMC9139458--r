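Package: plateletSPT
Title: Single-Particle Tracking and Mobility Analysis of Platelet Membrane Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantifying lateral mobility of
    membrane receptors (such as FcgammaRIIA) on spreading platelets from
    quantum-dot single-particle tracking in TIRF microscopy. Generates
    ground-truth receptor trajectories under directed, Brownian and confined
    subdiffusive motion regimes, renders them as blinking diffraction-limited
    emitters in noisy movies stratified by platelet-like region masks
    (filopodia, lamellipodia, cell body), recovers tracks by
    Laplacian-of-Gaussian spot detection, phase-correlation drift correction
    and gap-closing nearest-neighbour linking, estimates per-track
    time-averaged mean squared displacement, fits the combined anomalous plus
    directed diffusion model MSD(t) = 4*D*t^alpha + v^2*t^2, computes track
    lengths and motion classes, and summarises groups with rank-based
    statistics (Kruskal-Wallis with Dunn's multiple comparisons). Also
    provides simple image morphometrics: micropattern coverage, spread-area
    time series and protrusion (filopodia-like) detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    tiff,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
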