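Package: capmotion
Title: Motility Analysis of Cap Mesenchyme Cell Tracks Around Ureteric Tips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing and statistical analysis of 3D cell tracks of
    nephron progenitor (cap mesenchyme) cells swarming around ureteric tips
    in live-imaged embryonic kidney explants. Resolves mitotic branch points
    in tracks by frame-to-frame assignment, computes per-cell geometry
    relative to the nearest ureteric tip, removes spatially heterogeneous
    tissue drift using inverse-square-distance weighted tip movements,
    derives motility statistics (mean squared displacement, velocity
    autocorrelation, speed heterogeneity, tip-directed movement), and fits a
    steady-state convection-diffusion model of the cell-to-tip distance
    distribution by maximum likelihood. Includes a synthetic track generator
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
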