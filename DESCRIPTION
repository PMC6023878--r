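Package: popshift
Title: Population Decoding and State-Dependent Geometry of Trial-Structured Spike Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-aligned spike recordings from Go/No-Go
    click-rate discrimination tasks: optimal-prior linear stimulus reconstruction
    with lagged per-unit filters, vector-strength and Rayleigh phase-locking
    statistics, prototype-based linear population decoding with balanced
    pseudo-population cross-validation and label-shuffle nulls, projection of
    population activity onto decoding axes with spontaneous-baseline geometry
    (asymmetry and target-enhancement indices, cross-state attribution), and
    iterative removal of lick-responsive units to control for motor confounds.
    Includes a synthetic-session generator that plants each of these structures
    in inhomogeneous-Poisson spike trains so the full pipeline is verifiable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
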