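Package: nucsas
Title: Small-Angle Scattering Analysis of Nucleosome Core Particles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of one-dimensional small-angle X-ray and neutron
    scattering (SAXS/SANS) profiles of protein-DNA complexes, with an
    emphasis on nucleosome core particles.  Provides reading, writing and
    merging of three-column .dat profiles; neutron scattering-length-density
    and X-ray electron-density contrast calculations with H/D exchange and
    match-point prediction; model-free analysis (Guinier fits with automatic
    window selection, regularized indirect Fourier transform P(r) inversion,
    dimensionless Kratky transforms, difference P(r)); Stuhrmann
    contrast-variation analysis; component molecular weights and per-q
    protein/DNA/cross-term intensity decomposition from contrast series;
    core-shell cylinder form factors with global multi-contrast fitting;
    Debye-formula bead-model scattering; and a synthetic nucleosome
    scattering generator with recorded ground truth for validation,
    including high-pressure unwrapping/hysteresis series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
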