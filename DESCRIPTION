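Package: valvespectra
Title: FTIR Spectral Fingerprinting of Oxidative Damage in Decellularized Heart-Valve Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric analysis of attenuated-total-reflection Fourier
    transform infrared (FTIR-ATR) spectra of decellularized heart-valve
    tissue subjected to freeze-drying, dried storage, and induced oxidative
    damage. Implements Savitzky-Golay second-derivative band-ratio
    biomarkers (CH2/CH3 symmetric stretch intensity ratio, amide-I/amide-II
    area ratio, beta-sheet/alpha-helix intensity ratio) with ANOVA and
    Tukey HSD group comparison, principal component analysis and linear
    discriminant analysis of vector-normalized spectral regions, a
    feed-forward neural network classifier evaluated by leave-one-out
    cross-validation, confusion-matrix performance metrics with exact
    binomial confidence intervals, chord-diagram edge-list export,
    quantification of NBT-formazan staining from micrographs, and a
    synthetic-spectrum generator emulating the six treatment groups for
    validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    png
Config/testthat/edition: 3
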