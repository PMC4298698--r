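Package: circaquant
Title: Quantification of Circadian Behavior, Bioluminescence Rhythms, and
    Phase Coherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying circadian organization in rodent
    experiments: light and feeding protocol schedules (Zeitgeber/circadian
    time conversion, gradual food-restriction ramps), wheel-running activity
    records with chi-square periodogram, normalized Fourier power spectra,
    light-masking time courses and food-anticipatory activity metrics,
    FFT-NLLS damped-cosine fitting of PER2::LUC bioluminescence traces with
    relative-amplitude normalization and quality-control exclusion, circular
    phase statistics (mean angle, circular variance, Watson-Williams F test,
    percentile-bootstrap variance-difference test, Mann-Whitney U),
    grid-based quantification of bioluminescence image stacks, and synthetic
    data generators emulating the statistical structure of each assay for
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
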