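Package: eegrqa
Title: Multiscale Recurrence and Entropy Analysis of Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Nonlinear dynamical analysis of multichannel scalp EEG on the
    standard 10-20 montage. Decomposes 30-second awake segments into dyadic
    wavelet frequency bands (MODWT multiresolution analysis), computes
    recurrence quantification measures (maximum and mean diagonal line
    length, trapping time, determinism, laminarity) and sample entropy per
    band, and summarizes them as per-sensor multiscale curves with
    confidence intervals and area-under-curve region statistics contrasting
    centrotemporal against other sensors across case and contrast cohorts
    with a one-way ANOVA. Includes EDF input/output, a seeded synthetic
    cohort generator with a region-localized complexity deficit for
    end-to-end validation, and a reproducible simulate/extract/analyze
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
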