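Package: embryomotion
Title: Quantification of Embryonic Movement from Intensity Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for quantifying the emergence of movement in Drosophila
    embryos from brightfield recordings: per-ROI mean-grey-value trace
    extraction from frame stacks, rolling-baseline detrending with noise
    thresholding, hatch cropping, phase-wise movement summation (myogenic and
    neurogenic phases), sliding-window FFT spectrograms with period-amplitude
    summaries, activity-bout detection, ratiometric GCaMP/tdTomato delta-F/F
    with passive-reporter motion correction, the associated group-comparison
    statistics (four-test normality gate, Mann-Whitney with Bonferroni,
    Welch and Brown-Forsythe ANOVA with Dunnett T3, Kruskal-Wallis with
    Dunn), and qPCR efficiency and fold-change calculations. Includes a
    seeded synthetic-recording generator with genotype presets and ground
    truth so the whole pipeline is testable without recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    zoo,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
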