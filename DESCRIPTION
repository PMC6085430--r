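Package: diauxr
Title: Quantification of Diauxic Lag Times from Microplate Growth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the diauxic shift of bacterial cultures grown
    in microplate readers. A log2 OD600 time series is segmented into three
    line segments by an exhaustive least-squares breakpoint search; the
    diauxic lag is the time between the intersections of adjacent segments
    and is normalized to the first-sugar generation time, giving a
    dimensionless per-well lag ratio. Includes seeded simulators for
    piecewise-exponential diauxic growth, nucleotide (ppGpp/pppGpp/GTP)
    timecourses and decay series, assay standard curves, and comparative-Ct
    qPCR tables; plus fraction-of-total-G normalization, semilog decay-rate
    fitting, linear standard-curve interpolation, 2^-ddCt relative
    expression, Tukey boxplot summaries and pairwise group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
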