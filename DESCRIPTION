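Package: reporterpos
Title: Genomic-Position Effects on Reporter Gene Expression in Sulfolobus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for quantifying how genomic
    integration position shapes expression of a beta-galactosidase (lacS)
    reporter cassette in Sulfolobus acidocaldarius. Estimates enzyme
    activity from ONPG conversion time series by fitting a Monod-type
    smoothed kinetic model over scanned fitting windows, quantifies
    relative transcription from qRT-PCR quantification cycles with the
    delta-delta-CT method, annotates integration sites on the circular
    genome (distance to the nearest replication origin, A/B chromatin
    compartment, transcriptional insulation and read-through donors),
    correlates the transcriptional and translational readouts, and ships
    a seeded synthetic-data generator emulating every input so the whole
    pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    minpack.lm,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
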