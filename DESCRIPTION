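Package: clockmine
Title: Comparative Genomics and Diurnal Rhythm Analysis of KaiABC-Type Circadian Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying KaiABC-type circadian clock systems across
    prokaryotic proteomes and for characterising diurnal gene expression.
    Implements reciprocal best-hit homology screening with exact
    Smith-Waterman local alignment, per-strain clock-factor inventories and
    genus-level similarity summaries, co-occurrence testing of clock factors
    over deduplicated clock systems by right-sided Fisher's exact tests with
    Benjamini-Hochberg correction, harmonic-regression detection of
    24-hour oscillating transcripts with peak-phase and amplitude
    estimation, circular correlation of peak-phase programs between
    datasets, and position-frequency-matrix profiling of conserved KaiC
    sequence motifs. Includes seeded synthetic-data generators that emulate
    protein families at controlled identity, factor presence matrices with
    planted enrichments, and sinusoid-plus-trend expression time series,
    so the whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
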