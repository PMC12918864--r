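Package: mechscreen
Title: Genome-Wide CRISPR Mechanical Sorting Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for pooled CRISPR-knockout screens sorted by
    cell stiffness in a ridged microfluidic device, together with the two
    supporting biophysical assays. Provides seeded synthetic-data generators
    with known ground truth (guide libraries, negative-binomial screen
    counts, amplicon FASTQ reads, Hertzian force curves, ridge-deflection
    cell tracks); sgRNA quantification from FASTQ with Gini-index quality
    control; gene-level negative-binomial Wald enrichment testing with
    median-of-ratios normalization; AFM force-curve analysis with two-stage
    contact-point detection and spherical-indenter Hertz fitting; per-ridge
    trajectory deflection and interaction-time metrics; and a
    hit-prioritization cascade combining functional categories, expression
    terciles, fold-change filters and Kaplan-Meier tercile survival tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    survival
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    car,
    jsonlite
Config/testthat/edition: 3
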