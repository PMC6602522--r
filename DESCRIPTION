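Package: mtratio
Title: Regional Missense Tolerance Ratio Profiles from Coding Variation
Version: 0.1.0
Authors@R:
    person("MTR", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Computes the Missense Tolerance Ratio (MTR), a per-codon measure
    of regional intolerance to missense variation, from an in-frame coding
    sequence and a set of observed single-nucleotide variants. Observed and
    expected missense/synonymous proportions are summed over truncated sliding
    windows; significantly depleted regions are identified with an exact
    binomial test adjusted for false discovery rate by the Benjamini-Hochberg
    method. Includes readers for FASTA coding sequences and VCF/TSV variants,
    population-stratified profiles, variant-query parsing, writers for
    per-variant and per-residue score tables and BED region output, a
    synthetic-data generator with known ground truth for calibration and power
    checks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
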