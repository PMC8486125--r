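Package: nanoscape
Title: Error Landscape Profiling for Nanopore Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterises the sequencing-error landscape of Oxford Nanopore
    long reads from a reference genome and dual-strand alignments. Reconstructs
    per-base alignment columns from SAM records, decomposes errors into
    mismatches, insertions and deletions, profiles substitution bias
    (transitions versus transversions, optionally stratified by base
    modification calls), GC-dependent error and coverage bias, quality-score
    calibration against the Phred scale with a quadratic error model and
    threshold/retention trade-offs, accuracy of low-complexity regions
    (homopolymers, heteropolymers and trinucleotide repeats), perfect k-mer
    statistics with Pearson skewness and seed-size bounds, sequence-specific
    error contexts (harmful k-mers) summarised as layered automata, and
    translocation-speed profiles from per-base signal event counts. Includes a
    synthetic read generator with exact ground truth so the full pipeline is
    verifiable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
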