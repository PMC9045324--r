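Package: replicontools
Title: Virtual Digestion, Collapsed-Repeat Resolution and Rearrangement
    Mapping for Linear Replicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating and comparing assemblies of linear
    bacterial replicons, in particular the giant linear plasmids of
    high-GC actinomycetes. Simulates rare-cutter restriction digests and
    matches predicted fragments to observed pulsed-field gel bands;
    detects assembler-collapsed long terminal inverted repeats from read
    coverage and reconstructs the full-length plasmid; maps structural
    rearrangements (insertions, deletions, inversions, translocations)
    and SNPs between near-identical replicons by unique k-mer anchoring;
    quantifies transposase gene density and tests breakpoint proximity to
    mobile elements by permutation; and generates seeded synthetic
    replicons with full ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
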