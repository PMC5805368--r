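Package: sRNAsurv
Title: Small RNA Biogenesis Signatures and Genome Surveillance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects small RNA biogenesis signatures in genome alignments:
    ping-pong 10-nt 5' overlap and Dicer 2-nt 3' overhang register z-scores,
    per read-size pair and per locus. Provides exact read mapping with a
    multimap cap, genome segmentation into feature classes, read-set cleaning,
    expressed-locus discovery, per-locus strand bias, size distributions,
    5' nucleotide composition and length-normalized coverage metagenes,
    discovery of siRNA-producing transposon-control master loci, per-context
    (CG/CHG/CHH) bisulfite methylation rate accounting with coverage
    filtering, and assembly decontamination statistics (matched-fraction
    filter, N50). Includes a mechanism-labelled synthetic data generator
    (Dicer duplexes, ping-pong pairs, degradation fragments, methylation
    calls) for validation of the statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
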