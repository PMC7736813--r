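Package: duoasm
Title: Arbitration of Two Long-Read Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares a contiguous but error-prone long-read genome assembly
    against a fragmented but accurate one. Calls structural discrepancies
    (uncovered gaps, contig overlaps, redundancies and losses) from
    assembly-to-assembly alignments, defines the consensus-error set from
    read-backed variant calls with GATK-style hard filters and the
    homozygous-genotype rule, characterizes error clustering against a
    Poisson null, scans sliding windows for error enrichment and its
    association with GC content and DNA methylation, classifies the impact
    of each error on protein translation, detects telomere motif arrays and
    centromeric repeat regions, and assesses telomere-to-telomere status.
    Ships a synthetic-truth generator that plants every event class with a
    complete ledger so the whole pipeline is testable without raw
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
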