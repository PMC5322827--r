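Package: rnaprep
Title: Pre-Processing of Spliced RNA-Seq Alignments for SNP Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transforms a coordinate-sorted BAM file of spliced RNA-seq
    alignments into a cleaned, splice-free, deduplicated, overlap-merged BAM
    suitable for haplotype-based SNP callers. Reads are quality-filtered,
    duplicates are collapsed with base-level reconciliation of disagreeing
    copies, overlapping mates are merged so shared fragment evidence is
    counted once, intron-spanning reads are split into their exonic parts,
    and error-prone read ends can be masked by zeroing base qualities. A
    companion per-cycle mismatch profiler measures error rates at the first
    and last sequencing cycles to guide the choice of flank-masking widths.
    Deterministic synthetic references and alignment scenarios are included
    so every rule is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    Rsamtools,
    tibble,
    withr
Suggests:
    GenomicAlignments,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
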