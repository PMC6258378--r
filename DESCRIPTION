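Package: svjigsaw
Title: Nucleotide-Resolution Characterization of Clustered Copy-Number
    Variant Breakpoint Junctions
Version: 0.1.0
Authors@R:
    person("svjigsaw", "Developers", email = "svjigsaw@example.org",
           role = c("aut", "cre"))
Description: Tools for resolving complex germline rearrangements from
    short-read sequencing data at single-nucleotide resolution. Split
    reads bridging a breakpoint junction are clustered and assembled
    into consensus sequences, and junctions are characterized for
    microhomology, templated and non-templated insertions, and nearby
    repeat elements and novel SNVs. Parsed HGVS-like rearrangement
    descriptors and copy-number segments are combined into derivative
    chromosome structures, duplications are classified as tandem or
    interspersed, and per-junction repair-pathway signatures (NHEJ,
    MMEJ, alt-NHEJ, replicative template switching) are scored to
    suggest a formation mechanism (chromothripsis versus
    chromoanasynthesis) per case. A rearrangement simulator with fully
    specified junction chemistry provides ground-truthed synthetic
    references, reads and alignments for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
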