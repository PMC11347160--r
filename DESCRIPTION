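Package: knockinDesign
Title: Design Engine for CRISPR/Cas Insertional Knock-In Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end design of CRISPR/Cas insertional knock-in reagents:
    enumeration and composite ranking of guide RNAs by off-target specificity
    (aggregated MIT/Hsu scoring), cut-to-insert distance and transcript
    position; construction of homology-directed-repair donors (dsDNA or
    ssODN) with optional mutational recoding driven by Cutting Frequency
    Determination (CFD) re-cut scoring, silent codon substitutions and
    non-coding transversions under splice-junction protection; synthesis
    feasibility flagging and homology-arm trimming; automatic ssODN strand
    polarity selection; and genotyping primer design with genome-wide
    in-silico PCR off-target rejection and a staged constraint-relaxation
    ladder. Includes a deterministic synthetic mini-genome generator
    (FASTA + GFF3) so the whole pipeline runs with no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
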