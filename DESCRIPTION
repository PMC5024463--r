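Package: indelstruct
Title: Structural Triage of Small In-Frame Insertions and Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotation and structure-based pathogenicity triage of small
    (<= 21 nucleotide) insertions and deletions detected by panel
    sequencing, as applied to inherited eye disease cohorts. Provides
    VCF/transcript-based indel normalization and consequence calling with
    quality and allele-frequency filters, homopolymer-run and tandem-repeat
    sequence-context classification, structure-template selection by local
    alignment with a variant-window identity criterion, geometric
    annotation of mapped variant residues (secondary structure, solvent
    accessibility, sheet topology, inter-chain contacts and salt bridges),
    rule-based disruption verdicts, concordance statistics against
    clinical assessments, and seeded generators for synthetic cohorts and
    ideal-geometry structures so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
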