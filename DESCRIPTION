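Package: RetinoPanel
Title: Targeted Gene-Panel Diagnostics for Inherited Retinal Dystrophies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the computational workflow of a
    targeted exon-capture gene-panel diagnostic assay for retinitis pigmentosa
    and related retinal dystrophies: capture target design from gene models
    (exon flanks, 3'-UTRs, proximal promoters), pileup-level simulation of
    454-style pyrosequencing output (read lengths, GC-dependent capture
    dropout, homopolymer indel errors, allele read fractions), variant
    consequence annotation and a known-SNP/consequence/read-fraction triage
    cascade with fixed, stringent and dynamic thresholds, per-exon coverage
    summaries with coverage-based multi-exon deletion detection, pedigree
    cosegregation under dominant, recessive and X-linked models, and
    patient-level diagnostic classification with cohort reporting. Ships a
    63-gene panel catalog and a 23-patient diagnostic run synopsis as
    plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: VariantDetection, TargetedResequencing, Coverage, Sequencing,
    Genetics
RoxygenNote: 7.3.3
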