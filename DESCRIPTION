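Package: scmutcall
Title: De Novo Somatic Mutation Calling from Droplet Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls de novo somatic mutations from droplet-based single-cell
    RNA-seq allele counts using a cascade of biologically motivated filters:
    singlet and cross-lineage removal, a per-cell binomial allelic filter,
    Fisher's exact lineage/clonotype enrichment with fixed significance and
    enrichment-factor thresholds, SNP and cross-patient masking, a
    transcribed-strand trinucleotide-context bias filter, and proximity
    clustering. Includes benchmarking of calls against orthogonal DNA
    evidence and TCR clonotype structure, per-lineage mutation-burden
    profiles, neighbor-joining lineage tracing of cell subtypes from
    mutation sharing, and a fully labeled synthetic-data simulator so the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    vcfR
Suggests:
    Rsamtools,
    GenomicAlignments,
    phangorn,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
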