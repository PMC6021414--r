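Package: mitoHyperMut
Title: Detection of APOBEC-Mediated Mitochondrial DNA Hypermutation in
    Amplicon Reads
Version: 0.99.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects APOBEC3-style hypermutation of the circular
    mitochondrial genome from deep amplicon sequencing. Reads are aligned
    to a circular reference (rCRS-style 1-based coordinates, regions may
    wrap the replication origin), a downsampled per-library consensus is
    built with ambiguous bases masked as N, per-read C-to-T/G-to-A
    mutation loads are histogrammed, a hypermutation threshold is
    calibrated from a no-mutation control library, and hypermutated reads
    are reported as parts-per-million frequencies together with 12-class
    substitution matrices, strand-bias summaries and 5'-dinucleotide
    (TpC/CpC) context enrichment chi-square statistics. A synthetic-data
    module simulates strand-specific cytidine deamination with
    dinucleotide-context preference, uniform sequencing error, and an
    in-silico differential-denaturation (3D-PCR) selection stage, so the
    whole pipeline can be exercised and validated against truth labels.
License: MIT + file LICENSE
Depends:
    R (>= 4.3)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Sequencing, SomaticMutation, VariantDetection, Software
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'reference.R'
    'simulate.R'
    'consensus.R'
    'mitoHyperMut-package.R'
    'mutcall.R'
    'spectrum.R'
    'report.R'
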