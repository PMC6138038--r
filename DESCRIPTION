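Package: mitopair
Title: Comparative Analysis of Doubly Uniparentally Inherited Mitogenome Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of bivalve species carrying
    doubly uniparental inheritance (DUI), where maternally (F) and paternally
    (M) transmitted mitochondrial genomes coexist and diverge deeply.
    Provides annotated-genome input/output (GenBank flat files, FASTA),
    sliding-window AT-skew/GC composition profiling, substitution counting
    and uncorrected p-distance scans, a frameshift-aware curation pipeline
    that screens coding sequences by nucleotide/amino-acid alignment
    consistency and recovers protein alignments against position-specific
    scoring profiles, partitioned supermatrix construction with NEXUS/PHYLIP
    export, M-versus-F tree congruence statistics (Robinson-Foulds
    bipartitions, MRCA-normalized node heights), gene-order and
    duplication/tRNA structure comparison, and a seeded simulator of F/M
    mitogenome pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
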