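Package: rlkfam
Title: Genome-Wide Identification and Comparative Analysis of LRR-RLK Gene
    Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide analysis of the leucine-rich
    repeat receptor-like kinase (LRR-RLK) gene family in plant genomes.
    Integrates profile-HMM, similarity-search and transmembrane evidence into
    domain-architecture-validated family calls; assigns genes to the 21
    canonical LRR-RLK subfamilies from a reference-anchored phylogeny;
    profiles exon-intron organisation of the kinase domain and flags
    intronless retrogene candidates; detects tandem-duplication sets on
    annotated chromosomes; scans promoters for IUPAC cis-regulatory elements
    with per-subfamily over-representation tests; performs hypergeometric
    GO/KEGG enrichment and between-species subfamily proportion comparisons;
    and clusters expression matrices with a differential-expression filter.
    A synthetic-study generator with a ground-truth manifest makes every
    stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mclust,
    jsonlite
biocViews: Genetics, Phylogenetics, GeneFamily, Annotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
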