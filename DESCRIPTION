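Package: radmapr
Title: Linkage-Map Construction from RAD-Seq Genotypes in an Outbred F1 Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds chromosome-level linkage maps from restriction-site-associated
    DNA sequencing (RAD-seq) genotypes of a single outbred F1 family.  Provides
    depth-guided filtering of a multi-sample VCF, maximum-likelihood inference of
    parental cross-types under a global heterozygote-dropout model with genotype
    correction, segregation-distortion and parent-concordance filters, pairwise
    recombination-fraction estimation, agglomerative clustering of assembly
    scaffolds into linkage groups, sex-specific map ordering, consensus scaffold
    anchoring and orientation with AGP and GFF liftover output, ortholog-synteny
    micro-inversion analysis, and a synthetic F1-cross simulator with ground truth
    for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
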