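Package: qtlCandidates
Title: Candidate Causal Gene Identification and Prioritization at Molecular QTLs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies and prioritizes candidate causal genes at molecular
    quantitative trait loci (mQTLs, pQTLs and related molecular phenotypes).
    Combines a variant-centric "bottom-up" arm (genes overlapping the sentinel's
    linkage-disequilibrium range, the k nearest protein-coding genes, significant
    cis-eQTL target genes, and coding-consequence IMPACT flags) with a
    phenotype-centric "top-down" arm (sentinel-flanking genes cross-referenced
    against curated annotation gene sets, scored 1-5 by the number of supporting
    databases). Genes found by both arms form the concurrent set, the most
    likely causal candidates; a nearest-concurrent rule yields exactly one gene
    per locus. Includes benchmarking utilities (sensitivity, two specificity
    definitions, criterion-stratified Fisher's exact enrichment with Bonferroni
    correction) and a synthetic-locus simulator with planted causal genes for
    end-to-end validation.
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
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, SNP, GeneTarget, FunctionalGenomics,
    GenePrediction
RoxygenNote: 7.3.3
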