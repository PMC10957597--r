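Package: WildAlleleScan
Title: Prioritising Wild-Relative Alleles of Drought and Salt Response Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A comparative-genomics pipeline for prioritising wild-relative
    alleles of abiotic-stress genes that were lost during crop domestication,
    modelled on the tomato / Solanum chilense system. Genes are selected by
    keyword search over Gene Ontology annotations, matched to their
    counterparts in the cultivated reference by coverage-filtered local
    alignment, and their protein pairs globally aligned to extract amino acid
    substitutions, insertions and deletions. Substitutions are screened with
    PROVEAN / SIFT4G / PPVED deleteriousness scores, back-translated through
    the reference gene models to genomic SNVs, intersected with per-accession
    VCFs under a homozygous-evidence rule, and summarised as a species-level
    allele-sharing matrix with hierarchical clustering and a heatmap. The
    package also estimates genome size from a k-mer occurrence spectrum
    (error spike, heterozygous and homozygous peaks) and ships a synthetic
    data generator that produces every pipeline input with recorded ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    pheatmap,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
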