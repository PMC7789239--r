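Package: timephen
Title: Tumor Immune Microenvironment Phenotyping from Bulk Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers and validates tumor immune microenvironment (TIME)
    phenotypes from bulk expression data. Provides single-sample gene set
    enrichment (ssGSEA) scoring of immune cell-type marker sets, resampled
    consensus clustering with PAC-based selection of the number of clusters,
    in-group proportion (IGP) cross-cohort validation, a phenotype-signature
    TIME index with optimal survival cutoff, and a nearest-centroid
    single-sample classifier. Companion genomic procedures cover
    epigenetically silenced gene calling from methylation beta-values,
    global methylation level, fraction of genome altered/gained/lost from
    copy-number segments, mutational signature extraction by non-negative
    matrix factorization with cosine matching to a reference catalogue, and
    a multi-omics immunomodulator regulation screen. A synthetic multi-omic
    cohort generator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    survival,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
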