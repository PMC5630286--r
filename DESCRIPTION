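Package: mbsomatic
Title: Tumor-Only Somatic Mutation Discovery for Mouse Medulloblastoma Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tumor-only somatic SNV/indel discovery workflow for mouse
    medulloblastoma whole-exome data, built around Fisher's-exact somatic
    criteria against a public reference normal, multi-stage germline
    filtering (SNP databases, then raw read evidence from a panel of 18
    laboratory strains), realignment-based SNV and indel review, and
    ancestor-panel validation. Downstream components annotate coding
    consequences, map mouse mutations to human orthologs in mRNA space,
    compare against a human medulloblastoma mutation catalog, and compute
    cohort statistics (per-tumor burden, subgroup comparisons,
    hypergeometric enrichment). A seeded synthetic-cohort generator
    emulates the study design (18 strain haplotypes, 12 tumors in three
    subgroups, ancestor controls) for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    BiocGenerics,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
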