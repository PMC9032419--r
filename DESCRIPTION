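Package: karyodose
Title: Copy-Number-Aware, Allele-Resolved Transcriptome Analysis for
    Aneuploid Hybrid Yeasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gene expression in aneuploid interspecies
    hybrid yeasts such as lager-brewing Saccharomyces pastorianus, in which
    S. cerevisiae (Sc) and S. eubayanus (Se) sub-genomes coexist at unequal
    chromosome copy numbers. Provides binned-coverage karyotyping with
    hybrid-chromosome breakpoint detection, a negative-binomial Wald test
    for differential expression with median-of-ratios normalisation,
    orthologue (homeolog) pairing and allele dosage-expression regression,
    chi-squared sub-genome representation tests, an orthologue-summed
    consolidated transcriptome with cross-strain comparison, hypergeometric
    gene-set enrichment with sub-genome composition scores, and a synthetic
    hybrid-genome generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
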