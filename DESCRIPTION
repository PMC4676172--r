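Package: oltseq
Title: Genomic Deconvolution and Prognostic Screening for Post-Transplant
    Recurrent Liver Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrated genomic analysis of matched primary and
    post-transplant recurrent hepatocellular carcinoma: verification of tumor
    origin through a clonal-relationship statistic on shared somatic variants,
    maximum-likelihood estimation of donor-cell contamination from germline
    SNP allele fractions and from somatic VAF dilution, binned copy-number
    log-ratio segmentation with cross-patient recurrent-region discovery,
    negative-binomial differential expression with median-of-ratios
    normalization, deletion-by-under-expression candidate gene integration,
    and Kaplan-Meier / Cox proportional-hazards prognostic screening. Includes
    a synthetic cohort generator with ground truth that emulates the
    five-specimen transplant study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
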