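Package: glsskat
Title: Generalized Least-Squares SKAT for Rare-Variant Association in Family Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based gene-region rare-variant association testing by
    generalized least squares. A kinship matrix estimated from dense genotype
    data (Balding-Nichols or identity-by-state) is used to decorrelate the
    phenotype and genotype matrices, after which weighted SKAT, burden and
    SKAT-O tests with exact quadratic-form tail probabilities are applied per
    gene region. Includes a gene-dropping pedigree simulator with a
    covariate-plus-polygenic quantitative trait model, REML heritability
    estimation for a heritability-weighted transform, readers and writers for
    VCF/PED/TSV inputs, and an evaluation harness for pooled type-I error,
    power and genomic-control lambda.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
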