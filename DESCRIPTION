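Package: grsonset
Title: Genetic Risk Scores and Age at Onset of Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of unweighted and weighted genetic risk scores
    (GRS) from VCF genotypes and GWAS effect-weight tables, with effect-allele
    harmonization and proxy-variant substitution, and downstream age-at-onset
    analyses for coronary revascularization cohorts: sex-specific age strata,
    Cochran-Armitage and linear trend tests, correlation, sex-adjusted and
    multivariable linear models, and interaction tests. Includes a synthetic
    cohort generator (Hardy-Weinberg genotypes, GWAS-scale effect sizes,
    covariates with age-dependent prevalence) so the whole pipeline is
    testable without access to individual-level data.
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
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
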