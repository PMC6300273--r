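Package: grsburden
Title: Blood-Pressure Genetic Risk Scores and Coronary Disease Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct unweighted and effect-size-weighted genetic risk
    scores (GRS) from a blood-pressure SNP panel and genotype dosages, with
    the quality-control filters used in hypertension GRS studies (minor
    allele count, variant missingness, sample call rate, Hardy-Weinberg
    equilibrium, LD pruning, proxy substitution), and estimate
    quartile-based associations of the score with hypertension, coronary
    heart disease, and multi-level coronary-vessel burden via logistic and
    baseline-category multinomial regression. Includes a seeded synthetic
    cohort generator with known ground truth for calibration and
    parameter-recovery testing, pleiotropy and interaction screens,
    sensitivity-subset analyses, and forest-table output.
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
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
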