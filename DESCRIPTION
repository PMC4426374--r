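Package: migwas
Title: Multiple-Imputation Genome-Wide Association for Low-Depth
    Genotyping-by-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association testing when most genotype calls are
    missing, as is typical of low-depth genotyping-by-sequencing (GBS)
    panels. Missing allelic dosages are multiply imputed by fully
    conditional specification (a pseudo-Gibbs sampler) with classification
    trees defining donor pools, and single-marker mixed-model tests run
    under four schemes (complete cases, average dosages, multiple imputes
    with fixed structure, and multiple imputes with per-impute structure
    and kinship). Per-impute estimates are pooled by Rubin's rules with
    Barnard-Rubin degrees of freedom and the gamma fraction-of-missing-
    information statistic, and significance is controlled by Storey
    q-values. Includes a synthetic GBS panel generator (population
    structure, linkage-disequilibrium blocks, calibrated per-marker
    missingness, polygenic traits) and the imputation-uncertainty
    diagnostics: scheme-consistency regressions, the arcsin(gamma) factor
    model with cross-validation, average mutual information, and pairwise
    r-squared on average dosages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rpart,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
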