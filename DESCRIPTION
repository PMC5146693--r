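Package: grslife
Title: Genomic Risk Scores and Lifetime Risk of Coronary Heart Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and survival-based evaluation of polygenic
    (genomic) risk scores for incident coronary heart disease. Builds an
    LD-thinned, summary-statistic-weighted genomic risk score from GWAS
    weights and genotype dosages; computes 10-year clinical risk from
    coefficient-table engines (Framingham-style and pooled-cohort-equation
    style); fits age-timescale, sex-stratified Cox models with delayed
    entry; and quantifies incremental predictive value with the 10-year
    truncated Harrell C-index and its correlated jackknife comparison,
    categorical and continuous net reclassification improvement, integrated
    discrimination improvement, Kaplan-Meier and Aalen-Johansen lifetime
    risk curves, and fixed-effect inverse-variance meta-analysis. Includes
    a synthetic cohort generator (LD-blocked genotypes, summary statistics,
    Weibull proportional-hazards event times with competing mortality) so
    the whole pipeline is testable without individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    pROC,
    vcfR
Config/testthat/edition: 3
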