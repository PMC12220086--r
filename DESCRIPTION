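Package: rxdose
Title: Medication Dose Phenotypes from Drug Purchase Records and Their
    Genetic Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives longitudinal medication dose phenotypes (daily dose
    per purchase, median dose, maximum dose, treatment length) from
    pharmacy dispensing records, applies cohort selection filters, and
    relates the phenotypes to polygenic scores and pharmacogenomic
    variants: linear mixed models with random intercepts and time
    slopes for daily doses, forward stepwise regression against a
    Bonferroni threshold, a per-variant association scan with
    rank-based inverse normal transformation, windowed LD pruning,
    permutation-based pharmacogene set enrichment, and an adjusted
    R-squared variance partition of polygenic versus pharmacogenomic
    contributions. Ships a synthetic biobank generator with planted
    effects so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    MASS,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
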