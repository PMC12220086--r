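#!/usr/bin/env Rscript
# Stage 1: generate the synthetic biobank used by all downstream stages.
#
# Conditions: 2,000 people on a statin-like drug with package strengths
# 10/20/40/80 mg, three correlated polygenic scores (CHD and BMI with
# planted positive effects on log daily dose, EA null), one planted
# large-effect pharmacogene variant, 20% refill jitter, stockpiling and
# >365-day treatment breaks. Everything is reproducible from one seed.

library(rxdose)

seed <- 2026
fix_dir <- "results/fixture"

cfg <- simulation_config(
  n_individuals = 2000,
  n_variants = 400,
  beta_pgs = c(CHD = 0.05, BMI = 0.03, EA = 0),
  pgx_variants = data.frame(variant_id = "rs_pgx1", freq = 0.25,
                            beta = -0.25, gene_id = "PGXGENE1"),
  seed = stage_seed(seed, "simulate"))

cohort <- simulate_cohort(cfg)
paths <- write_fixture(cohort, fix_dir)

cat("Synthetic cohort written to", fix_dir, "\n")
cat("  persons:   ", nrow(cohort$covariates), "\n")
cat("  purchases: ", nrow(cohort$purchases), "\n")
cat("  variants:  ", ncol(cohort$genotypes),
    "(", nrow(variant_filter(cohort$variant_info)), "pass MAF/info filters )\n")
cat("  planted PGS effects:",
    paste(names(cfg$beta_pgs), cfg$beta_pgs, sep = "=", collapse = ", "), "\n")
cat("  planted PGx effect: ", cfg$pgx_variants$beta, "per allele at freq",
    cfg$pgx_variants$freq, "\n")
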