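#!/usr/bin/env Rscript
# Stage 6: relative contributions of polygenic scores and pharmacogene
# variants to the median dose, via adjusted R^2 across four nested
# models: base covariates; + PGx dosages; + PGSs; + both.

library(rxdose)
library(data.table)

fx <- read_fixture("results/fixture")
summ <- fread("results/dose_summaries.tsv", colClasses = list(character = "person_id"))
assoc <- fread("results/pgs_association.tsv")

selected <- unique(assoc[model_tag == "ols_median" & !is.na(term) &
                           term %in% colnames(fx$pgs) &
                           (is.na(candidate) | candidate == ""), term])
if (!length(selected)) selected <- "CHD"
pgx_ids <- vapply(fx$truth$pgx_variants, function(v) v$variant_id, "")
cat("PGS terms:", paste(selected, collapse = ", "),
    "| PGx variants:", paste(pgx_ids, collapse = ", "), "\n")

pgs_z <- standardize_pgs(fx$pgs)[, selected, drop = FALSE]
pgx_z <- scale(fx$genotypes[, pgx_ids, drop = FALSE])

vp <- variance_partition(summ, fx$covariates, pgs_z, pgx_z)
tab <- vp$table
cat("\nAdjusted R^2 ladder:\n")
print(tab[, .(model, r2 = round(r2, 4), adj_r2 = round(adj_r2, 4), p_terms)])
cat("\nPGx adds", round(tab[model == "base_pgx", adj_r2] -
                          tab[model == "base", adj_r2], 4),
    "adjusted R^2 over base; PGS adds a further",
    round(tab[model == "full", adj_r2] -
            tab[model == "base_pgx", adj_r2], 4), "\n")

fwrite(tab, "results/variance_partition.tsv", sep = "\t")
cat("Wrote results/variance_partition.tsv\n")
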