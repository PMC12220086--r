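#!/usr/bin/env Rscript
# Stage 5: pharmacogene set analysis on the scan results.
#
# Variants map to genes with +/- 5 kb flanks, one top SNV per gene is
# kept, both the drug's PGx set and the all-gene background are
# LD-pruned (50-kb window, step 5 SNVs, r^2 <= 0.2), the set's median p
# is compared to 10,000 permuted background draws, and PGx SNVs below
# the 5th background percentile are reported as hits.

library(rxdose)
library(data.table)

seed <- 2026
fx <- read_fixture("results/fixture")
scan <- fread("results/gwas_median.tsv",
              colClasses = list(character = c("variant_id", "chromosome")))

top <- map_top_snv_per_gene(scan, fx$genes)
cat("Genes with an assigned top SNV:", nrow(top), "\n")

bg_pruned <- ld_prune(top[, .(variant_id, chromosome, position, p)],
                      fx$genotypes)
bg_top <- merge(bg_pruned, top[, .(gene_id, variant_id)], by = "variant_id")
drug0 <- unique(fx$gene_sets$drug)[1]
set_genes <- fx$gene_sets[drug == drug0, gene_id]
pgx_pruned <- bg_top[gene_id %in% set_genes]
cat("Pruned background:", nrow(bg_pruned), "SNVs; pruned PGx set:",
    nrow(pgx_pruned), "genes\n")

if (nrow(pgx_pruned) >= 10) {
  enr <- permutation_enrichment(pgx_pruned$p, bg_pruned$p, n_perm = 10000,
                                seed = stage_seed(seed, "enrich"))
  cat("Observed median p:", signif(enr$observed_median_p, 3),
      "| permutation p:", enr$permutation_p, "\n")
  hits <- empirical_threshold_hits(pgx_pruned, bg_pruned$p)
  cat("Empirical 5% threshold:", signif(hits$threshold, 3), "—",
      nrow(hits$hits), "PGx SNV(s) below it\n")
  if (nrow(hits$hits)) print(hits$hits[, .(gene_id, variant_id, p = signif(p, 2))])
  fwrite(data.table(drug = drug0, n_genes_pruned = enr$n_genes_pruned,
                    observed_median_p = enr$observed_median_p,
                    n_permutations = enr$n_permutations,
                    permutation_p = enr$permutation_p,
                    background_size = enr$background_size,
                    threshold_5pct = hits$threshold),
         "results/enrichment.tsv", sep = "\t")
  fwrite(hits$hits, "results/enrichment_hits.tsv", sep = "\t")
  cat("Wrote results/enrichment.tsv, enrichment_hits.tsv\n")
} else {
  cat("Pruned PGx set below 10 genes; enrichment test refused.\n")
}
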