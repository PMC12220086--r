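#!/usr/bin/env Rscript
# Stage 2: cohort selection and dose phenotypes.
#
# Applies the inclusion filters (age >= 18, span > 365 days, >= 6 unique
# purchase dates, first purchase on/after 2005-01-01), then derives the
# dose variables: 14-day consolidation, >365-day batching, daily dose
# per purchase, median of within-batch medians, maximum repeatedly
# purchased strength, and treatment length on supply. Log-scale 3-SD
# outliers and treatment lengths below 2 years are excluded for the
# consolidated metrics.

library(rxdose)
library(data.table)

seed <- 2026
fx <- read_fixture("results/fixture")

spec <- cohort_spec("C10AA05",
                    first_purchase_on_or_after = as.Date("2005-01-01"))
icd <- assign_main_icd(fx$purchases, seed = stage_seed(seed, "icd"))
sel <- select_cohort(fx$purchases, spec, main_icd = icd)
cat("Cohort selection:\n")
print(sel$ledger)
cat("  retained:", length(sel$persons), "persons; cohort accepted:",
    sel$accepted, "\n\n")

dose <- derive_dose_phenotypes(sel$purchases)
flt <- log_outlier_filter(dose$daily$daily_dose)
daily <- dose$daily[flt$keep]
cat("Daily doses:", nrow(dose$daily), "observations,",
    flt$n_excluded, "excluded by the 3-SD log filter\n")

summ <- dose$summary[!is.na(median_dose)]
n0 <- nrow(summ)
summ <- summ[treatment_length_years >= 2]
cat("Median-dose set:", n0, "persons,", n0 - nrow(summ),
    "below 2 years' supply excluded\n")
mflt <- log_outlier_filter(summ$median_dose)
summ <- summ[mflt$keep]
cat("  ", mflt$n_excluded, "median-dose outliers excluded; final n =",
    nrow(summ), "\n")
cat("  median dose mg (mean, SD):", round(mean(summ$median_dose), 1),
    ",", round(sd(summ$median_dose), 1), "\n")
cat("  top strength group:", paste(dose$max_dose$top_levels, collapse = "+"),
    "mg;", sum(summ$max_dose_binary == 1, na.rm = TRUE), "carriers\n")

cs <- cohort_summary(sel$purchases, fx$covariates)
cat("  purchases on unique dates (mean, SD):", round(cs$purchases_mean, 1),
    ",", round(cs$purchases_sd, 1), "\n")
cat("  female:", cs$percent_female, "%\n")

dir.create("results", showWarnings = FALSE)
write_tsv_out <- function(x, f) data.table::fwrite(x, file.path("results", f),
                                                   sep = "\t")
write_tsv_out(daily, "daily_doses.tsv")
write_tsv_out(summ, "dose_summaries.tsv")
write_tsv_out(sel$ledger, "exclusion_ledger.tsv")
cat("Wrote results/daily_doses.tsv, dose_summaries.tsv, exclusion_ledger.tsv\n")
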