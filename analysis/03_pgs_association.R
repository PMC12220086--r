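#!/usr/bin/env Rscript
# Stage 3: polygenic score associations with the dose phenotypes.
#
# Median dose: OLS on log median dose with forward stepwise selection
# against the Bonferroni threshold. Maximum dose: logistic regression.
# Daily doses: linear mixed model with per-person random intercept and
# random time slope. The generator planted CHD = 0.05 and BMI = 0.03
# per SD on log dose, EA = 0, so stepwise should select CHD and BMI.

library(rxdose)
library(data.table)

seed <- 2026
fx <- read_fixture("results/fixture")
summ <- fread("results/dose_summaries.tsv", colClasses = list(character = "person_id"))
daily <- fread("results/daily_doses.tsv", colClasses = list(character = "person_id"))

pgs_z <- standardize_pgs(fx$pgs)
cand <- colnames(pgs_z)
thr <- bonferroni_threshold(length(cand))
cat("Candidates:", paste(cand, collapse = ", "),
    "| Bonferroni threshold:", signif(thr, 3), "\n\n")

## median dose, forward stepwise OLS
med_fitter <- function(terms) fit_linear_median(summ, fx$covariates, pgs_z,
                                                pgs_terms = terms)
sw <- forward_stepwise(med_fitter, cand, thr)
cat("Median dose — single-score models:\n")
print(sw$single[, .(candidate, beta = round(beta, 4), se = round(se, 4),
                    p = signif(p, 2))])
cat("Selected (in order):", paste(sw$selected, collapse = " -> "), "\n")
if (!is.null(sw$final))
  print(sw$final[term %in% sw$selected,
                 .(term, beta = round(beta, 4), se = round(se, 4),
                   p = signif(p, 2))])

## maximum dose, logistic
mx <- summ[!is.na(max_dose_binary)]
if (data.table::uniqueN(mx$max_dose_binary) > 1) {
  lg <- fit_logistic_max(mx, fx$covariates, pgs_z, pgs_terms = sw$selected)
  cat("\nMaximum dose — odds ratios per SD (joint model):\n")
  print(lg[term %in% sw$selected,
           .(term, or = round(or, 3), ci_low = round(ci_low, 3),
             ci_high = round(ci_high, 3), p = signif(p, 2))])
}

## daily doses, linear mixed model
lmm <- fit_lmm_daily(daily, fx$covariates, pgs_z, pgs_terms = sw$selected)
cat("\nDaily doses — mixed model (", unique(lmm$model_tag), "):\n", sep = "")
print(lmm[term %in% sw$selected,
          .(term, beta = round(beta, 4), se = round(se, 4), p = signif(p, 2))])

out <- rbindlist(list(sw$single, if (!is.null(sw$final)) sw$final, lmm),
                 fill = TRUE)
fwrite(out, "results/pgs_association.tsv", sep = "\t")
cat("\nWrote results/pgs_association.tsv\n")
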