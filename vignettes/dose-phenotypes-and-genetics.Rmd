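---
title: "Deriving medication dose phenotypes from purchase records and relating them to polygenic and pharmacogenomic variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving medication dose phenotypes from purchase records and relating them to polygenic and pharmacogenomic variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxdose)
```

## The problem

Pharmacy dispensing registries record, for every prescription filled,
the date, the package strength (mg per pill), the package size, and the
number of packages. They do not record the prescribed daily dose. Yet
for drugs taken chronically — statins, beta blockers, anticoagulants,
antidepressants — the purchase rhythm itself encodes the dose: a person
taking 20 mg/day who buys 30-pill packages of 20 mg returns roughly
every 30 days, so dispensed milligrams divided by the time to the next
purchase estimates the daily maintenance dose. `rxdose` implements this
estimator and the filtering scaffolding it needs, then connects the
derived phenotypes to genetics: polygenic scores (PGS) for traits that
drive prescribing, and single pharmacogene (PGx) variants that alter
drug metabolism.

## Dose phenotypes

Three phenotypes are derived per person and drug.

**Daily dose per purchase.** Purchases within 14 days of an earlier
purchase are consolidated into it (dated at the earliest date — people
sometimes split one fill across pharmacy visits). Runs of purchases
separated by gaps of more than 365 days form separate *batches*;
within a batch, purchase *i* contributes `total_mg_i / (date_{i+1} -
date_i)` mg/day, and the last purchase only closes the previous
interval. Single-purchase batches carry no interval and are dropped.
Two conventions were genuinely open and are fixed here: consolidation
is greedy from the earliest purchase with the window anchored at its
opening date (no transitive chaining across overlapping windows), and
"within 2 weeks" means ≤ 14 days inclusive while a batch break is
strictly > 365 days.

**Median dose.** The median of daily doses is taken within each batch
first and then across batch medians, so a short trial period does not
outweigh years of stable treatment. Even-count medians are the midpoint
of the central pair. Persons with a treatment length below 2 years are
excluded before this phenotype is analysed — short histories produce
unstable medians — and so are log-scale outliers (below).

**Maximum dose.** The highest package strength bought on at least three
unique (non-consolidated) dates. Cohort-wide, the top strength is
merged downward with the next level until the top group has at least
100 carriers, and the analysis variable is binary membership in that
top group. This phenotype captures peak treatment intensity without
aggregating purchases.

Supporting machinery: treatment length is total pills dispensed at one
pill per day, divided by 365.25 (the conversion the registry wording
leaves open; the Julian year is used); class-level pooling first scales
each drug by its WHO Defined Daily Dose factor so a value of 1 means
one standard maintenance dose; a mono-drug filter retains a purchase
only when the target drug accounts for at least 75% of the class's
purchases (counted on unique purchase dates, boundary inclusive) in the
forward-looking year from that purchase; and dose values more than 3 SD
from the mean on the natural-log scale are excluded in one
non-iterative pass with moments pooled over the whole cohort.

Cohort selection applies, in a fixed order: purchases before age 18
dropped, then per person an a-priori id exclusion, span > 365 days,
at least 6 purchases on unique *raw* dates (consolidation exists only
inside dose derivation), a first-purchase date on or after 2005-01-01
for longitudinal analyses, and a main-diagnosis restriction where a
drug class needs one (the main code is the person's modal prescription
code, ties broken by a seeded draw). Every excluded person is
attributed to the first filter that removed them, so attrition tables
reproduce exactly.

## Association models

Daily doses are modelled on the natural-log scale — a Box-Cox profile
over the intercept-only model is reported (`boxcox_select()`), and for
multiplicative dose data its λ confidence interval covers 0 — with a
linear mixed model: fixed effects for sex, age at purchase, years since
first purchase, ten genotype PCs and the PGS terms; a per-person random
intercept and random slope on years since first purchase with
unstructured covariance; REML with the BOBYQA optimizer. Singular
random-effect fits are automatically refit with the intercept only and
flagged. P-values are Wald z on the fixed effects. Satterthwaite-type
degrees of freedom would be slightly more conservative in small
cohorts; at the cohort sizes this package targets (hundreds of persons,
tens of observations each) the difference is negligible, and tests that
compare against planted effects use 2-SE bands rather than exact
p-values for this reason.

Median dose uses OLS on log dose (sex, birth year, treatment length,
ten PCs); maximum dose uses logistic regression with odds ratios per SD
of PGS. PGSs are standardized to Z-scores with moments from a reference
population, and analysis subsets are extracted *afterwards* — a
subset's scores need not have mean 0. Affine changes of the raw scores
therefore never change any p-value.

Forward stepwise selection first fits each candidate PGS alone, then
greedily adds the remaining candidate with the smallest conditional
p-value while that p-value beats the Bonferroni threshold (family α of
0.05 over the number of candidate scores: 11 scores give 0.0045, 12
give 0.004). Reported coefficients come from the final joint model; the
one-at-a-time results are returned alongside. With correlated
candidates proxying one signal, only the stronger enters — the second
is conditionally non-significant — which is the behaviour the selection
is designed to expose.

The variance partition fits four nested OLS models of log median dose —
base covariates; + PGx variant dosages; + PGSs; + both — with all
genetic predictors as Z-scores, and reports adjusted
R² = 1 − (1 − R²)(n − 1)/(n − p − 1). Unadjusted R² is monotone along
the nesting; adjusted R² need not be.

## The per-variant scan

Variants with MAF < 0.5% or imputation info < 0.8 are removed
(boundaries keep-at-threshold). The quantitative phenotype is
rank-inverse-normal transformed with the Blom offset,
Φ⁻¹((r − 3/8)/(n + 1/4)), average ranks on ties; the offset variant is
a free choice and Blom is the common default. Each variant is then
tested in its own additive-coding regression. The linear scan
residualizes phenotype and genotypes on the covariates once via QR and
regresses residual on residual; by Frisch–Waugh–Lovell this equals the
full multiple regression exactly (estimate, SE, and t), which the test
suite verifies against a direct normal-equations solve at 1e-8
relative tolerance. The logistic scan fits one GLM per variant with
Wald tests from the final IRLS weights. Optional covariates implement
the two standard designs: adding the indication trait's PGS (does the
signal survive adjustment for disease genetics?) and conditioning on
known functional variants (is a locus merely tagging them?). A
whole-genome mixed-model scan is deliberately out of scope: the
synthetic cohorts are unrelated by construction, so plain fixed-effects
regression is the correct tool at this scale.

## PGx gene-set enrichment

Scan results are reduced to one SNV per gene: a variant belongs to
every gene whose interval ± 5 kb contains it (inclusive; multi-gene
membership allowed), and per gene the minimum-p variant is kept, ties
to the smaller position. Both the drug's PGx gene set and the all-gene
background are then LD-pruned — 50-kb window, step of 5 SNVs, r² (of
dosages) threshold 0.2 — and the pruning is applied *separately but
with identical rules* to both sets so the null comparison is fair.
When a pair violates the threshold the larger-p member is dropped
(tie: larger position); passes repeat until stable and a final sweep
guarantees the postcondition that no retained pair within 50 kb has
r² > 0.2, which the tests verify by brute force.

The enrichment statistic is the median p of the pruned PGx set
(medians resist the single-tiny-p outlier), compared with 10,000
medians of equal-size samples drawn without replacement from the
pruned background (which includes the PGx genes). The permutation p is
the plain proportion of permuted medians at or below the observed one;
this can be exactly 0, and a (r+1)/(B+1) estimator is available behind
a flag for users who prefer a positively biased but nonzero value.
Sets with fewer than ten pruned genes are refused. Separately, PGx
SNVs below the 5th percentile of the background p-values (linear
interpolation between order statistics) are reported as hits; by
construction about 5% of the background sits below that threshold.

A caveat worth stating because it is quantitative: the median statistic
is *insensitive to a small number of strong signals*. If 3 genes of a
15-gene set carry near-zero p-values and the rest are null, the
observed median is the 5th order statistic of the 12 null genes
(≈ Beta(5, 8), mean 0.385) while the permutation null median is
≈ Beta(8, 8) (mean 0.5, SD 0.12); the test's power at α = 0.05 is then
only ≈ pbeta(qbeta(0.05, 8, 8), 5, 8) ≈ 0.3. The test is designed to
detect *broad* enrichment across a set, and roughly a third to half of
the set must carry signal before power becomes high. The acceptance
suite measures this honestly.

## The synthetic biobank generator

`simulate_cohort()` draws covariates (sex, birth year, ten synthetic
PCs), correlated PGSs from a user-supplied positive-definite trait
correlation, background genotypes as phased haplotypes under
Hardy–Weinberg equilibrium from a latent Gaussian AR(1) within LD
blocks (so within-block r² is tunable and blocks sit > 50 kb apart),
and independent PGx variant dosages. Each person's latent log
maintenance dose is

intercept + sex and age terms + Σ β_PGS·PGS + Σ β_PGx·dosage + N(0, σ),

and purchases realize it: the latent dose is snapped to the nearest
configured package strength (ties to the lower strength — prescribers
round down), new users start up to `titration_steps` strength levels
below target and climb one level per purchase, refill intervals equal
the days' supply at one pill per day jittered by a uniform ±20%
(`interval_jitter`, configurable because the estimator-exactness tests
need 0), purchases occasionally cover two packages
(`stockpile_prob` = 0.10), and with probability `gap_prob` = 0.04 a
purchase is followed by a > 365-day break. Defaults — 2,000 people, a
statin-like drug with 10/20/40/80 mg strengths and 30-pill packages,
planted per-SD effects of 0.05 (CHD) and 0.03 (BMI) on log dose, a
−0.25 per-allele PGx effect at frequency 0.25, residual SD 0.4, a mean
of 40 purchases per person (≈ 3.3 years' supply, so the 2-year filter
keeps nearly everyone) — are the study conditions of the bundled
analysis and of the tests, chosen once to be realistic for long-term
cardiovascular treatment.

What the generator deliberately does **not** emulate: real population
LD panels, relatedness and ancestry structure beyond the synthetic PCs,
adherence behaviour (a gap is a break in purchasing, not a model of
intake), combination products, or long-acting injectables (a
configuration hook exists, no conversion tables ship). Passing tests on
this generator therefore demonstrate algorithmic correctness and
statistical calibration under a known truth, not robustness to every
artefact of real registry data. Two quantitative consequences worth
knowing: snapping to discrete strengths attenuates planted effects
toward the nearest level, so recovery tests either use continuous
strengths or compare against 2-SE bands; and the refill jitter puts a
multiplicative ±20% error on individual daily-dose estimates that the
within-batch median largely, but not exactly, removes.

## Numerical choices and degenerate inputs

- Dates are ISO-8601 throughout; all genomic coordinates are 1-based
  inclusive in memory, and BED files are converted at the boundary.
- A constant dose series has log-SD 0 and the 3-SD filter excludes
  nothing; a constant response makes Box-Cox selection warn and skip;
  a constant binary outcome or a zero-variance PGS trait is an error.
- Monomorphic variants are skipped by the scan with a log entry;
  complete separation in the logistic fit is flagged, not hidden.
- Rank-deficient OLS designs error out naming the aliased columns
  rather than silently dropping them.
- One global seed fans out to named per-stage seeds (`stage_seed()`),
  so a rerun of any single stage reproduces its part of a full run.

## Problem sizes

The test suite and the acceptance script run the dose oracle on 1,000
random purchase histories, the null-calibration and power checks on
200 simulated gene sets with 2,000 permutations each, CI coverage on
200 regression replicates, and planted-variant scans at n = 2,000 with
a few hundred variants — sizes at which every distributional claim the
package makes is measurable in minutes on one CPU. The bundled
analysis scripts use the generator defaults above.
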