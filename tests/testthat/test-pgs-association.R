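# PGS association machinery: standardization contract, Bonferroni
# thresholds, Box-Cox check, the three model fitters, forward stepwise
# selection, and the variance partition.

test_that("PGS standardization uses reference moments and is affine-invariant", {
  set.seed(1)
  raw <- matrix(rnorm(200, mean = 5, sd = 3), 100, 2,
                dimnames = list(sprintf("S%05d", 1:100), c("A", "B")))
  z <- standardize_pgs(raw)
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))

  # a subset keeps the reference moments, so its own mean is generally != 0
  sub_ids <- rownames(raw)[1:30]
  z_sub <- standardize_pgs(raw, reference_ids = rownames(raw))[sub_ids, ]
  expect_equal(z_sub, z[sub_ids, ])
  expect_false(isTRUE(all.equal(colMeans(z_sub), c(A = 0, B = 0))))

  # affine rescaling of the raw scores leaves Z-scores unchanged
  z2 <- standardize_pgs(raw * 7 - 100)
  expect_equal(z2, z)

  const <- raw; const[, 2] <- 1
  expect_error(standardize_pgs(const), "zero-variance")
})

test_that("Bonferroni threshold is alpha over the number of scores", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(round(bonferroni_threshold(11), 4), 0.0045)
  expect_equal(round(bonferroni_threshold(12), 3), 0.004)
  expect_error(bonferroni_threshold(0), "at least 1")
})

test_that("Box-Cox profile selects log for log-normal and ~1 for normal data", {
  set.seed(2)
  ln <- exp(rnorm(1000, 1, 0.6))
  sel <- boxcox_select(ln)
  expect_lt(abs(sel$lambda_hat), 0.15)
  expect_equal(sel$transform, "log")

  nm <- rnorm(1000, 50, 5)
  sel2 <- boxcox_select(nm)
  expect_lt(abs(sel2$lambda_hat - 1), 0.5)

  expect_warning(sel3 <- boxcox_select(rep(2, 10)), "constant")
  expect_true(sel3$skipped)
})

test_that("linear median-dose fit recovers a planted per-SD effect", {
  set.seed(3)
  d <- sim_median_data(2000, beta_pgs = c(CHD = 0.08, BMI = 0))
  res <- fit_linear_median(d$summaries, d$covariates, d$pgs,
                           pgs_terms = c("CHD", "BMI"))
  chd <- res[term == "CHD"]
  expect_lt(abs(chd$beta - 0.08), 2 * chd$se)
  expect_gt(res[term == "BMI", p], 0.001)

  # duplicate model term is rejected
  expect_error(fit_linear_median(d$summaries, d$covariates, d$pgs,
                                 pgs_terms = c("CHD", "CHD")), "duplicate")
})

test_that("logistic maximum-dose fit reports odds ratios per SD", {
  set.seed(4)
  n <- 5000
  cov <- sim_covariates(n)
  pgs <- sim_pgs_matrix(n, "CHD")
  eta <- -0.5 + 0.15 * pgs[, "CHD"]
  y <- rbinom(n, 1, plogis(eta))
  summ <- data.table::data.table(person_id = cov$person_id, max_dose_binary = y)
  res <- fit_logistic_max(summ, cov, pgs, pgs_terms = "CHD")
  chd <- res[term == "CHD"]
  expect_lt(abs(chd$beta - 0.15), 2 * chd$se)
  expect_equal(chd$or, exp(chd$beta))
  expect_true(chd$ci_low < chd$or & chd$or < chd$ci_high)

  summ0 <- data.table::copy(summ)[, max_dose_binary := 1L]
  expect_error(fit_logistic_max(summ0, cov, pgs, pgs_terms = "CHD"), "constant")
})

test_that("daily-dose mixed model recovers a planted effect and flags singular fits", {
  set.seed(5)
  n <- 300; k <- 8
  cov <- sim_covariates(n)
  pgs <- sim_pgs_matrix(n, "CHD")
  ids <- rep(cov$person_id, each = k)
  tt <- rep(seq(0, 3.5, length.out = k), n)
  u0 <- rnorm(n, 0, 0.3)[rep(1:n, each = k)]
  u1 <- rnorm(n, 0, 0.08)[rep(1:n, each = k)]
  eta <- 3 + 0.05 * pgs[ids, "CHD"] + 0.03 * tt + u0 + u1 * tt +
    rnorm(n * k, 0, 0.25)
  obs <- data.table::data.table(person_id = ids, daily_dose = exp(eta),
                                years_since_first = tt,
                                age_at_purchase = 55 + tt)
  res <- fit_lmm_daily(obs, cov, pgs, pgs_terms = "CHD",
                       fixed_covariates = c("sex", "years_since_first"))
  chd <- res[term == "CHD"]
  expect_lt(abs(chd$beta - 0.05), 2.5 * chd$se)
  expect_equal(chd$model_tag, "lmm_ri_rs")
  expect_equal(unique(res$n_persons), n)

  # no random slope in truth: the intercept-only refit path engages
  eta2 <- 3 + u0 + rnorm(n * k, 0, 0.25)
  obs2 <- data.table::copy(obs)[, daily_dose := exp(eta2)]
  res2 <- fit_lmm_daily(obs2, cov, pgs, pgs_terms = "CHD",
                        fixed_covariates = c("sex", "years_since_first"))
  expect_equal(unique(res2$model_tag), "lmm_ri_only")
})

test_that("with one observation per person the LMM fixed effects match OLS", {
  set.seed(6)
  d <- sim_median_data(400, beta_pgs = c(CHD = 0.1))
  obs <- data.table::data.table(person_id = d$summaries$person_id,
                                daily_dose = d$summaries$median_dose,
                                years_since_first = 0,
                                age_at_purchase = 50)
  # the Hessian is flat in the intercept-variance direction here; the
  # optimizer warnings are expected and harmless for the fixed effects
  lmm <- suppressWarnings(
    fit_lmm_daily(obs, d$covariates, d$pgs, pgs_terms = "CHD",
                  fixed_covariates = "sex"))
  ols <- fit_linear_median(d$summaries, d$covariates, d$pgs,
                           pgs_terms = "CHD", fixed_covariates = "sex")
  expect_equal(lmm[term == "CHD", beta], ols[term == "CHD", beta],
               tolerance = 1e-4)
})

test_that("forward stepwise matches the plain greedy oracle and prunes proxies", {
  set.seed(7)
  d <- sim_median_data(1500, beta_pgs = c(CHD = 0.1, BMI = 0.06, EA = 0,
                                          SBP = 0))
  fitter <- function(terms) fit_linear_median(d$summaries, d$covariates,
                                              d$pgs, pgs_terms = terms)
  thr <- bonferroni_threshold(4)
  sw <- forward_stepwise(fitter, colnames(d$pgs), thr)
  expect_identical(sw$selected, oracle_stepwise(fitter, colnames(d$pgs), thr))
  expect_true(all(c("CHD", "BMI") %in% sw$selected))
  expect_false(any(c("EA", "SBP") %in% sw$selected))
  # single-score results cover every candidate
  expect_setequal(sw$single$candidate, colnames(d$pgs))

  # two highly correlated proxies of one signal: only one enters
  set.seed(8)
  d2 <- sim_median_data(1500, beta_pgs = c(CHD = 0.1, BMI = 0), rho = 0.95)
  fitter2 <- function(terms) fit_linear_median(d2$summaries, d2$covariates,
                                               d2$pgs, pgs_terms = terms)
  sw2 <- forward_stepwise(fitter2, c("CHD", "BMI"), bonferroni_threshold(2))
  expect_equal(length(sw2$selected), 1L)
})

test_that("variance partition shows the pharmacogene-dominant pattern", {
  set.seed(9)
  d <- sim_median_data(1500, beta_pgs = c(BMI = 0.02), noise_sd = 0.25,
                       pgx_beta = -0.4)
  pgs_z <- standardize_pgs(d$pgs)
  pgx_z <- scale(d$pgx)
  vp <- variance_partition(d$summaries, d$covariates, pgs_z, pgx_z)
  tab <- vp$table
  r2 <- setNames(tab$adj_r2, tab$model)
  # adding the PGx variant moves adjusted R^2 a lot; PGS alone adds little
  expect_gt(r2[["base_pgx"]] - r2[["base"]], 0.2)
  expect_lt(r2[["base_pgs"]] - r2[["base"]], 0.05)
  expect_lt(abs(r2[["full"]] - r2[["base_pgx"]]), 0.05)
  # unadjusted R^2 is monotone across the nesting chain i -> ii -> iv
  expect_true(tab[model == "base_pgx", r2] >= tab[model == "base", r2])
  expect_true(tab[model == "full", r2] >= tab[model == "base_pgx", r2])
  expect_true(tab[model == "full", r2] >= tab[model == "base_pgs", r2])

  # pure-noise outcome: all adjusted R^2 near zero
  set.seed(10)
  d0 <- sim_median_data(800, beta_pgs = c(BMI = 0), noise_sd = 0.5,
                        pgx_beta = 0)
  d0$summaries$median_dose <- exp(rnorm(800, 3, 0.5))
  vp0 <- variance_partition(d0$summaries, d0$covariates,
                            standardize_pgs(d0$pgs), scale(d0$pgx))
  expect_true(all(abs(vp0$table$adj_r2) < 0.03))
})
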