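# Per-variant scan: MAF/info filters, the Blom inverse normal
# transform, exact agreement with a direct normal-equations solution,
# planted-variant power, and the conditioning behaviour.

test_that("variant filter keeps MAF >= 0.5% and info >= 0.8, boundaries inclusive", {
  vi <- data.table::data.table(
    variant_id = c("a", "b", "c", "d"),
    maf = c(0.004, 0.10, 0.005, 0.3),
    info = c(0.99, 0.79, 0.80, 0.95))
  kept <- variant_filter(vi)
  expect_setequal(kept$variant_id, c("c", "d"))
})

test_that("inverse normal transform follows the Blom formula with average ranks", {
  # n = 3 distinct values: (r - 3/8) / (3 + 1/4)
  out <- inverse_normal_transform(c(5, 1, 9))
  expect_equal(out, qnorm((c(2, 1, 3) - 0.375) / 3.25))
  expect_equal(out[2], qnorm(0.625 / 3.25))

  # invariant under monotone transforms of the input
  set.seed(1)
  x <- rexp(50)
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(log(x)))

  # ties share the average rank and so the same transformed value
  tied <- inverse_normal_transform(c(1, 2, 2, 4))
  expect_equal(tied[2], tied[3])

  # output bounded by the extreme Blom quantiles
  n <- 200
  y <- inverse_normal_transform(rnorm(n))
  expect_true(all(abs(y) <= abs(qnorm((1 - 0.375) / (n + 0.25)))))

  expect_error(inverse_normal_transform(rep(3, 5)), "constant")
})

mk_scan_data <- function(n = 400, m = 12, beta = 0, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%05d", seq_len(n))
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(ids, sprintf("v%02d", seq_len(m))))
  cov <- data.table::data.table(person_id = ids, sex = rbinom(n, 1, 0.5),
                                age = rnorm(n, 50, 8))
  y <- 0.3 * cov$sex + 0.01 * cov$age + beta * G[, 1] + rnorm(n)
  vi <- data.table::data.table(variant_id = colnames(G), chromosome = "1",
                               position = seq_len(m) * 1000L,
                               maf = 0.3, info = 0.99)
  list(y = setNames(y, ids), G = G, cov = cov, vi = vi)
}

test_that("linear scan equals the direct normal-equations solution", {
  d <- mk_scan_data(n = 50, m = 8, beta = 0.2, seed = 2)
  res <- gwas_scan(d$y, d$G, d$cov, d$vi, family = "linear")
  for (v in res$variant_id) {
    X <- cbind(1, d$cov$sex, d$cov$age, d$G[, v])
    bh <- solve(crossprod(X), crossprod(X, d$y))
    r <- d$y - X %*% bh
    s2 <- sum(r^2) / (nrow(X) - ncol(X))
    seh <- sqrt(s2 * solve(crossprod(X))[4, 4])
    row <- res[variant_id == v]
    expect_equal(row$beta, bh[4], tolerance = 1e-8)
    expect_equal(row$se, seh, tolerance = 1e-8)
    tv <- bh[4] / seh
    expect_equal(row$p, 2 * pt(-abs(tv), nrow(X) - ncol(X)), tolerance = 1e-8)
  }
})

test_that("a covariate orthogonal to genotype leaves scan betas unchanged", {
  d <- mk_scan_data(n = 200, m = 6, beta = 0.15, seed = 3)
  res1 <- gwas_scan(d$y, d$G, d$cov, d$vi, family = "linear")
  # residualize a new covariate against genotype and existing covariates
  z <- rnorm(200)
  z_orth <- resid(lm(z ~ d$cov$sex + d$cov$age + d$G))
  cov2 <- data.table::copy(d$cov)[, extra := z_orth]
  res2 <- gwas_scan(d$y, d$G, cov2, d$vi, family = "linear")
  expect_equal(res1$beta, res2$beta, tolerance = 1e-10)
})

test_that("a planted variant reaches genome-wide significance and nulls stay flat", {
  n <- 2000
  set.seed(4)
  ids <- sprintf("S%05d", seq_len(n))
  m <- 60
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(ids, sprintf("v%02d", seq_len(m))))
  # ~10% of phenotype variance from the causal variant
  y <- setNames(0.5 * G[, 1] + rnorm(n), ids)
  cov <- data.table::data.table(person_id = ids, sex = rbinom(n, 1, 0.5))
  vi <- data.table::data.table(variant_id = colnames(G), chromosome = "1",
                               position = seq_len(m) * 1000L, maf = 0.3,
                               info = 0.99)
  res <- gwas_scan(y, G, cov, vi, family = "linear")
  expect_lt(res[variant_id == "v01", p], 5e-8)
  # null p-values roughly uniform: genomic inflation near 1
  null_p <- res[variant_id != "v01", p]
  lambda <- median(qchisq(1 - null_p, 1)) / qchisq(0.5, 1)
  expect_lt(abs(lambda - 1), 0.35)
})

test_that("conditioning on the causal variant silences its proxies", {
  n <- 1500
  sim <- simulate_ld_blocks(n, 10, block_size = 5, rho = 0.97, maf = 0.3,
                            seed = 5)
  ids <- rownames(sim$dosages)
  causal <- "var0003"
  y <- setNames(0.45 * sim$dosages[, causal] + rnorm(n), ids)
  cov <- data.table::data.table(person_id = ids,
                                sex = rbinom(n, 1, 0.5))
  vi <- data.table::copy(sim$info)[, info := 0.99]
  res <- gwas_scan(y, sim$dosages, cov, vi, family = "linear")
  proxies <- setdiff(sim$info[block == 1, variant_id], causal)
  expect_true(any(res[variant_id %in% proxies, p] < 5e-8))

  cond <- gwas_scan(y, sim$dosages, cov, vi, family = "linear",
                    condition_on = causal)
  expect_false(causal %in% cond$variant_id)
  expect_true(all(cond[variant_id %in% proxies, p] > 1e-4))
  expect_match(unique(cond$model_tag), "cond")
})

test_that("logistic scan recovers a planted log-odds effect", {
  n <- 3000
  set.seed(6)
  ids <- sprintf("S%05d", seq_len(n))
  G <- matrix(rbinom(n * 4, 2, 0.3), n, 4,
              dimnames = list(ids, paste0("v", 1:4)))
  y <- setNames(rbinom(n, 1, plogis(-0.4 + 0.4 * G[, 2])), ids)
  cov <- data.table::data.table(person_id = ids, sex = rbinom(n, 1, 0.5))
  vi <- data.table::data.table(variant_id = colnames(G), chromosome = "1",
                               position = 1:4 * 1000L, maf = 0.3, info = 0.99)
  res <- gwas_scan(y, G, cov, vi, family = "logistic")
  v2 <- res[variant_id == "v2"]
  expect_lt(abs(v2$beta - 0.4), 2.5 * v2$se)
  # agreement with stats::glm
  fit <- glm(y ~ sex + g, data = data.frame(y = y, sex = cov$sex, g = G[, 2]),
             family = binomial())
  expect_equal(v2$beta, unname(coef(fit)["g"]), tolerance = 1e-6)
})

test_that("the Manhattan table lays chromosomes end to end", {
  res <- data.table::data.table(
    variant_id = c("a", "b", "c"), chromosome = c("1", "1", "2"),
    position = c(100L, 200L, 50L), p = c(0.5, 5e-8, 1e-9))
  mt <- manhattan_table(res, gap_bp = 1000)
  expect_equal(mt$neg_log10_p[2], -log10(5e-8), tolerance = 1e-12)
  expect_false(mt$significant[2])  # boundary: strictly below 5e-8
  expect_true(mt$significant[3])
  expect_true(all(diff(mt[chromosome == "1", cum_pos]) > 0))
  expect_gt(mt[chromosome == "2", cum_pos], max(mt[chromosome == "1", cum_pos]))
})
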