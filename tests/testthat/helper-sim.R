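# Small person-level simulators used by the association tests: outcome
# models built directly from their definitions (not via the purchase
# generator), so model fits can be checked against known coefficients.

sim_covariates <- function(n) {
  data.table::data.table(
    person_id = sprintf("S%05d", seq_len(n)),
    sex = stats::rbinom(n, 1, 0.5),
    birth_year = sample(1940:1985, n, replace = TRUE),
    treatment_length_years = stats::runif(n, 2, 10))[
      , (paste0("PC", 1:10)) := lapply(1:10, function(i) stats::rnorm(n))][]
}

sim_pgs_matrix <- function(n, traits = c("CHD", "BMI"), rho = 0) {
  k <- length(traits)
  S <- matrix(rho, k, k); diag(S) <- 1
  m <- matrix(stats::rnorm(n * k), n) %*% chol(S)
  dimnames(m) <- list(sprintf("S%05d", seq_len(n)), traits)
  m
}

# log median dose = intercept + small covariate effects + planted PGS /
# PGx effects + noise
sim_median_data <- function(n, beta_pgs = c(CHD = 0.05, BMI = 0),
                            rho = 0, noise_sd = 0.5, pgx_beta = NULL,
                            pgx_freq = 0.3) {
  cov <- sim_covariates(n)
  pgs <- sim_pgs_matrix(n, names(beta_pgs), rho)
  eta <- 3 + 0.05 * cov$sex + 0.002 * (cov$birth_year - 1960) +
    0.01 * cov$treatment_length_years + as.numeric(pgs %*% beta_pgs)
  pgx <- NULL
  if (!is.null(pgx_beta)) {
    pgx <- matrix(stats::rbinom(n, 2, pgx_freq), ncol = 1,
                  dimnames = list(cov$person_id, "pgx1"))
    eta <- eta + pgx_beta * pgx[, 1]
  }
  summaries <- data.table::data.table(
    person_id = cov$person_id,
    median_dose = exp(eta + stats::rnorm(n, 0, noise_sd)))
  list(summaries = summaries, covariates = cov, pgs = pgs, pgx = pgx,
       eta = eta)
}

# independent plain-loop version of the greedy forward selection
oracle_stepwise <- function(fitter, candidates, threshold) {
  chosen <- character(0)
  left <- candidates
  while (length(left) > 0) {
    pvals <- rep(NA_real_, length(left))
    for (i in seq_along(left)) {
      res <- fitter(c(chosen, left[i]))
      pvals[i] <- res$p[res$term == left[i]]
    }
    i_best <- which.min(pvals)
    if (pvals[i_best] < threshold) {
      chosen <- c(chosen, left[i_best])
      left <- left[-i_best]
    } else break
  }
  chosen
}
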