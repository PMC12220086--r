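# Association of dose phenotypes with polygenic scores:
# reference-population Z-standardization, Box-Cox check, linear mixed
# model for daily doses, OLS for median dose, logistic for maximum dose,
# forward stepwise selection, and the PGS-vs-PGx variance partition.

#' Standardize polygenic scores in a reference population
#'
#' Each trait column is centred and scaled using the mean and SD of the
#' reference population; analysis subsets are extracted afterwards, so a
#' subset's scores generally do not have mean 0 / SD 1.
#'
#' @param raw_scores matrix or data.frame, persons in rows (rownames =
#'   person ids), traits in columns.
#' @param reference_ids person ids defining the reference population;
#'   default all rows.
#' @return numeric matrix of Z-scores with the same dimnames.
#' @export
standardize_pgs <- function(raw_scores, reference_ids = rownames(raw_scores)) {
  x <- as.matrix(raw_scores)
  if (is.null(rownames(x))) stop("raw_scores must have person ids as rownames")
  miss <- setdiff(reference_ids, rownames(x))
  if (length(miss)) stop("reference ids absent from scores: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  ref <- x[reference_ids, , drop = FALSE]
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance trait(s): ",
         paste(colnames(x)[sdv == 0], collapse = ", "))
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of scores tested for one medication.
#' @param alpha family-wise error rate (default 0.05).
#' @return per-test threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}

#' Box-Cox transformation check for a positive response
#'
#' Profiles the Box-Cox likelihood over a lambda grid for the
#' intercept-only model. The pipeline models log dose throughout; this
#' reports whether the data support that choice (lambda CI covering 0).
#'
#' @param values positive response values.
#' @param lambda_grid grid of lambda values to profile.
#' @return list with `lambda_hat`, `ci` (95% profile interval),
#'   `transform` ("log" when the CI covers 0, otherwise "power"), and
#'   `skipped` (TRUE for degenerate constant input).
#' @export
boxcox_select <- function(values, lambda_grid = seq(-2, 2, by = 0.02)) {
  if (any(values <= 0)) stop("Box-Cox requires strictly positive values")
  if (stats::sd(values) == 0) {
    warning("constant response; Box-Cox selection skipped")
    return(list(lambda_hat = NA_real_, ci = c(NA_real_, NA_real_),
                transform = NA_character_, skipped = TRUE))
  }
  bc <- MASS::boxcox(values ~ 1, lambda = lambda_grid, plotit = FALSE)
  lambda_hat <- bc$x[which.max(bc$y)]
  cutoff <- max(bc$y) - stats::qchisq(0.95, 1) / 2
  in_ci <- bc$x[bc$y >= cutoff]
  ci <- range(in_ci)
  list(lambda_hat = lambda_hat, ci = ci,
       transform = if (ci[1] <= 0 && ci[2] >= 0) "log" else "power",
       skipped = FALSE)
}

# assemble a model frame from outcome table + covariates + PGS matrix
build_frame <- function(tab, covariates, pgs = NULL, pgs_terms = character()) {
  dt <- merge(as_dt(tab), as_dt(covariates), by = "person_id", sort = FALSE)
  if (length(pgs_terms)) {
    if (is.null(pgs)) stop("PGS terms requested but no PGS matrix supplied")
    miss <- setdiff(pgs_terms, colnames(pgs))
    if (length(miss)) stop("unknown PGS term(s): ", paste(miss, collapse = ", "))
    dt <- cbind(dt, as.data.frame(pgs[dt$person_id, pgs_terms, drop = FALSE]))
  }
  dt
}

result_row <- function(term, est, se, p, model_tag, n_obs, n_persons,
                       link = "identity") {
  z <- stats::qnorm(0.975)
  data.table::data.table(
    term = term, beta = est, se = se, p = p,
    ci_low = if (link == "logit") exp(est - z * se) else est - z * se,
    ci_high = if (link == "logit") exp(est + z * se) else est + z * se,
    or = if (link == "logit") exp(est) else NA_real_,
    model_tag = model_tag, n_obs = n_obs, n_persons = n_persons)
}

#' Linear mixed model for daily doses
#'
#' Fits natural-log daily dose on fixed covariates and PGS terms with a
#' per-person random intercept and random slope on years since first
#' purchase (unstructured covariance), by REML with the BOBYQA
#' optimizer. Wald z tests per fixed term. A singular random-effects fit
#' triggers an intercept-only refit, flagged in `model_tag`.
#'
#' @param observations daily-dose observations (after the 3-SD log
#'   filter) with `person_id`, `daily_dose`, `years_since_first`,
#'   `age_at_purchase`.
#' @param covariates per-person covariates (`person_id`, `sex`, PCs,
#'   optional extras).
#' @param pgs standardized PGS matrix (rownames person ids) or NULL.
#' @param pgs_terms PGS columns to include as fixed effects.
#' @param fixed_covariates names of fixed covariate columns; defaults to
#'   sex, age at purchase, years since first purchase and PC1..PC10.
#' @return data.table of per-term results (see [result_row] fields).
#' @export
fit_lmm_daily <- function(observations, covariates, pgs = NULL,
                          pgs_terms = character(),
                          fixed_covariates = c("sex", "age_at_purchase",
                                               "years_since_first",
                                               paste0("PC", 1:10))) {
  dt <- build_frame(observations, covariates, pgs, pgs_terms)
  dt[, log_dose := log(daily_dose)]
  rhs <- paste(c(fixed_covariates, pgs_terms), collapse = " + ")
  form <- stats::as.formula(paste("log_dose ~", rhs,
                                  "+ (1 + years_since_first | person_id)"))
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            check.conv.singular = lme4::.makeCC(action = "ignore",
                                                                tol = 1e-4),
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- lme4::lmer(form, data = dt, REML = TRUE, control = ctrl)
  tag <- "lmm_ri_rs"
  if (lme4::isSingular(fit, tol = 1e-4)) {
    form2 <- stats::as.formula(paste("log_dose ~", rhs, "+ (1 | person_id)"))
    fit <- lme4::lmer(form2, data = dt, REML = TRUE, control = ctrl)
    tag <- "lmm_ri_only"
  }
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  result_row(rownames(co), est, se, p, tag, nrow(dt),
             data.table::uniqueN(dt$person_id))
}

#' Linear regression for log median dose
#'
#' Ordinary least squares of natural-log median dose on covariates and
#' PGS terms; Wald t tests. Persons are expected to have passed the
#' 2-year treatment-length and 3-SD log-outlier filters upstream.
#'
#' @inheritParams fit_lmm_daily
#' @param summaries per-person table with `person_id`, `median_dose`.
#' @param fixed_covariates default sex, birth year, treatment length and
#'   PC1..PC10.
#' @return data.table of per-term results.
#' @export
fit_linear_median <- function(summaries, covariates, pgs = NULL,
                              pgs_terms = character(),
                              fixed_covariates = c("sex", "birth_year",
                                                   "treatment_length_years",
                                                   paste0("PC", 1:10))) {
  dt <- build_frame(summaries, covariates, pgs, pgs_terms)
  dt[, log_dose := log(median_dose)]
  terms <- c(fixed_covariates, pgs_terms)
  dup <- terms[duplicated(terms)]
  if (length(dup)) stop("duplicate model term(s): ", paste(dup, collapse = ", "))
  form <- stats::as.formula(paste("log_dose ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(form, data = dt)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; aliased column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  co <- summary(fit)$coefficients
  result_row(rownames(co), co[, 1], co[, 2], co[, 4], "ols_median",
             nrow(dt), nrow(dt))
}

#' Logistic regression for the binary maximum dose
#'
#' Maximum-likelihood logistic fit; odds ratios with 95% CIs per SD of
#' PGS. Complete separation is flagged in `model_tag`.
#'
#' @inheritParams fit_linear_median
#' @param summaries per-person table with `person_id`, `max_dose_binary`.
#' @return data.table of per-term results (`or`, `ci_low`, `ci_high` on
#'   the odds-ratio scale).
#' @export
fit_logistic_max <- function(summaries, covariates, pgs = NULL,
                             pgs_terms = character(),
                             fixed_covariates = c("sex", "birth_year",
                                                  "treatment_length_years",
                                                  paste0("PC", 1:10))) {
  dt <- build_frame(summaries, covariates, pgs, pgs_terms)
  if (data.table::uniqueN(dt$max_dose_binary) < 2L)
    stop("maximum-dose outcome is constant; not analyzable")
  terms <- c(fixed_covariates, pgs_terms)
  form <- stats::as.formula(paste("max_dose_binary ~",
                                  paste(terms, collapse = " + ")))
  tag <- "logistic_max"
  withCallingHandlers(
    fit <- stats::glm(form, data = dt, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        tag <<- "logistic_max_separation"
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  result_row(rownames(co), co[, 1], co[, 2], co[, 4], tag,
             nrow(dt), nrow(dt), link = "logit")
}

#' Forward stepwise selection of polygenic scores
#'
#' Each candidate is first modelled individually. Selection then
#' proceeds greedily: at each round every remaining candidate is added
#' to the current model, the one with the smallest conditional p-value
#' is selected if that p-value is below the threshold, and the process
#' repeats until no remaining candidate passes.
#'
#' @param fitter function(pgs_terms) returning a per-term result table
#'   (any of the three model fitters, partially applied).
#' @param candidates character vector of candidate PGS term names.
#' @param threshold Bonferroni-corrected entry threshold, from
#'   [bonferroni_threshold()].
#' @return list with `single` (one-at-a-time results), `selected`
#'   (terms in entry order), `final` (joint-model result table, NULL if
#'   nothing selected), and `trace` (per-round candidate p-values).
#' @export
forward_stepwise <- function(fitter, candidates, threshold) {
  if (!length(candidates)) stop("no candidate terms supplied")
  single <- data.table::rbindlist(lapply(candidates, function(cand) {
    res <- fitter(cand)
    res[term == cand][, candidate := cand]
  }))
  selected <- character()
  remaining <- candidates
  trace <- list()
  repeat {
    if (!length(remaining)) break
    ps <- vapply(remaining, function(cand) {
      res <- fitter(c(selected, cand))
      res[term == cand, p]
    }, numeric(1))
    trace[[length(trace) + 1L]] <-
      data.table::data.table(round = length(selected) + 1L,
                             candidate = remaining, p = ps)
    best <- which.min(ps)
    if (ps[best] < threshold) {
      selected <- c(selected, remaining[best])
      remaining <- remaining[-best]
    } else break
  }
  final <- if (length(selected)) fitter(selected) else NULL
  list(single = single, selected = selected, final = final,
       trace = data.table::rbindlist(trace))
}

#' Variance partition across nested PGS / PGx models
#'
#' Four nested OLS fits of log median dose: (i) base covariates only,
#' (ii) base + PGx variant dosages, (iii) base + PGSs, (iv) base + both.
#' Genetic predictors are expected as Z-scores. Reports adjusted and
#' unadjusted R-squared per model.
#'
#' @param summaries per-person table with `person_id`, `median_dose`.
#' @param covariates base covariates table.
#' @param pgs_z matrix of standardized PGSs (columns = selected scores).
#' @param pgx_z matrix of standardized PGx variant dosages.
#' @param fixed_covariates base covariate columns.
#' @return list with `table` (model, r2, adj_r2, p_terms) and the four
#'   fitted model summaries' coefficient tables.
#' @export
variance_partition <- function(summaries, covariates, pgs_z, pgx_z,
                               fixed_covariates = c("sex", "birth_year",
                                                    "treatment_length_years",
                                                    paste0("PC", 1:10))) {
  dt <- merge(as_dt(summaries), as_dt(covariates), by = "person_id",
              sort = FALSE)
  pgs_z <- as.matrix(pgs_z); pgx_z <- as.matrix(pgx_z)
  dt <- cbind(dt, as.data.frame(pgs_z[dt$person_id, , drop = FALSE]),
              as.data.frame(pgx_z[dt$person_id, , drop = FALSE]))
  dt$log_dose <- log(dt$median_dose)
  models <- list(base = fixed_covariates,
                 base_pgx = c(fixed_covariates, colnames(pgx_z)),
                 base_pgs = c(fixed_covariates, colnames(pgs_z)),
                 full = c(fixed_covariates, colnames(pgx_z), colnames(pgs_z)))
  fits <- lapply(models, function(tm) {
    if (nrow(dt) <= length(tm) + 1L)
      stop("too few observations for ", length(tm), " predictors")
    stats::lm(stats::as.formula(paste("log_dose ~", paste(tm, collapse = " + "))),
              data = dt)
  })
  tab <- data.table::rbindlist(lapply(names(fits), function(nm) {
    s <- summary(fits[[nm]])
    data.table::data.table(model = nm, r2 = s$r.squared,
                           adj_r2 = s$adj.r.squared,
                           p_terms = length(stats::coef(fits[[nm]])) - 1L,
                           n = nrow(dt))
  }))
  list(table = tab,
       coefficients = lapply(fits, function(f) summary(f)$coefficients))
}
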