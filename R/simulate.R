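# Synthetic biobank generator. Emulates the statistical structure of
# longitudinal dispensing data linked to genotypes: discrete package
# strengths, titration toward a latent maintenance dose, refill-interval
# jitter, stockpiling, treatment gaps > 365 days, planted polygenic
# effects on log dose, and large-effect pharmacogene variants. Every
# planted coefficient is recorded so downstream recovery is testable.

#' Simulation configuration
#'
#' Defaults define the study conditions used by the analysis drivers
#' and tests: a statin-like drug with discrete package strengths, three
#' correlated polygenic scores with modest planted effects on log daily
#' dose, one large-effect pharmacogene variant, moderate residual noise,
#' and realistic purchase behaviour (20% refill jitter, occasional
#' stockpiling and treatment breaks).
#'
#' @param n_individuals cohort size.
#' @param n_variants number of background variants (in LD blocks).
#' @param n_chromosomes chromosomes the background variants span.
#' @param drugs list of drug definitions: each a list with `drug_code`,
#'   `strengths` (available package strengths in mg, or NULL for
#'   continuous dosing), `pills_per_package`, `rx_code` (main diagnosis
#'   written on prescriptions).
#' @param ddd_factors data.frame `drug_code`, `mg_per_ddd`.
#' @param pgs_traits trait names.
#' @param pgs_cor trait correlation matrix (symmetric positive
#'   definite).
#' @param beta_pgs named vector: effect on log dose (log-mg/day per PGS
#'   SD).
#' @param pgx_variants data.frame `variant_id`, `freq`, `beta`
#'   (log-mg/day per allele), `gene_id`.
#' @param noise_sd SD of residual log dose.
#' @param gap_prob probability a purchase is followed by a > 365-day
#'   treatment break.
#' @param stockpile_prob probability a purchase covers 2 packages.
#' @param titration_steps dose-escalation opportunities: new users start
#'   up to this many strength levels below their latent dose and climb
#'   one level per purchase.
#' @param interval_jitter uniform relative jitter of refill intervals
#'   (default 0.2, i.e. +/-20%).
#' @param n_purchases_mean mean purchases per person (minimum 6 always
#'   drawn).
#' @param block_size,block_rho LD-block size (SNVs) and within-block
#'   haplotype autocorrelation for background variants.
#' @param sex_beta,age_beta fixed demographic effects on log dose.
#' @param n_set_null_genes background genes added to each drug's PGx
#'   gene set (so pruned sets reach testable size).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_individuals = 2000,
                              n_variants = 400,
                              n_chromosomes = 2,
                              drugs = list(list(drug_code = "C10AA05",
                                                strengths = c(10, 20, 40, 80),
                                                pills_per_package = 30,
                                                rx_code = "E78")),
                              ddd_factors = data.frame(drug_code = "C10AA05",
                                                       mg_per_ddd = 20),
                              pgs_traits = c("CHD", "BMI", "EA"),
                              pgs_cor = matrix(c(1, 0.25, -0.1,
                                                 0.25, 1, -0.2,
                                                 -0.1, -0.2, 1), 3, 3),
                              beta_pgs = c(CHD = 0.05, BMI = 0.03, EA = 0),
                              pgx_variants = data.frame(variant_id = "rs_pgx1",
                                                        freq = 0.25,
                                                        beta = -0.25,
                                                        gene_id = "PGXGENE1"),
                              noise_sd = 0.4,
                              gap_prob = 0.04,
                              stockpile_prob = 0.10,
                              titration_steps = 2,
                              interval_jitter = 0.2,
                              n_purchases_mean = 40,
                              block_size = 10,
                              block_rho = 0.8,
                              sex_beta = -0.05,
                              age_beta = -0.003,
                              n_set_null_genes = 12,
                              seed = 1L) {
  if (!length(drugs)) stop("zero drugs configured")
  dimnames(pgs_cor) <- list(pgs_traits, pgs_traits)
  if (!isSymmetric(unname(pgs_cor)))
    stop("PGS correlation matrix is not symmetric")
  ev <- eigen(pgs_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("PGS correlation matrix is not positive definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  pgx <- as_dt(pgx_variants)
  if (nrow(pgx)) {
    assert_cols(pgx, c("variant_id", "freq", "beta", "gene_id"), "pgx_variants")
    if (any(pgx$freq <= 0 | pgx$freq >= 1))
      stop("pgx allele frequencies must lie in (0,1)")
  }
  probs <- c(gap_prob, stockpile_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (interval_jitter < 0 || interval_jitter >= 1)
    stop("interval_jitter must lie in [0,1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  miss <- setdiff(names(beta_pgs), pgs_traits)
  if (length(miss)) stop("beta_pgs names unknown: ", paste(miss, collapse = ", "))
  structure(list(n_individuals = n_individuals, n_variants = n_variants,
                 n_chromosomes = n_chromosomes, drugs = drugs,
                 ddd_factors = as_dt(ddd_factors), pgs_traits = pgs_traits,
                 pgs_cor = pgs_cor, beta_pgs = beta_pgs, pgx_variants = pgx,
                 noise_sd = noise_sd, gap_prob = gap_prob,
                 stockpile_prob = stockpile_prob,
                 titration_steps = titration_steps,
                 interval_jitter = interval_jitter,
                 n_purchases_mean = n_purchases_mean,
                 block_size = block_size, block_rho = block_rho,
                 sex_beta = sex_beta, age_beta = age_beta,
                 n_set_null_genes = n_set_null_genes, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Genotype dosages with block-wise LD
#'
#' Phased haplotypes are generated under Hardy-Weinberg equilibrium from
#' a latent Gaussian AR(1) process within blocks (autocorrelation
#' `rho`), thresholded at the allele frequency, and summed to dosages.
#' Adjacent variants within a block are correlated (r-squared tunable
#' via `rho`; `rho = 1` copies the haplotype exactly for equal
#' frequencies); blocks are separated by `gap_bp` so some variant pairs
#' fall within a 50-kb pruning window and others beyond it.
#'
#' @param n_individuals people to simulate.
#' @param n_variants total variants (>= 2).
#' @param block_size variants per block.
#' @param rho within-block haplotype autocorrelation, scalar or
#'   per-block.
#' @param maf allele frequencies, scalar, length `n_variants`, or NULL
#'   to draw from Uniform(0.05, 0.5).
#' @param n_chromosomes chromosomes to spread blocks over.
#' @param spacing_bp distance between adjacent variants in a block
#'   (default 2000).
#' @param gap_bp distance between consecutive blocks (default 100000,
#'   beyond the 50-kb pruning window).
#' @param seed optional seed (omit when called inside another seeded
#'   generator).
#' @param ids optional person ids for rownames.
#' @return list with `dosages` (n x m matrix in [0,2]) and `info`
#'   (data.table `variant_id`, `chromosome`, `position`, `maf`,
#'   `block`).
#' @export
simulate_ld_blocks <- function(n_individuals, n_variants, block_size = 10,
                               rho = 0.8, maf = NULL, n_chromosomes = 1,
                               spacing_bp = 2000, gap_bp = 100000,
                               seed = NULL, ids = NULL) {
  if (n_variants < 2) stop("need at least 2 variants")
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(n_variants / block_size)
  if (length(rho) == 1L) rho <- rep(rho, n_blocks)
  if (length(rho) != n_blocks) stop("rho must be scalar or one per block")
  if (is.null(maf)) maf <- stats::runif(n_variants, 0.05, 0.5)
  if (length(maf) == 1L) maf <- rep(maf, n_variants)
  n_hap <- 2L * n_individuals
  dos <- matrix(0L, n_individuals, n_variants)
  info <- vector("list", n_blocks)
  chrom_of_block <- rep(seq_len(n_chromosomes), length.out = n_blocks)
  next_pos <- rep(1e5, n_chromosomes)
  v0 <- 0L
  for (b in seq_len(n_blocks)) {
    m <- min(block_size, n_variants - v0)
    z <- matrix(0, n_hap, m)
    z[, 1] <- stats::rnorm(n_hap)
    if (m > 1) for (j in 2:m)
      z[, j] <- rho[b] * z[, j - 1] +
        sqrt(max(0, 1 - rho[b]^2)) * stats::rnorm(n_hap)
    f <- maf[v0 + seq_len(m)]
    H <- sweep(z, 2, stats::qnorm(f), "<") + 0L
    dos[, v0 + seq_len(m)] <- H[seq_len(n_individuals), ] +
      H[n_individuals + seq_len(n_individuals), ]
    ch <- chrom_of_block[b]
    pos <- next_pos[ch] + spacing_bp * (seq_len(m) - 1L)
    next_pos[ch] <- pos[m] + gap_bp
    info[[b]] <- data.table::data.table(
      variant_id = sprintf("var%04d", v0 + seq_len(m)),
      chromosome = as.character(ch), position = as.integer(pos),
      maf = f, block = b)
    v0 <- v0 + m
  }
  info <- data.table::rbindlist(info)
  dimnames(dos) <- list(ids %||% sprintf("P%05d", seq_len(n_individuals)),
                        info$variant_id)
  list(dosages = dos, info = info)
}

snap_to_strength <- function(dose, strengths) {
  # nearest configured strength; ties go to the lower strength
  s <- sort(strengths)
  vapply(dose, function(d) {
    dist <- abs(s - d)
    s[which.min(dist)]  # which.min takes the first (lower) on ties
  }, numeric(1))
}

#' Simulate a synthetic biobank cohort
#'
#' Draws covariates, correlated polygenic scores, background genotypes
#' in LD blocks, and pharmacogene variant dosages; forms each person's
#' latent log maintenance dose as intercept + demographic terms +
#' planted PGS and PGx effects + Gaussian noise; and realizes purchase
#' histories by snapping the latent dose to the nearest package
#' strength, titrating new users upward, jittering refill intervals,
#' and inserting stockpiling and > 365-day gaps. All planted
#' coefficients are recorded in `truth`. Fully reproducible from the
#' config seed.
#'
#' @param config a [simulation_config()].
#' @return list of class `simulated_cohort`: `purchases`, `covariates`,
#'   `pgs` (person x trait matrix), `genotypes` (person x variant dosage
#'   matrix), `variant_info`, `genes`, `gene_sets`, `ddd_factors`,
#'   `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  ids <- sprintf("P%05d", seq_len(n))

  sex <- stats::rbinom(n, 1, 0.6)
  birth_year <- sample(1940:1985, n, replace = TRUE)
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(ids, paste0("PC", 1:10)))
  covariates <- data.table::data.table(person_id = ids, sex = sex,
                                       birth_year = birth_year)
  covariates <- cbind(covariates, as.data.frame(pcs))

  L <- chol(config$pgs_cor)
  pgs <- matrix(stats::rnorm(n * length(config$pgs_traits)), n) %*% L
  dimnames(pgs) <- list(ids, config$pgs_traits)

  bg <- simulate_ld_blocks(n, config$n_variants,
                           block_size = config$block_size,
                           rho = config$block_rho,
                           n_chromosomes = config$n_chromosomes, ids = ids)
  bg$info[, info := pmin(1, 0.82 + stats::rbeta(.N, 2, 8))]
  low_q <- sample(nrow(bg$info), max(1, round(0.05 * nrow(bg$info))))
  bg$info[low_q, info := stats::runif(length(low_q), 0.5, 0.799)]

  pgx <- config$pgx_variants
  if (nrow(pgx)) {
    gx <- sapply(pgx$freq, function(f)
      stats::rbinom(n, 1, f) + stats::rbinom(n, 1, f))
    colnames(gx) <- pgx$variant_id
    rownames(gx) <- ids
    pgx_pos <- max(bg$info[chromosome == "1", position]) + 2e6 +
      seq_len(nrow(pgx)) * 3e5
    pgx_info <- data.table::data.table(variant_id = pgx$variant_id,
                                       chromosome = "1",
                                       position = as.integer(pgx_pos),
                                       maf = pgx$freq, block = NA_integer_,
                                       info = 0.99)
    genotypes <- cbind(bg$dosages, gx)
    variant_info <- rbind(bg$info, pgx_info)
  } else {
    genotypes <- bg$dosages
    variant_info <- data.table::copy(bg$info)
  }

  # one gene per LD block, plus a gene around each pharmacogene variant
  genes <- variant_info[!is.na(block),
                        .(chromosome = chromosome[1],
                          start = min(position) - 1000L,
                          end = max(position) + 1000L), by = block]
  genes[, gene_id := sprintf("GENE%03d", block)][, block := NULL]
  if (nrow(pgx)) {
    pg <- variant_info[is.na(block)]
    pgx_genes <- data.table::data.table(gene_id = pgx$gene_id,
                                        chromosome = pg$chromosome,
                                        start = pg$position - 2000L,
                                        end = pg$position + 2000L)
    genes <- rbind(genes[, .(gene_id, chromosome, start, end)],
                   unique(pgx_genes))
  } else genes <- genes[, .(gene_id, chromosome, start, end)]

  null_genes <- sample(grep("^GENE", genes$gene_id, value = TRUE),
                       min(config$n_set_null_genes,
                           sum(startsWith(genes$gene_id, "GENE"))))
  gene_sets <- data.table::rbindlist(lapply(config$drugs, function(d)
    data.table::data.table(drug = d$drug_code,
                           gene_id = c(pgx$gene_id, null_genes))))

  drug_of <- sample(seq_along(config$drugs), n, replace = TRUE)
  intercepts <- vapply(config$drugs, function(d)
    log(if (is.null(d$strengths)) config$ddd_factors$mg_per_ddd[
      match(d$drug_code, config$ddd_factors$drug_code)]
      else stats::median(d$strengths)), numeric(1))

  first_offset <- sample.int(365 * 11, n, replace = TRUE) - 1L
  first_date <- as.Date("2005-01-01") + first_offset
  age_first <- as.numeric(first_date - as.Date(paste0(birth_year, "-07-01"))) / 365.25

  latent <- intercepts[drug_of] + config$sex_beta * sex +
    config$age_beta * (age_first - 60) +
    as.numeric(pgs %*% ifelse(is.na(config$beta_pgs[config$pgs_traits]), 0,
                              config$beta_pgs[config$pgs_traits]))
  if (nrow(pgx))
    latent <- latent + as.numeric(genotypes[, pgx$variant_id, drop = FALSE] %*%
                                    pgx$beta)
  latent <- latent + stats::rnorm(n, 0, config$noise_sd)

  n_pur <- 6L + stats::rpois(n, max(0, config$n_purchases_mean - 6))
  pur <- vector("list", n)
  for (i in seq_len(n)) {
    d <- config$drugs[[drug_of[i]]]
    target <- exp(latent[i])
    k <- n_pur[i]
    if (is.null(d$strengths)) {
      strength_seq <- rep(target, k)
    } else {
      s <- sort(d$strengths)
      tgt_idx <- which(s == snap_to_strength(target, s))[1]
      start_idx <- max(1L, tgt_idx - config$titration_steps)
      strength_seq <- s[pmin(start_idx + seq_len(k) - 1L, tgt_idx)]
    }
    packs <- 1L + stats::rbinom(k, 1, config$stockpile_prob)
    supply <- d$pills_per_package * packs
    jit <- stats::runif(k, -config$interval_jitter, config$interval_jitter)
    interval <- pmax(1, round(supply * (1 + jit)))
    gap <- stats::rbinom(k, 1, config$gap_prob) == 1L
    interval[gap] <- interval[gap] + 366L +
      sample.int(300L, sum(gap), replace = TRUE)
    dates <- first_date[i] + c(0, cumsum(interval[-k]))
    alt <- stats::runif(k) < 0.2
    pur[[i]] <- data.table::data.table(
      person_id = ids[i], drug_code = d$drug_code, date = dates,
      mg_per_pill = strength_seq, pills_per_package = d$pills_per_package,
      n_packages = packs,
      rx_diagnosis = ifelse(alt, "I10", d$rx_code %||% "E78"),
      age_at_purchase = as.numeric(dates - as.Date(paste0(birth_year[i], "-07-01"))) / 365.25)
  }
  purchases <- data.table::rbindlist(pur)
  data.table::setorder(purchases, person_id, date)

  if (nrow(pgx)) {
    bad <- setdiff(pgx$gene_id, genes$gene_id)
    if (length(bad)) stop("pgx gene(s) missing from annotation: ",
                          paste(bad, collapse = ", "))
  }

  structure(list(purchases = purchases, covariates = covariates, pgs = pgs,
                 genotypes = genotypes, variant_info = variant_info,
                 genes = genes, gene_sets = gene_sets,
                 ddd_factors = data.table::copy(config$ddd_factors),
                 truth = list(beta_pgs = config$beta_pgs,
                              pgx_variants = data.table::copy(pgx),
                              sex_beta = config$sex_beta,
                              age_beta = config$age_beta,
                              intercepts = intercepts,
                              noise_sd = config$noise_sd,
                              latent_log_dose = stats::setNames(latent, ids),
                              drug_assigned = stats::setNames(
                                vapply(config$drugs[drug_of], `[[`, "",
                                       "drug_code"), ids),
                              seed = config$seed)),
            class = "simulated_cohort")
}
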