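# End-to-end orchestration: synthetic cohort (or files on disk) ->
# dose phenotypes -> cohort selection -> PGS association -> per-variant
# scan -> PGx enrichment -> variance partition. Each stage writes its
# table and a manifest entry (row counts, seed) so any stage can be
# re-run and audited in isolation.

#' Pipeline run configuration
#'
#' @param output_dir directory for result tables and the manifest.
#' @param seed global seed; per-stage seeds derive from it via
#'   [stage_seed()].
#' @param simulation a [simulation_config()] (its seed is overridden by
#'   the derived stage seed) or NULL to read tables from `input_dir`.
#' @param input_dir fixture directory read with [read_fixture()] when
#'   `simulation` is NULL.
#' @param cohort a [cohort_spec()]; defaults to the standard filters.
#' @param candidate_pgs candidate PGS names for stepwise selection;
#'   default all traits in the PGS table.
#' @param alpha family-wise alpha for the Bonferroni threshold.
#' @param n_perm permutations for the enrichment stage.
#' @param min_treatment_length_years filter for median/max dose models.
#' @return a `run_config` list.
#' @export
run_config <- function(output_dir, seed = 1L, simulation = simulation_config(),
                       input_dir = NULL, cohort = NULL,
                       candidate_pgs = NULL, alpha = 0.05, n_perm = 1000,
                       min_treatment_length_years = 2) {
  if (is.null(simulation) && is.null(input_dir))
    stop("either a simulation config or an input directory is required")
  if (is.null(simulation)) {
    needed <- file.path(input_dir, c("purchases.tsv", "covariates.tsv",
                                     "pgs.tsv", "dosages.tsv",
                                     "gene_sets.tsv", "ddd_factors.tsv"))
    missing <- needed[!file.exists(needed)]
    if (length(missing))
      stop("input file(s) not found: ", paste(basename(missing), collapse = ", "))
  }
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 simulation = simulation, input_dir = input_dir,
                 cohort = cohort, candidate_pgs = candidate_pgs,
                 alpha = alpha, n_perm = n_perm,
                 min_treatment_length_years = min_treatment_length_years),
            class = "run_config")
}

#' Derive dose phenotypes for one drug's purchases
#'
#' Convenience composition of the dose algorithms: consolidation (14
#' days), batching (> 365-day gaps), daily doses, per-person median
#' dose, maximum dose, and treatment length.
#'
#' @param purchases purchase table for one drug.
#' @param min_carriers carrier threshold for maximum-dose merging.
#' @return list with `daily` (observations), `summary` (per-person
#'   median dose, max dose, treatment length, unique purchase dates),
#'   `max_dose` (full [max_dose()] result).
#' @export
derive_dose_phenotypes <- function(purchases, min_carriers = 100) {
  cons <- consolidate_purchases(purchases)
  bat <- split_batches(cons)
  daily <- daily_doses(bat)
  med <- median_dose(daily)
  mx <- max_dose(purchases, min_carriers = min_carriers)
  tl <- treatment_length(purchases)
  nd <- as_dt(purchases)[, .(n_purchases_unique_dates =
                               data.table::uniqueN(date)), by = person_id]
  summary <- Reduce(function(a, b) merge(a, b, by = "person_id", all = TRUE),
                    list(med, mx$table, tl, nd))
  list(daily = daily, summary = summary, max_dose = mx)
}

#' Run the full pipeline
#'
#' Executes all stages in order on a simulated or on-disk cohort and
#' writes result TSVs plus a YAML manifest under `config$output_dir`.
#' Reruns with the same config (and seed) produce identical outputs.
#'
#' @param config a [run_config()].
#' @return list with the main in-memory results (`dose`, `pgs_stepwise`,
#'   `gwas`, `enrichment`, `variance`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed)

  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    cohort_data <- simulate_cohort(sim_cfg)
  } else {
    cohort_data <- read_fixture(config$input_dir)
  }
  manifest$simulate <- list(n_persons = nrow(cohort_data$covariates),
                            n_purchases = nrow(cohort_data$purchases),
                            n_variants = ncol(cohort_data$genotypes))

  # --- cohort selection ------------------------------------------------
  spec <- config$cohort %||% cohort_spec(
    drug_or_class = unique(cohort_data$purchases$drug_code)[1],
    first_purchase_on_or_after = as.Date("2005-01-01"))
  icd <- assign_main_icd(cohort_data$purchases,
                         seed = stage_seed(config$seed, "icd"))
  sel <- select_cohort(cohort_data$purchases, spec, main_icd = icd)
  write_tsv(sel$ledger, file.path(config$output_dir, "exclusion_ledger.tsv"))
  manifest$cohorts <- list(n_selected = length(sel$persons),
                           accepted = sel$accepted)

  # --- dose phenotypes -------------------------------------------------
  dose <- derive_dose_phenotypes(sel$purchases)
  flt <- log_outlier_filter(dose$daily$daily_dose)
  daily_kept <- dose$daily[flt$keep]
  summ <- dose$summary[!is.na(median_dose)]
  summ <- summ[treatment_length_years >= config$min_treatment_length_years]
  mflt <- log_outlier_filter(summ$median_dose)
  summ <- summ[mflt$keep]
  write_tsv(daily_kept, file.path(config$output_dir, "daily_doses.tsv"))
  write_tsv(summ, file.path(config$output_dir, "dose_summaries.tsv"))
  manifest$doses <- list(n_daily = nrow(daily_kept),
                         n_daily_excluded_3sd = flt$n_excluded,
                         n_summaries = nrow(summ))

  # --- PGS association -------------------------------------------------
  pgs_z <- standardize_pgs(cohort_data$pgs)
  cand <- config$candidate_pgs %||% colnames(pgs_z)
  thr <- bonferroni_threshold(length(cand), config$alpha)
  covars <- cohort_data$covariates
  med_fitter <- function(terms) fit_linear_median(summ, covars, pgs_z, terms)
  step_med <- forward_stepwise(med_fitter, cand, thr)
  assoc_rows <- list(step_med$single)
  if (!is.null(step_med$final)) assoc_rows <- c(assoc_rows, list(step_med$final))
  assoc <- data.table::rbindlist(assoc_rows, fill = TRUE)
  write_tsv(assoc, file.path(config$output_dir, "pgs_association.tsv"))
  manifest$pgs_assoc <- list(threshold = thr, selected = step_med$selected)

  # --- GWAS scan -------------------------------------------------------
  vi_kept <- variant_filter(cohort_data$variant_info)
  pheno <- stats::setNames(summ$median_dose, summ$person_id)
  pheno_int <- stats::setNames(inverse_normal_transform(pheno), names(pheno))
  scan_cov <- merge(covars, summ[, .(person_id, treatment_length_years)],
                    by = "person_id")
  scan_res <- gwas_scan(pheno_int, cohort_data$genotypes, scan_cov, vi_kept,
                        family = "linear",
                        covariate_cols = c("sex", "birth_year",
                                           "treatment_length_years",
                                           paste0("PC", 1:10)))
  write_tsv(scan_res, file.path(config$output_dir, "gwas_median.tsv"))
  manifest$gwas <- list(n_variants = nrow(scan_res),
                        n_genome_wide = sum(scan_res$genome_wide))

  # --- PGx enrichment --------------------------------------------------
  enr <- NULL
  top <- map_top_snv_per_gene(scan_res, cohort_data$genes)
  drug0 <- spec$drug_or_class
  set_genes <- as_dt(cohort_data$gene_sets)[drug == drug0, gene_id]
  bg_pruned <- ld_prune(top[, .(variant_id, chromosome, position, p)],
                        cohort_data$genotypes)
  bg_top <- merge(bg_pruned, top[, .(gene_id, variant_id)], by = "variant_id")
  pgx_pruned <- bg_top[gene_id %in% set_genes]
  if (nrow(pgx_pruned) >= 10) {
    enr <- permutation_enrichment(pgx_pruned$p, bg_pruned$p,
                                  n_perm = config$n_perm,
                                  seed = stage_seed(config$seed, "enrich"))
    hits <- empirical_threshold_hits(pgx_pruned, bg_pruned$p)
    write_tsv(data.table::data.table(drug = drug0,
                                     n_genes_pruned = enr$n_genes_pruned,
                                     observed_median_p = enr$observed_median_p,
                                     permutation_p = enr$permutation_p,
                                     background_size = enr$background_size,
                                     threshold_5pct = hits$threshold),
              file.path(config$output_dir, "enrichment.tsv"))
    manifest$enrich <- list(permutation_p = enr$permutation_p)
  } else {
    manifest$enrich <- list(skipped = "pruned PGx set below 10 genes")
  }

  # --- variance partition ----------------------------------------------
  vp <- NULL
  pgx_ids <- cohort_data$truth$pgx_variants$variant_id %||%
    cohort_data$truth$pgx_variants[["variant_id"]]
  if (length(pgx_ids) && length(step_med$selected)) {
    pgx_z <- scale(cohort_data$genotypes[, pgx_ids, drop = FALSE])
    vp <- variance_partition(summ, covars,
                             pgs_z[, step_med$selected, drop = FALSE], pgx_z)
    write_tsv(vp$table, file.path(config$output_dir, "variance_partition.tsv"))
    manifest$variance <- as.list(stats::setNames(vp$table$adj_r2,
                                                 vp$table$model))
  }

  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  invisible(list(cohort = cohort_data, selection = sel, dose = dose,
                 summaries = summ, pgs_stepwise = step_med, gwas = scan_res,
                 enrichment = enr, variance = vp, manifest = manifest))
}
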