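# Readers and writers for the pipeline's table formats. All tables are
# tab-delimited with a header row and ISO-8601 dates; genotypes travel
# either as VCF v4.2 with a DS (dosage) FORMAT field or as a plain
# dosage-matrix TSV (variants in rows, persons in columns); gene
# intervals as BED (0-based half-open on disk, converted to 1-based
# inclusive on read).

write_tsv <- function(dt, path) {
  data.table::fwrite(as_dt(dt), path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  data.table::fread(path, sep = "\t", header = TRUE, ...)
}

#' Read / write purchase records
#'
#' Purchase TSV columns: person_id, drug_code, date (ISO-8601),
#' mg_per_pill, pills_per_package, n_packages, rx_diagnosis,
#' age_at_purchase. Rows with unparseable dates are reported with their
#' line numbers.
#'
#' @param path file path.
#' @return data.table of purchases with `date` as Date.
#' @export
read_purchases <- function(path) {
  dt <- read_tsv(path, colClasses = list(character = "date"))
  assert_cols(dt, c("person_id", "drug_code", "date", "mg_per_pill",
                    "pills_per_package", "n_packages"), basename(path))
  parsed <- as.Date(dt$date, format = "%Y-%m-%d")
  bad <- which(is.na(parsed) & !is.na(dt$date) & nzchar(dt$date))
  if (length(bad))
    stop("unparseable date(s) in ", basename(path), " at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  dt[, date := parsed]
  dt[, person_id := as.character(person_id)]
  dt[]
}

#' @rdname read_purchases
#' @param purchases purchase table.
#' @export
write_purchases <- function(purchases, path) {
  dt <- as_dt(purchases)
  dt[, date := format(date, "%Y-%m-%d")]
  write_tsv(dt, path)
}

#' Read / write per-person covariates
#' @param path file path.
#' @return data.table keyed by `person_id`.
#' @export
read_covariates <- function(path) {
  dt <- read_tsv(path)
  assert_cols(dt, "person_id", basename(path))
  dt[, person_id := as.character(person_id)]
  dt[]
}

#' @rdname read_covariates
#' @param covariates covariate table.
#' @export
write_covariates <- function(covariates, path) write_tsv(covariates, path)

#' Read / write a PGS matrix
#'
#' Wide TSV: person_id column plus one column per trait.
#'
#' @param path file path.
#' @return numeric matrix with person ids as rownames.
#' @export
read_pgs <- function(path) {
  dt <- read_tsv(path)
  assert_cols(dt, "person_id", basename(path))
  ids <- as.character(dt$person_id)
  m <- as.matrix(dt[, !"person_id"])
  rownames(m) <- ids
  m
}

#' @rdname read_pgs
#' @param pgs matrix with rownames.
#' @export
write_pgs <- function(pgs, path) {
  dt <- data.table::data.table(person_id = rownames(pgs))
  write_tsv(cbind(dt, as.data.frame(pgs)), path)
}

#' Read / write a dosage matrix TSV
#'
#' Variants in rows (columns `variant_id`, `chromosome`, `position`
#' then one column per person), dosages in [0, 2].
#'
#' @param path file path.
#' @return person x variant numeric matrix.
#' @export
read_dosage_matrix <- function(path) {
  dt <- read_tsv(path)
  assert_cols(dt, c("variant_id", "chromosome", "position"), basename(path))
  vid <- dt$variant_id
  m <- t(as.matrix(dt[, !c("variant_id", "chromosome", "position")]))
  colnames(m) <- vid
  m
}

#' @rdname read_dosage_matrix
#' @param dosages person x variant matrix with dimnames.
#' @param variant_info data.frame with `variant_id`, `chromosome`,
#'   `position` matching the matrix columns.
#' @export
write_dosage_matrix <- function(dosages, variant_info, path) {
  vi <- as_dt(variant_info)[match(colnames(dosages), variant_id)]
  out <- cbind(vi[, .(variant_id, chromosome, position)],
               as.data.frame(t(dosages)))
  write_tsv(out, path)
}

#' Write genotype dosages as VCF v4.2 with a DS FORMAT field
#'
#' Alleles are written as placeholder A/G; the dosage in DS is the
#' quantity of record. GT is emitted alongside as the rounded hard call
#' so readers without DS support still decode something.
#'
#' @param dosages person x variant matrix.
#' @param variant_info `variant_id`, `chromosome`, `position` (+ optional
#'   `ref`, `alt`).
#' @param path output path (plain text).
#' @export
write_vcf_dosage <- function(dosages, variant_info, path) {
  vi <- as_dt(variant_info)[match(colnames(dosages), variant_id)]
  ids <- rownames(dosages)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt_of <- function(d) c("0/0", "0/1", "1/1")[pmin(2L, pmax(0L, round(d))) + 1L]
  for (j in seq_len(ncol(dosages))) {
    d <- dosages[, j]
    fields <- paste(gt_of(d), format(d, trim = TRUE, digits = 6), sep = ":")
    writeLines(paste(c(vi$chromosome[j], vi$position[j], vi$variant_id[j],
                       vi$ref[j] %||% "A", vi$alt[j] %||% "G", ".", "PASS",
                       ".", "GT:DS", fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from VCF
#'
#' Decodes the DS FORMAT field into a person x variant matrix; when DS
#' is absent, falls back to GT hard calls (allele counts) with a
#' warning.
#'
#' @param path VCF path.
#' @return person x variant numeric matrix.
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- v@fix[, "ID"]
  fmt <- v@gt[1, "FORMAT"]
  if (grepl("\\bDS\\b", fmt)) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    warning("VCF has no DS field; falling back to GT hard calls")
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  rownames(ds) <- ids
  t(ds)
}

#' Read / write gene intervals as BED
#'
#' BED on disk is 0-based half-open; in memory the package uses 1-based
#' inclusive coordinates.
#'
#' @param path BED path.
#' @return data.table `gene_id`, `chromosome`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chromosome", "bed_start", "bed_end",
                                        "gene_id"))
  dt[, .(gene_id, chromosome = as.character(chromosome),
         start = bed_start + 1L, end = bed_end)]
}

#' @rdname read_bed
#' @param genes table with 1-based inclusive `start`, `end`.
#' @export
write_bed <- function(genes, path) {
  dt <- as_dt(genes)
  out <- dt[, .(chromosome, bed_start = start - 1L, bed_end = end, gene_id)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a full synthetic cohort to plain-text fixture files
#'
#' Emits purchases/covariates/PGS as TSV, genotypes both as VCF (DS
#' field) and as a dosage-matrix TSV, variant metadata, gene intervals
#' as BED, gene sets and DDD factors as TSV, and the planted truth as
#' YAML. Everything round-trips losslessly through the matching
#' readers.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param directory output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_fixture <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  write_purchases(cohort$purchases, p("purchases.tsv"))
  write_covariates(cohort$covariates, p("covariates.tsv"))
  write_pgs(cohort$pgs, p("pgs.tsv"))
  write_dosage_matrix(cohort$genotypes, cohort$variant_info, p("dosages.tsv"))
  write_vcf_dosage(cohort$genotypes, cohort$variant_info, p("genotypes.vcf"))
  write_tsv(cohort$variant_info, p("variant_info.tsv"))
  write_bed(cohort$genes, p("genes.bed"))
  write_tsv(cohort$gene_sets, p("gene_sets.tsv"))
  write_tsv(cohort$ddd_factors, p("ddd_factors.tsv"))
  tr <- cohort$truth
  yaml::write_yaml(list(beta_pgs = as.list(tr$beta_pgs),
                        pgx_variants = if (nrow(tr$pgx_variants))
                          lapply(seq_len(nrow(tr$pgx_variants)), function(i)
                            as.list(tr$pgx_variants[i])) else list(),
                        sex_beta = tr$sex_beta, age_beta = tr$age_beta,
                        intercepts = as.list(tr$intercepts),
                        noise_sd = tr$noise_sd, seed = tr$seed),
                   p("truth.yaml"))
  invisible(c(purchases = p("purchases.tsv"), covariates = p("covariates.tsv"),
              pgs = p("pgs.tsv"), dosages = p("dosages.tsv"),
              vcf = p("genotypes.vcf"), variant_info = p("variant_info.tsv"),
              genes = p("genes.bed"), gene_sets = p("gene_sets.tsv"),
              ddd = p("ddd_factors.tsv"), truth = p("truth.yaml")))
}

#' Read a fixture directory back into cohort tables
#'
#' @param directory directory written by [write_fixture()].
#' @return list with the same table components as the cohort (truth as
#'   the parsed YAML list).
#' @export
read_fixture <- function(directory) {
  p <- function(f) file.path(directory, f)
  list(purchases = read_purchases(p("purchases.tsv")),
       covariates = read_covariates(p("covariates.tsv")),
       pgs = read_pgs(p("pgs.tsv")),
       genotypes = read_dosage_matrix(p("dosages.tsv")),
       variant_info = read_tsv(p("variant_info.tsv"))[
         , chromosome := as.character(chromosome)][],
       genes = read_bed(p("genes.bed")),
       gene_sets = read_tsv(p("gene_sets.tsv")),
       ddd_factors = read_tsv(p("ddd_factors.tsv")),
       truth = yaml::read_yaml(p("truth.yaml")))
}
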