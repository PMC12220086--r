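# PGx gene-set analysis on scan results: SNV-to-gene assignment with
# flanks, top SNV per gene, windowed LD pruning, permutation enrichment
# of the median p-value, and empirical-threshold hit calling.
#
# Coordinates are 1-based inclusive throughout; BED inputs are converted
# on read (see read_bed).

#' Top SNV per gene
#'
#' Assigns each variant to every protein-coding gene whose interval,
#' extended by `flank` bp on both sides, contains its position
#' (boundaries inclusive; multi-gene membership allowed), then keeps the
#' minimum-p variant per gene, breaking ties by smaller position.
#'
#' @param gwas_results scan results with `variant_id`, `chromosome`,
#'   `position`, `p`.
#' @param annotation gene table with `gene_id`, `chromosome`, `start`,
#'   `end` (1-based inclusive).
#' @param flank flanking region in bp (default 5000).
#' @return data.table `gene_id`, `variant_id`, `chromosome`, `position`,
#'   `p`; genes without any variant are omitted (message).
#' @export
map_top_snv_per_gene <- function(gwas_results, annotation, flank = 5000) {
  res <- as_dt(gwas_results)
  ann <- as_dt(annotation)
  assert_cols(res, c("variant_id", "chromosome", "position", "p"), "scan results")
  assert_cols(ann, c("gene_id", "chromosome", "start", "end"), "annotation")
  if (any(ann$start > ann$end)) stop("annotation has start > end")
  ann2 <- ann[, .(gene_id, chromosome, w_start = start - flank, w_end = end + flank)]
  res2 <- res[, .(variant_id, chromosome, position, p,
                  w_start = position, w_end = position)]
  data.table::setkey(ann2, chromosome, w_start, w_end)
  ov <- data.table::foverlaps(res2, ann2, type = "within", nomatch = NULL)
  if (nrow(ov) == 0L)
    return(data.table::data.table(gene_id = character(), variant_id = character(),
                                  chromosome = character(), position = integer(),
                                  p = numeric()))
  top <- ov[order(p, position), .SD[1L], by = gene_id,
            .SDcols = c("variant_id", "chromosome", "position", "p")]
  missing_genes <- setdiff(ann$gene_id, top$gene_id)
  if (length(missing_genes))
    message(length(missing_genes), " gene(s) without any assigned variant omitted")
  top[]
}

pairwise_r2 <- function(G) {
  suppressWarnings(stats::cor(G))^2
}

#' Windowed LD pruning
#'
#' Sliding-window pruning with a 50-kb window, a step of 5 SNVs, and an
#' r-squared threshold of 0.2 (squared Pearson correlation of dosages).
#' Whenever a pair within a window exceeds the threshold, the member
#' with the larger p-value is removed (tie: larger position); windows
#' advance by `step` SNVs and passes repeat until stable. A final sweep
#' over all remaining pairs within `window_bp` enforces the guarantee
#' that no retained pair within the window has r-squared above the
#' threshold.
#'
#' @param snvs data.frame with `variant_id`, `chromosome`, `position`,
#'   `p`, position-sorted within chromosome.
#' @param genotypes person x variant dosage matrix covering the SNVs;
#'   SNVs without genotypes are dropped with a warning.
#' @param window_bp window size in bp (default 50000).
#' @param step window step in SNVs (default 5).
#' @param r2_max r-squared threshold (default 0.2).
#' @return the retained SNV rows.
#' @export
ld_prune <- function(snvs, genotypes, window_bp = 50000, step = 5,
                     r2_max = 0.2) {
  dt <- as_dt(snvs)
  assert_cols(dt, c("variant_id", "chromosome", "position", "p"), "snvs")
  missing <- setdiff(dt$variant_id, colnames(genotypes))
  if (length(missing)) {
    warning(length(missing), " SNV(s) without genotypes dropped")
    dt <- dt[!variant_id %in% missing]
  }
  prune_chrom <- function(d) {
    data.table::setorder(d, position)
    alive <- rep(TRUE, nrow(d))
    drop_worse <- function(i, j) {
      # remove the larger-p member; tie -> larger position
      worse <- if (d$p[i] > d$p[j] ||
                   (d$p[i] == d$p[j] && d$position[i] > d$position[j])) i else j
      alive[worse] <<- FALSE
    }
    repeat {
      changed <- FALSE
      idx <- which(alive)
      if (length(idx) < 2L) break
      for (s in seq(1L, length(idx), by = step)) {
        i0 <- idx[s]
        win <- idx[d$position[idx] >= d$position[i0] &
                   d$position[idx] <= d$position[i0] + window_bp & alive[idx]]
        if (length(win) < 2L) next
        r2 <- pairwise_r2(genotypes[, d$variant_id[win], drop = FALSE])
        r2[is.na(r2)] <- 0
        for (a in seq_len(length(win) - 1L)) for (b in (a + 1L):length(win)) {
          ia <- win[a]; ib <- win[b]
          if (alive[ia] && alive[ib] && r2[a, b] > r2_max) {
            drop_worse(ia, ib)
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    # guarantee sweep over all surviving pairs within the window
    repeat {
      idx <- which(alive)
      violated <- FALSE
      if (length(idx) >= 2L) {
        for (a in seq_len(length(idx) - 1L)) {
          for (b in (a + 1L):length(idx)) {
            ia <- idx[a]; ib <- idx[b]
            if (!alive[ia] || !alive[ib]) next
            if (d$position[ib] - d$position[ia] > window_bp) break
            r2 <- pairwise_r2(genotypes[, d$variant_id[c(ia, ib)], drop = FALSE])[1, 2]
            if (!is.na(r2) && r2 > r2_max) {
              drop_worse(ia, ib)
              violated <- TRUE
            }
          }
        }
      }
      if (!violated) break
    }
    d[alive]
  }
  out <- dt[, prune_chrom(.SD), by = chromosome,
            .SDcols = setdiff(names(dt), "chromosome")]
  data.table::setorder(out, chromosome, position)
  out[]
}

#' Permutation enrichment of a PGx gene set
#'
#' Compares the observed median p-value of the (pruned) PGx-set SNVs to
#' a null distribution built by repeatedly sampling an equal number of
#' SNVs without replacement from the pruned background set (which
#' includes the PGx genes). The permutation p-value is the proportion of
#' permuted medians as low as or lower than the observed median; with
#' `plus_one = TRUE` the positively biased estimator (r+1)/(B+1) is
#' used instead, which cannot return exactly zero.
#'
#' @param pgx_p p-values of the pruned PGx-set SNVs (one per gene's top
#'   SNV).
#' @param background_p p-values of the pruned background SNVs.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param min_set minimum PGx set size for a valid test (default 10).
#' @param plus_one use the (r+1)/(B+1) estimator (default FALSE).
#' @return list of class `enrichment_result`: `n_genes_pruned`,
#'   `observed_median_p`, `n_permutations`, `permutation_p`,
#'   `background_size`.
#' @export
permutation_enrichment <- function(pgx_p, background_p, n_perm = 10000,
                                   seed = 1L, min_set = 10, plus_one = FALSE) {
  k <- length(pgx_p)
  if (k < min_set)
    stop("pruned PGx set has ", k, " genes; at least ", min_set,
         " required for a valid test")
  if (length(background_p) < k)
    stop("background smaller than the PGx set")
  obs <- stats::median(pgx_p)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    stats::median(background_p[sample.int(length(background_p), k)]),
    numeric(1))
  r <- sum(perm <= obs)
  pp <- if (plus_one) (r + 1) / (n_perm + 1) else r / n_perm
  structure(list(n_genes_pruned = k, observed_median_p = obs,
                 n_permutations = n_perm, permutation_p = pp,
                 background_size = length(background_p)),
            class = "enrichment_result")
}

#' PGx SNVs below the empirical background threshold
#'
#' The significance threshold is the 5th percentile (linear
#' interpolation between order statistics) of the pruned background
#' p-values; PGx-set SNVs with p strictly below it are returned.
#'
#' @param pgx_snvs pruned PGx SNV table with `variant_id`, `p` (and any
#'   carried columns, e.g. `gene_id`).
#' @param background_p p-values of the pruned background SNVs.
#' @param percentile background percentile defining the threshold
#'   (default 0.05).
#' @return list with `threshold` and `hits` (the qualifying rows).
#' @export
empirical_threshold_hits <- function(pgx_snvs, background_p,
                                     percentile = 0.05) {
  dt <- as_dt(pgx_snvs)
  assert_cols(dt, c("variant_id", "p"), "PGx SNVs")
  if (length(background_p) < 20)
    warning("background has fewer than 20 SNVs; the empirical threshold is unstable")
  thr <- unname(stats::quantile(background_p, percentile, type = 7))
  list(threshold = thr, hits = dt[p < thr][])
}
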