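# Independent straightforward re-implementation of the dose rules,
# written as plain loops directly from their verbal statement. Used as
# the oracle against the vectorized implementation; kept free of any
# package internals.

oracle_consolidate <- function(dates, totals, window = 14) {
  stopifnot(!is.unsorted(dates))
  out_dates <- c()
  out_totals <- c()
  i <- 1
  n <- length(dates)
  while (i <= n) {
    open <- dates[i]
    tot <- 0
    j <- i
    while (j <= n && as.numeric(dates[j] - open) <= window) {
      tot <- tot + totals[j]
      j <- j + 1
    }
    out_dates <- c(out_dates, open)
    out_totals <- c(out_totals, tot)
    i <- j
  }
  list(dates = as.Date(out_dates, origin = "1970-01-01"), totals = out_totals)
}

oracle_batches <- function(dates, gap = 365) {
  b <- 1
  ids <- numeric(length(dates))
  ids[1] <- 1
  if (length(dates) > 1) for (i in 2:length(dates)) {
    if (as.numeric(dates[i] - dates[i - 1]) > gap) b <- b + 1
    ids[i] <- b
  }
  ids
}

# daily doses within one batch: mg_i / days to next purchase; the last
# purchase yields nothing; single-purchase batches are excluded
oracle_daily <- function(dates, totals, gap = 365) {
  bid <- oracle_batches(dates, gap)
  doses <- numeric(0)
  for (b in unique(bid)) {
    idx <- which(bid == b)
    if (length(idx) < 2) next
    for (k in seq_len(length(idx) - 1)) {
      i <- idx[k]
      doses <- c(doses, totals[i] / as.numeric(dates[idx[k + 1]] - dates[i]))
    }
  }
  doses
}

oracle_median_dose <- function(dates, totals, gap = 365) {
  bid <- oracle_batches(dates, gap)
  batch_medians <- numeric(0)
  for (b in unique(bid)) {
    idx <- which(bid == b)
    if (length(idx) < 2) next
    ds <- numeric(0)
    for (k in seq_len(length(idx) - 1)) {
      i <- idx[k]
      ds <- c(ds, totals[i] / as.numeric(dates[idx[k + 1]] - dates[i]))
    }
    batch_medians <- c(batch_medians, median(ds))
  }
  if (!length(batch_medians)) return(NA_real_)
  median(batch_medians)
}

# full person-level oracle on a raw purchase list (one person, one drug)
oracle_person <- function(dates, mg, pills, packs, window = 14, gap = 365) {
  cons <- oracle_consolidate(dates, mg * pills * packs, window)
  list(daily = oracle_daily(cons$dates, cons$totals, gap),
       median = oracle_median_dose(cons$dates, cons$totals, gap),
       treatment_years = sum(pills * packs) / 365.25)
}

# random small purchase list for one person
random_purchase_list <- function(n_max = 12) {
  n <- sample(2:n_max, 1)
  gaps <- sample(c(1:60, 300:420), n - 1, replace = TRUE)
  dates <- as.Date("2010-01-01") + cumsum(c(0, gaps))
  data.table::data.table(
    person_id = "X",
    drug_code = "D",
    date = dates,
    mg_per_pill = sample(c(5, 10, 20, 40, 80), n, replace = TRUE),
    pills_per_package = sample(c(28, 30, 100), n, replace = TRUE),
    n_packages = sample(1:2, n, replace = TRUE),
    rx_diagnosis = "E78",
    age_at_purchase = 50 + seq_len(n) / 10)
}

run_package_person <- function(pp) {
  cons <- consolidate_purchases(pp)
  bat <- split_batches(cons)
  daily <- daily_doses(bat)
  med <- median_dose(daily)
  list(daily = daily$daily_dose,
       median = if (nrow(med)) med$median_dose else NA_real_,
       treatment_years = treatment_length(pp)$treatment_length_years)
}
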