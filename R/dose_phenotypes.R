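# Purchase-to-dose algorithms: consolidation, batching, daily doses,
# median and maximum dose, treatment length, DDD scaling, mono-drug filter.
#
# Conventions fixed across the module:
#   * "within 2 weeks" means <= 14 days after the window-opening purchase;
#   * a new batch starts when the gap to the previous purchase is
#     strictly greater than 365 days;
#   * even-count medians are the midpoint of the two central values
#     (stats::median default);
#   * one pill per day when converting supply to time.

#' Consolidate purchases within a 14-day window
#'
#' Dispensing events for the same person that fall within 14 days of an
#' earlier event are merged into a single purchase dated at the earliest
#' date of the window, with the dispensed milligrams summed. Merging is
#' greedy from the earliest purchase: a window opens at the first
#' unmerged purchase and absorbs every later purchase dated at most
#' `window_days` after the opening date; it does not chain beyond that.
#'
#' @param purchases a data.frame/data.table of dispensing events for a
#'   single drug or class, with columns `person_id`, `date` (Date),
#'   `mg_per_pill`, `pills_per_package`, `n_packages`, and optionally
#'   `age_at_purchase`. Must be sorted by date within person.
#' @param window_days consolidation window length in days (default 14).
#' @return a data.table with one row per consolidated purchase:
#'   `person_id`, `date` (window opening), `total_mg`, `n_merged`,
#'   `source_dates` (list column), and `age_at_purchase` (of the opening
#'   purchase) when present in the input.
#' @export
consolidate_purchases <- function(purchases, window_days = 14) {
  dt <- as_dt(purchases)
  assert_cols(dt, c("person_id", "date", "mg_per_pill", "pills_per_package",
                    "n_packages"), "purchases")
  if (!inherits(dt$date, "Date")) stop("`date` must be of class Date")
  if (nrow(dt) == 0L) {
    out <- data.table::data.table(person_id = character(), date = as.Date(character()),
                                  total_mg = numeric(), n_merged = integer())
    return(out)
  }
  unsorted <- dt[, any(diff(as.numeric(date)) < 0), by = person_id][V1 == TRUE]
  if (nrow(unsorted))
    stop("purchases must be sorted by date within person; offending person(s): ",
         paste(utils::head(unsorted$person_id, 5), collapse = ", "))
  dt[, total_mg := mg_per_pill * pills_per_package * n_packages]
  if (any(dt$total_mg <= 0)) stop("non-positive dispensed mg encountered")
  has_age <- "age_at_purchase" %in% names(dt)

  one_person <- function(d) {
    n <- nrow(d)
    grp <- integer(n)
    open <- 1L
    g <- 1L
    grp[1L] <- 1L
    if (n > 1L) for (i in 2L:n) {
      if (as.numeric(d$date[i] - d$date[open]) > window_days) {
        g <- g + 1L
        open <- i
      }
      grp[i] <- g
    }
    d[, .(date = date[1L], total_mg = sum(total_mg), n_merged = .N,
          source_dates = list(date),
          age_at_purchase = if (has_age) age_at_purchase[1L] else NA_real_),
      by = .(grp_ = grp)][, grp_ := NULL][]
  }
  out <- dt[, one_person(.SD), by = person_id]
  if (!has_age) out[, age_at_purchase := NULL]
  out[]
}

#' Split consolidated purchases into treatment batches
#'
#' A new batch starts whenever the gap from the previous purchase is
#' strictly greater than `gap_days`. Batches with a single purchase carry
#' no dose information (the last purchase only closes the interval of the
#' one before it) and are flagged for exclusion.
#'
#' @param consolidated output of [consolidate_purchases()], sorted by
#'   date within person.
#' @param gap_days gap defining a treatment break (default 365; a gap of
#'   exactly `gap_days` stays in the same batch).
#' @return the input with `batch_id` (within-person index) and `usable`
#'   (batch size >= 2) columns added.
#' @export
split_batches <- function(consolidated, gap_days = 365) {
  dt <- as_dt(consolidated)
  assert_cols(dt, c("person_id", "date", "total_mg"), "consolidated purchases")
  dt[, batch_id := {
    gaps <- c(0, diff(as.numeric(date)))
    cumsum(gaps > gap_days) + 1L
  }, by = person_id]
  dt[, usable := .N >= 2L, by = .(person_id, batch_id)]
  dt[]
}

#' Daily dose per purchase within batches
#'
#' For each batch, the dispensed milligrams of purchase i are divided by
#' the number of days until purchase i+1, giving an estimated daily dose.
#' The last purchase of a batch serves only as the end date of the
#' preceding purchase and yields no observation; single-purchase batches
#' yield nothing.
#'
#' @param batched output of [split_batches()].
#' @param first_date optional named vector of each person's first
#'   purchase date used as time origin for `years_since_first`; defaults
#'   to the first date present per person.
#' @return a data.table of observations: `person_id`, `batch_id`, `date`,
#'   `daily_dose` (mg/day), `interval_days`, `years_since_first`, and
#'   `age_at_purchase` when available.
#' @export
daily_doses <- function(batched, first_date = NULL) {
  dt <- as_dt(batched)[usable == TRUE]
  has_age <- "age_at_purchase" %in% names(dt)
  if (nrow(dt) == 0L)
    return(data.table::data.table(person_id = character(), batch_id = integer(),
                                  date = as.Date(character()), daily_dose = numeric(),
                                  interval_days = numeric(), years_since_first = numeric()))
  data.table::setorder(dt, person_id, date)
  obs <- dt[, {
    k <- .N
    iv <- as.numeric(diff(as.numeric(date)))
    stopifnot(all(iv > 0))
    list(date = date[-k], daily_dose = total_mg[-k] / iv,
         interval_days = iv,
         age_at_purchase = if (has_age) age_at_purchase[-k] else NA_real_)
  }, by = .(person_id, batch_id)]
  if (!has_age) obs[, age_at_purchase := NULL]
  if (is.null(first_date)) {
    obs[, years_since_first := as.numeric(date - min(date)) / 365.25, by = person_id]
  } else {
    obs[, years_since_first := as.numeric(date - first_date[person_id]) / 365.25]
  }
  obs[]
}

#' Median dose per person
#'
#' The median is taken within each usable batch first, then across batch
#' medians, so treatment periods separated by long breaks contribute
#' equally rather than in proportion to their purchase counts.
#'
#' @param observations output of [daily_doses()].
#' @return data.table `person_id`, `median_dose`, `n_batches`, `n_obs`.
#'   Persons with no usable batch are absent (callers log them).
#' @export
median_dose <- function(observations) {
  dt <- as_dt(observations)
  if (nrow(dt) == 0L)
    return(data.table::data.table(person_id = character(), median_dose = numeric(),
                                  n_batches = integer(), n_obs = integer()))
  bm <- dt[, .(m = stats::median(daily_dose), n = .N), by = .(person_id, batch_id)]
  bm[, .(median_dose = stats::median(m), n_batches = .N, n_obs = sum(n)),
     by = person_id][]
}

#' Maximum dose level and binary indicator
#'
#' Works on raw (non-consolidated) purchases. A package strength is
#' eligible for a person when bought on at least `min_dates` unique
#' dates; the person's maximum dose level is the highest eligible
#' strength. Cohort-wide, the top strength is merged downward with the
#' next level until the top group has at least `min_carriers` carriers
#' (or a single group remains); the binary variable contrasts membership
#' in that top group against all lower levels.
#'
#' @param purchases raw purchase table with `person_id`, `date`,
#'   `mg_per_pill`.
#' @param min_dates minimum unique purchase dates per strength (default 3).
#' @param min_carriers minimum carriers of the top level before merging
#'   stops (default 100).
#' @return list with `table` (`person_id`, `max_dose_level`,
#'   `max_dose_binary`), `top_levels` (strengths merged into the top
#'   group), `dropped` (persons with no eligible strength), and
#'   `analyzable` (FALSE when the binary variable is constant).
#' @export
max_dose <- function(purchases, min_dates = 3, min_carriers = 100) {
  dt <- as_dt(purchases)
  assert_cols(dt, c("person_id", "date", "mg_per_pill"), "purchases")
  elig <- dt[, .(n_dates = data.table::uniqueN(date)), by = .(person_id, mg_per_pill)]
  elig <- elig[n_dates >= min_dates]
  all_persons <- unique(dt$person_id)
  if (nrow(elig) == 0L) {
    empty <- data.table::data.table(person_id = character(),
                                    max_dose_level = numeric(),
                                    max_dose_binary = integer())
    return(list(table = empty, top_levels = numeric(), dropped = all_persons,
                analyzable = FALSE))
  }
  per <- elig[, .(max_dose_level = max(mg_per_pill)), by = person_id]
  dropped <- setdiff(all_persons, per$person_id)

  levels_desc <- sort(unique(per$max_dose_level), decreasing = TRUE)
  top_set <- levels_desc[1L]
  while (length(top_set) < length(levels_desc) &&
         sum(per$max_dose_level %in% top_set) < min_carriers) {
    top_set <- levels_desc[seq_len(length(top_set) + 1L)]
  }
  per[, max_dose_binary := as.integer(max_dose_level %in% top_set)]
  analyzable <- data.table::uniqueN(per$max_dose_binary) > 1L
  list(table = per[], top_levels = top_set, dropped = dropped,
       analyzable = analyzable)
}

#' Treatment length from days' supply
#'
#' Total pills dispensed, at one pill per day, converted to years
#' (365.25 days/year).
#'
#' @param purchases raw purchase table with `person_id`,
#'   `pills_per_package`, `n_packages`.
#' @return data.table `person_id`, `treatment_length_years`.
#' @export
treatment_length <- function(purchases) {
  dt <- as_dt(purchases)
  assert_cols(dt, c("person_id", "pills_per_package", "n_packages"), "purchases")
  if (nrow(dt) == 0L)
    return(data.table::data.table(person_id = character(),
                                  treatment_length_years = numeric()))
  dt[, .(treatment_length_years = sum(pills_per_package * n_packages) / 365.25),
     by = person_id][]
}

#' Scale doses to Defined Daily Doses
#'
#' Divides `daily_dose` (or `median_dose`) by the drug-specific DDD
#' factor so drugs within a class share a common scale; class-level
#' pooling happens only after scaling.
#'
#' @param observations table carrying `drug_code` and a dose column.
#' @param ddd_factors data.frame with `drug_code`, `mg_per_ddd`.
#' @param dose_col name of the dose column to scale.
#' @return the table with the dose column rescaled to DDD/day.
#' @export
ddd_scale <- function(observations, ddd_factors, dose_col = "daily_dose") {
  dt <- as_dt(observations)
  fac <- as_dt(ddd_factors)
  assert_cols(dt, c("drug_code", dose_col), "observations")
  assert_cols(fac, c("drug_code", "mg_per_ddd"), "ddd_factors")
  miss <- setdiff(unique(dt$drug_code), fac$drug_code)
  if (length(miss))
    stop("no DDD factor for drug code(s): ", paste(miss, collapse = ", "))
  if (any(fac$mg_per_ddd <= 0)) stop("DDD factors must be positive")
  dt <- merge(dt, fac[, .(drug_code, mg_per_ddd)], by = "drug_code", sort = FALSE)
  dt[, (dose_col) := get(dose_col) / mg_per_ddd]
  dt[, mg_per_ddd := NULL]
  dt[]
}

#' Mono-drug sliding-window filter
#'
#' Retains a target-drug purchase only when, in the forward-looking
#' window from its date to 365 days later, unique dates with a
#' target-drug purchase make up at least 75% of unique dates with any
#' purchase in the medication class. This excludes periods of
#' simultaneous or trial use of other drugs in the class.
#'
#' @param class_purchases purchases across one medication class with
#'   `person_id`, `drug_code`, `date`.
#' @param target_drug drug code of interest.
#' @param window_days window length (default 365).
#' @param min_share minimum share of target purchases (default 0.75,
#'   boundary inclusive).
#' @return the retained target-drug purchase rows.
#' @export
mono_drug_filter <- function(class_purchases, target_drug, window_days = 365,
                             min_share = 0.75) {
  dt <- as_dt(class_purchases)
  assert_cols(dt, c("person_id", "drug_code", "date"), "class purchases")
  tgt <- dt[drug_code == target_drug]
  if (nrow(tgt) == 0L) return(tgt)
  keep <- logical(nrow(tgt))
  split_all <- split(dt, dt$person_id)
  for (i in seq_len(nrow(tgt))) {
    pid <- tgt$person_id[i]
    t0 <- tgt$date[i]
    w <- split_all[[pid]]
    w <- w[date >= t0 & date <= t0 + window_days]
    share <- data.table::uniqueN(w[drug_code == target_drug, date]) /
      data.table::uniqueN(w$date)
    keep[i] <- share >= min_share
  }
  tgt[keep][]
}

#' Log-scale 3-SD outlier filter
#'
#' Values more than `n_sd` standard deviations from the mean of the
#' natural-log values are excluded. Mean and SD come from a single pass
#' over the full pre-filter set (no iteration). A constant series has
#' SD 0 and nothing is excluded.
#'
#' @param values positive numeric vector.
#' @param n_sd exclusion threshold in SD units (default 3).
#' @return list with `keep` (logical vector), `log_mean`, `log_sd`,
#'   `n_excluded`.
#' @export
log_outlier_filter <- function(values, n_sd = 3) {
  if (any(values <= 0)) stop("values must be positive for log-scale filtering")
  lv <- log(values)
  m <- mean(lv)
  s <- stats::sd(lv)
  if (length(values) < 2L || is.na(s) || s == 0) {
    keep <- rep(TRUE, length(values))
  } else {
    keep <- abs(lv - m) <= n_sd * s
  }
  list(keep = keep, log_mean = m, log_sd = if (is.na(s)) 0 else s,
       n_excluded = sum(!keep))
}
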