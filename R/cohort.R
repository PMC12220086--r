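# Inclusion/exclusion filters and cohort descriptives.

#' Cohort selection specification
#'
#' Thresholds for building a per-drug analysis cohort: purchase records
#' must span more than `min_span_days`, contain at least
#' `min_unique_purchases` purchases on unique dates, purchases before
#' age `min_age` are dropped, and (optionally) the person's main
#' prescription diagnosis must fall in `required_rx_codes` and the first
#' purchase must be on or after `first_purchase_on_or_after`.
#'
#' @param drug_or_class identifier for the drug or class being selected.
#' @param min_span_days span threshold, strict (default 365: spans of
#'   exactly 365 days are excluded).
#' @param min_unique_purchases minimum purchases on unique dates (default 6).
#' @param min_age minimum age at purchase in years (default 18).
#' @param min_cohort_size minimum persons for an analyzable cohort
#'   (default 500).
#' @param required_rx_codes optional character vector of diagnosis code
#'   prefixes the main ICD code must match.
#' @param first_purchase_on_or_after optional Date; persons whose first
#'   retained purchase precedes it are excluded (daily-dose analyses use
#'   2005-01-01).
#' @param min_treatment_length_years minimum treatment length on supply
#'   for median/maximum dose analyses (default 2; applied downstream).
#' @param exclude_ids optional person ids excluded a priori (e.g. overlap
#'   with PGS training data).
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(drug_or_class,
                        min_span_days = 365,
                        min_unique_purchases = 6,
                        min_age = 18,
                        min_cohort_size = 500,
                        required_rx_codes = NULL,
                        first_purchase_on_or_after = NULL,
                        min_treatment_length_years = 2,
                        exclude_ids = NULL) {
  stopifnot(min_span_days >= 0, min_unique_purchases >= 0, min_age >= 0,
            min_cohort_size >= 0, min_treatment_length_years >= 0)
  structure(list(drug_or_class = drug_or_class,
                 min_span_days = min_span_days,
                 min_unique_purchases = min_unique_purchases,
                 min_age = min_age,
                 min_cohort_size = min_cohort_size,
                 required_rx_codes = required_rx_codes,
                 first_purchase_on_or_after =
                   if (!is.null(first_purchase_on_or_after))
                     as.Date(first_purchase_on_or_after) else NULL,
                 min_treatment_length_years = min_treatment_length_years,
                 exclude_ids = exclude_ids),
            class = "cohort_spec")
}

#' Select an analysis cohort
#'
#' Applies the selection filters in a fixed order — under-age purchases
#' dropped first (row level), then per person: a-priori id exclusion,
#' span > `min_span_days`, unique purchase dates, first-purchase date,
#' and main-diagnosis restriction. Each excluded person is attributed to
#' the first filter that removes them, giving a reproducible attrition
#' ledger.
#'
#' @param purchases purchase table with `person_id`, `date`,
#'   `age_at_purchase`, and `rx_diagnosis` when a diagnosis restriction
#'   applies.
#' @param spec a [cohort_spec()].
#' @param main_icd optional named vector person -> main diagnosis code
#'   (from [assign_main_icd()]); required when `spec$required_rx_codes`
#'   is set.
#' @return list with `persons` (retained ids), `purchases` (retained
#'   rows for those persons), `ledger` (per-filter exclusion counts),
#'   and `accepted` (FALSE when the final cohort is smaller than
#'   `min_cohort_size`).
#' @export
select_cohort <- function(purchases, spec, main_icd = NULL) {
  dt <- as_dt(purchases)
  assert_cols(dt, c("person_id", "date", "age_at_purchase"), "purchases")
  n0 <- data.table::uniqueN(dt$person_id)
  ledger <- list()
  excluded <- character()

  # row-level age filter; persons losing all purchases count against it
  before <- unique(dt$person_id)
  dt <- dt[age_at_purchase >= spec$min_age]
  gone <- setdiff(before, dt$person_id)
  ledger[["under_age"]] <- length(gone)
  excluded <- c(excluded, gone)

  drop_step <- function(dt, bad, label) {
    ledger[[label]] <<- length(bad)
    excluded <<- c(excluded, bad)
    dt[!person_id %in% bad]
  }

  if (!is.null(spec$exclude_ids)) {
    bad <- intersect(unique(dt$person_id), spec$exclude_ids)
    dt <- drop_step(dt, bad, "a_priori_exclusion")
  } else ledger[["a_priori_exclusion"]] <- 0L

  per <- dt[, .(span = as.numeric(max(date) - min(date)),
                n_dates = data.table::uniqueN(date),
                first = min(date)), by = person_id]
  dt <- drop_step(dt, per[span <= spec$min_span_days, person_id], "span")
  per <- per[person_id %in% dt$person_id]
  dt <- drop_step(dt, per[n_dates < spec$min_unique_purchases, person_id],
                  "unique_dates")
  per <- per[person_id %in% dt$person_id]
  if (!is.null(spec$first_purchase_on_or_after)) {
    dt <- drop_step(dt, per[first < spec$first_purchase_on_or_after, person_id],
                    "first_purchase_date")
  } else ledger[["first_purchase_date"]] <- 0L

  if (!is.null(spec$required_rx_codes)) {
    if (is.null(main_icd))
      stop("required_rx_codes set but no main_icd supplied; run assign_main_icd()")
    ids <- unique(dt$person_id)
    ok <- vapply(ids, function(p) {
      code <- main_icd[[p]]
      !is.null(code) && !is.na(code) &&
        any(startsWith(code, spec$required_rx_codes))
    }, logical(1))
    dt <- drop_step(dt, ids[!ok], "diagnosis")
  } else ledger[["diagnosis"]] <- 0L

  persons <- unique(dt$person_id)
  led <- data.table::data.table(filter = names(ledger),
                                n_excluded = unlist(ledger, use.names = FALSE))
  stopifnot(n0 == length(persons) + sum(led$n_excluded))
  list(persons = persons, purchases = dt[], ledger = led,
       accepted = length(persons) >= spec$min_cohort_size)
}

#' Assign each person's main prescription diagnosis
#'
#' The most frequent diagnosis code across a person's prescriptions;
#' ties are resolved by a seeded uniform draw so assignment is
#' reproducible.
#'
#' @param purchases table with `person_id`, `rx_diagnosis`.
#' @param seed integer seed for tie-breaking.
#' @return named character vector person -> main code.
#' @export
assign_main_icd <- function(purchases, seed = 1L) {
  dt <- as_dt(purchases)
  assert_cols(dt, c("person_id", "rx_diagnosis"), "purchases")
  counts <- dt[, .N, by = .(person_id, rx_diagnosis)]
  set.seed(seed)
  data.table::setorder(counts, person_id, rx_diagnosis)
  res <- counts[, {
    top <- rx_diagnosis[N == max(N)]
    .(code = if (length(top) == 1L) top else top[sample.int(length(top), 1L)])
  }, by = person_id]
  stats::setNames(res$code, res$person_id)
}

#' Flag purchases occurring after a hard cardiovascular event
#'
#' Adds a 0/1 covariate that is 1 for purchases on or after the
#' person's earliest qualifying event (myocardial or cerebral
#' infarction) and 0 otherwise; persons without events are all 0.
#'
#' @param purchases table with `person_id`, `date`.
#' @param event_dates data.frame with `person_id`, `event_date` (Date);
#'   multiple events per person allowed, the earliest counts.
#' @return integer vector of flags aligned with `purchases` rows.
#' @export
event_covariate <- function(purchases, event_dates) {
  dt <- as_dt(purchases)
  ev <- as_dt(event_dates)
  if (nrow(ev) == 0L) return(rep(0L, nrow(dt)))
  assert_cols(ev, c("person_id", "event_date"), "event dates")
  first_ev <- ev[, .(event_date = min(event_date)), by = person_id]
  m <- merge(dt[, .(person_id, date, .row = .I)], first_ev,
             by = "person_id", all.x = TRUE, sort = FALSE)
  data.table::setorder(m, .row)
  as.integer(!is.na(m$event_date) & m$date >= m$event_date)
}

#' Cohort descriptives
#'
#' Table-1-style summary: size, female share, purchases on unique dates,
#' age at first purchase, span between first and last purchase, the
#' prescription-diagnosis frequency table, and the share of persons with
#' a hard cardiovascular event during treatment (rounded to whole
#' percent, as reported).
#'
#' @param purchases retained purchase table.
#' @param covariates per-person table with `person_id`, `sex`
#'   (1 = female).
#' @param event_dates optional event table as in [event_covariate()].
#' @return list of summary statistics.
#' @export
cohort_summary <- function(purchases, covariates, event_dates = NULL) {
  dt <- as_dt(purchases)
  cov <- as_dt(covariates)
  per <- dt[, .(n_dates = data.table::uniqueN(date),
                age_first = age_at_purchase[which.min(date)],
                span_years = as.numeric(max(date) - min(date)) / 365.25),
            by = person_id]
  n <- nrow(per)
  cov <- cov[person_id %in% per$person_id]
  n_female <- sum(cov$sex == 1)
  ev <- list(n = 0L, percent = 0)
  if (!is.null(event_dates) && nrow(event_dates)) {
    evd <- as_dt(event_dates)
    with_ev <- merge(per, evd[, .(event_date = min(event_date)), by = person_id],
                     by = "person_id")
    first_last <- dt[, .(first = min(date), last = max(date)), by = person_id]
    with_ev <- merge(with_ev, first_last, by = "person_id")
    k <- with_ev[event_date >= first & event_date <= last, .N]
    ev <- list(n = k, percent = round(100 * k / n))
  }
  diag_tab <- if ("rx_diagnosis" %in% names(dt))
    dt[, .N, by = rx_diagnosis][order(-N)] else NULL
  list(n = n,
       n_female = n_female,
       percent_female = round(100 * n_female / n, 1),
       purchases_mean = mean(per$n_dates), purchases_sd = stats::sd(per$n_dates),
       age_first_mean = mean(per$age_first), age_first_sd = stats::sd(per$age_first),
       span_years_mean = mean(per$span_years), span_years_sd = stats::sd(per$span_years),
       diagnosis_table = diag_tab,
       events = ev)
}

#' Percentage of persons with an event, as reported
#'
#' @param n_events count of persons with an event.
#' @param n cohort size.
#' @param digits rounding digits (default 0, whole percent).
#' @return numeric percentage.
#' @export
event_percent <- function(n_events, n, digits = 0) {
  round(100 * n_events / n, digits)
}
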