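# Purchase-to-dose algorithms: worked examples traced by hand, the
# conservation/invariance properties, and agreement with the plain-loop
# oracle on random purchase lists.

mk_purchases <- function(days, mg = 20, pills = 30, packs = 1,
                         person = "A", drug = "D") {
  data.table::data.table(
    person_id = person, drug_code = drug,
    date = as.Date("2010-01-01") + days,
    mg_per_pill = mg, pills_per_package = pills, n_packages = packs,
    rx_diagnosis = "E78", age_at_purchase = 50)
}

test_that("consolidation merges within 14 days, anchored at the opening date", {
  # days 0 and 10 merge into one purchase dated day 0 with summed mg
  pp <- mk_purchases(c(0, 10), mg = 20, pills = 30)  # 600 mg each
  cons <- consolidate_purchases(pp)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$date, as.Date("2010-01-01"))
  expect_equal(cons$total_mg, 1200)

  # 15 days apart: two purchases (boundary is <= 14)
  expect_equal(nrow(consolidate_purchases(mk_purchases(c(0, 15)))), 2L)
  expect_equal(nrow(consolidate_purchases(mk_purchases(c(0, 14)))), 1L)

  # greedy anchoring: {0,10} merge, 20 opens a new window (20 > 14 after 0)
  cons3 <- consolidate_purchases(mk_purchases(c(0, 10, 20)))
  expect_equal(nrow(cons3), 2L)
  expect_equal(as.numeric(cons3$date - as.Date("2010-01-01")), c(0, 20))

  expect_error(consolidate_purchases(mk_purchases(c(10, 0))), "sorted")
})

test_that("batch splitting uses strictly-more-than-365-day gaps", {
  pp <- mk_purchases(cumsum(c(0, 30, 400, 30)))
  bat <- split_batches(consolidate_purchases(pp))
  expect_equal(bat$batch_id, c(1L, 1L, 2L, 2L))
  expect_true(all(bat$usable))

  # gap of exactly 365 days stays in one batch
  bat365 <- split_batches(consolidate_purchases(mk_purchases(c(0, 365))))
  expect_equal(bat365$batch_id, c(1L, 1L))

  # a single purchase gives zero usable batches
  bat1 <- split_batches(consolidate_purchases(mk_purchases(0)))
  expect_false(any(bat1$usable))
  expect_equal(nrow(daily_doses(bat1)), 0L)
})

test_that("daily dose is dispensed mg over days to the next purchase", {
  # 20 mg x 30 pills, next purchase 30 days later -> 20 mg/day
  pp <- mk_purchases(c(0, 30))
  obs <- daily_doses(split_batches(consolidate_purchases(pp)))
  expect_equal(obs$daily_dose, 20)
  expect_equal(obs$interval_days, 30)

  # 10 mg x 100 pills x 2 packages over 50 days -> 40 mg/day
  pp2 <- mk_purchases(c(0, 50), mg = 10, pills = 100, packs = c(2, 1))
  obs2 <- daily_doses(split_batches(consolidate_purchases(pp2)))
  expect_equal(obs2$daily_dose, 40)

  # k purchases -> k-1 observations; mass conservation
  pp3 <- mk_purchases(cumsum(c(0, 25, 40, 33, 60)), mg = c(10, 20, 40, 20, 10))
  bat3 <- split_batches(consolidate_purchases(pp3))
  obs3 <- daily_doses(bat3)
  expect_equal(nrow(obs3), 4L)
  expect_equal(sum(obs3$daily_dose * obs3$interval_days),
               sum(bat3$total_mg[-5]))
})

test_that("median dose is the median of within-batch medians", {
  pp <- mk_purchases(cumsum(c(0, 20, 20, 20)), mg = c(10, 20, 40, 99))
  # one batch, intervals 20 days: daily doses {15, 30, 60} scaled by 30/20
  obs <- daily_doses(split_batches(consolidate_purchases(pp)))
  expect_equal(median_dose(obs)$median_dose, median(obs$daily_dose))

  # two batches with different medians -> midpoint for the even count
  obs2 <- data.table::data.table(
    person_id = "A", batch_id = c(1L, 1L, 1L, 2L, 2L, 2L),
    daily_dose = c(10, 10, 10, 30, 30, 30))
  expect_equal(median_dose(obs2)$median_dose, 20)

  # constant doses are a fixed point
  obs3 <- data.table::data.table(person_id = "A", batch_id = 1L,
                                 daily_dose = rep(20, 7))
  expect_equal(median_dose(obs3)$median_dose, 20)
})

test_that("maximum dose requires three unique dates and merges sparse top levels", {
  # 40 mg on 5 dates, 80 mg on 2 dates -> level 40
  pp <- rbind(mk_purchases(1:5 * 40, mg = 40), mk_purchases(c(300, 340), mg = 80))
  res <- max_dose(pp, min_carriers = 1)
  expect_equal(res$table$max_dose_level, 40)

  # top strength with too few carriers merges downward
  many <- data.table::rbindlist(lapply(1:30, function(i)
    mk_purchases(1:3 * 30, mg = 40, person = sprintf("p%02d", i))))
  few <- data.table::rbindlist(lapply(31:32, function(i)
    mk_purchases(1:3 * 30, mg = 80, person = sprintf("p%02d", i))))
  res2 <- max_dose(rbind(many, few), min_carriers = 10)
  expect_equal(sort(res2$top_levels), c(40, 80))
  expect_true(all(res2$table$max_dose_binary == 1L))
  expect_false(res2$analyzable)

  # persons with no strength on >= 3 dates are dropped
  res3 <- max_dose(mk_purchases(c(0, 30)), min_carriers = 1)
  expect_equal(res3$dropped, "A")
})

test_that("treatment length converts total pills to years at one pill per day", {
  pp <- mk_purchases(c(0, 100), pills = c(700, 30.5), packs = 1)
  expect_equal(treatment_length(pp)$treatment_length_years, 2)
  expect_equal(nrow(treatment_length(mk_purchases(numeric(0)))), 0L)
  pp2 <- mk_purchases(1:12 * 30, pills = 30, packs = 1)
  expect_equal(treatment_length(pp2)$treatment_length_years, 360 / 365.25)
})

test_that("DDD scaling divides by the drug factor and commutes with the median", {
  obs <- data.table::data.table(person_id = "A", batch_id = 1L,
                                drug_code = "D", daily_dose = c(10, 20, 40))
  fac <- data.table::data.table(drug_code = "D", mg_per_ddd = 20)
  scaled <- ddd_scale(obs, fac)
  expect_equal(scaled$daily_dose, c(0.5, 1, 2))
  expect_equal(median_dose(scaled)$median_dose,
               median_dose(obs)$median_dose / 20)
  expect_error(ddd_scale(obs, fac[0]), "no DDD factor")
})

test_that("mono-drug filter keeps purchases with >= 75% class share in the year ahead", {
  base <- mk_purchases(c(0, 30, 60), drug = "T")
  # only the target drug -> all retained
  expect_equal(nrow(mono_drug_filter(base, "T")), 3L)

  # purchase at day 0 sees 3 target + 1 other dates ahead: share exactly
  # 0.75, boundary retained; later purchases see 2/3 and 1/2 and drop
  mixed <- rbind(mk_purchases(c(0, 30, 60), drug = "T"),
                 mk_purchases(90, drug = "O"))
  kept <- mono_drug_filter(mixed, "T")
  expect_equal(kept$date, as.Date("2010-01-01"))

  # 2 target + 1 other -> 0.667 < 0.75, dropped
  mixed2 <- rbind(mk_purchases(c(0, 30), drug = "T"),
                  mk_purchases(60, drug = "O"))
  expect_equal(nrow(mono_drug_filter(mixed2, "T")), 0L)
})

test_that("log-scale outlier filter is single-pass and symmetric", {
  expect_equal(log_outlier_filter(rep(7, 5))$n_excluded, 0L)

  vals <- c(rep(exp(1), 100), exp(10))
  flt <- log_outlier_filter(vals)
  z <- abs(log(vals) - mean(log(vals))) / sd(log(vals))
  expect_identical(flt$keep, z <= 3)
  expect_equal(flt$n_excluded, 1L)

  # symmetric values give symmetric exclusions
  sym <- exp(c(-10, -1, -0.5, 0, 0.5, 1, 10))
  fs <- log_outlier_filter(sym)
  expect_identical(fs$keep, rev(fs$keep))
})

test_that("translation and scale invariances hold exactly", {
  set.seed(11)
  pp <- random_purchase_list()
  shift <- data.table::copy(pp)[, date := date + 1234]
  a <- run_package_person(pp)
  b <- run_package_person(shift)
  expect_identical(sort(a$daily), sort(b$daily))
  expect_identical(a$median, b$median)
  expect_identical(a$treatment_years, b$treatment_years)

  scaled <- data.table::copy(pp)[, mg_per_pill := mg_per_pill * 3]
  s <- run_package_person(scaled)
  expect_equal(sort(s$daily), sort(a$daily * 3))
  expect_equal(s$median, a$median * 3)
})

test_that("outputs match the plain-loop oracle on random purchase lists", {
  set.seed(42)
  for (i in 1:200) {
    pp <- random_purchase_list()
    got <- run_package_person(pp)
    want <- oracle_person(pp$date, pp$mg_per_pill, pp$pills_per_package,
                          pp$n_packages)
    expect_equal(sort(got$daily), sort(want$daily), tolerance = 0)
    expect_equal(got$median, want$median, tolerance = 0)
    expect_equal(got$treatment_years, want$treatment_years, tolerance = 0)
  }
})

test_that("median dose is unchanged by duplicating one batch at odd batch counts", {
  obs <- data.table::data.table(
    person_id = "A", batch_id = rep(1:3, each = 3),
    daily_dose = c(10, 12, 14, 20, 22, 24, 30, 32, 34))
  m0 <- median_dose(obs)$median_dose
  dup <- rbind(obs, data.table::copy(obs[batch_id == 2])[, batch_id := 4L])
  # 4 batches with medians {12, 22, 32, 22}: median still 22
  expect_equal(median_dose(dup)$median_dose, m0)
})
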