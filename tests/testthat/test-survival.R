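make_events <- function(time, event, ...) {
  n <- length(time)
  tibble::tibble(
    restoration = paste0("r", seq_len(n)), patient = paste0("p", seq_len(n)),
    time_years = time, event = event, failure_kind = NA_character_,
    gender = "female", age_ge_40 = FALSE, posterior = FALSE,
    multisurface = FALSE, ...)
}

test_that("event-table construction applies the correlate rules", {
  cohort <- tibble::tibble(
    restoration = c("r1", "r2"), patient = c("ex:patient_A", "ex:patient_B"),
    restoration_date = as.Date(c("2001-06-01", "2005-01-01")),
    restoration_class = "ohd:resin_filling_restoration",
    tooth = c(19L, 8L), surfaces = c("MOD", "M"),
    outcome = c("failed", "censored"),
    outcome_date = as.Date(c("2004-06-01", "2008-01-01")),
    failure_kind = c("refill", NA))
  demo <- tibble::tibble(patient = c("ex:patient_A", "ex:patient_B"),
                         birth_date = as.Date(c("1950-01-01", "1980-01-01")),
                         gender = c("female", "male"))
  ev <- build_event_table(cohort, demo)
  expect_identical(ev$posterior, c(TRUE, FALSE))
  expect_identical(ev$multisurface, c(TRUE, FALSE))
  expect_identical(ev$age_ge_40, c(TRUE, FALSE))
  expect_identical(ev$event, c(1L, 0L))
  expect_equal(ev$time_years[1], as.numeric(as.Date("2004-06-01") -
                                              as.Date("2001-06-01")) / 365.25)

  # zero-duration and missing-demographics records are dropped with warnings
  cohort0 <- cohort
  cohort0$outcome_date[1] <- cohort0$restoration_date[1]
  expect_warning(ev0 <- build_event_table(cohort0, demo), "zero-duration")
  expect_identical(nrow(ev0), 1L)
  demo_na <- demo; demo_na$birth_date[2] <- NA
  expect_warning(ev2 <- build_event_table(cohort, demo_na), "missing birth date")
  expect_identical(nrow(ev2), 1L)
})

test_that("event-table covariates agree with generator ground truth", {
  pr <- generate_practice(small_config(n_patients = 60, seed = 21))
  store <- materialize_pipeline(pr)
  ev <- build_event_table(extract_restoration_cohort(store),
                          patient_demographics(store))
  gt <- pr$ground_truth |>
    dplyr::filter(ada_code %in% ORACLE_RESIN_CODES, has_followup) |>
    dplyr::mutate(patient = paste0("ex:patient_", patient_id))
  # match records one-to-one on patient + covariate-defining fields
  key_ev <- ev |>
    dplyr::transmute(patient, male = gender == "male", age_ge_40,
                     posterior, multisurface) |>
    dplyr::arrange(dplyr::across(dplyr::everything()))
  key_gt <- gt |>
    dplyr::transmute(patient, male, age_ge_40, posterior,
                     multisurface = nchar(surfaces) > 1) |>
    dplyr::arrange(dplyr::across(dplyr::everything()))
  expect_equal(as.data.frame(key_ev), as.data.frame(key_gt))
})

test_that("the product-limit estimator matches hand computation exactly", {
  # [5, 8+, 12]: S = 2/3 on [5, 12), 0 at 12; median 12
  km <- km_fit(make_events(c(5, 8, 12), c(1L, 0L, 1L)))
  expect_equal(km$curve$time, c(5, 12))
  expect_equal(km$curve$surv, c(2 / 3, 0), tolerance = 1e-12)
  expect_equal(km$medians$median, 12)

  # no censoring: the KM curve is the empirical survivor function
  tms <- c(1, 2, 3, 4, 6)
  km2 <- km_fit(make_events(tms, rep(1L, 5)))
  expect_equal(km2$curve$surv, 1 - seq_len(5) / 5, tolerance = 1e-12)
  expect_equal(km2$medians$median, 3)

  # all censored: survival stays 1, median undefined
  km3 <- km_fit(make_events(c(2, 5, 9), rep(0L, 3)))
  expect_identical(nrow(km3$curve), 0L)
  expect_true(is.na(km3$medians$median))

  expect_error(km_fit(make_events(numeric(0), integer(0))), "no event records")
})

test_that("KM with ties and censoring matches the independent oracle and survfit", {
  set.seed(33)
  time <- round(rexp(120, 0.2), 1) + 0.1
  event <- rbinom(120, 1, 0.6)
  km <- km_fit(make_events(time, event))
  hand <- oracle_km(time, event)
  expect_equal(km$curve$time, hand$time)
  expect_equal(km$curve$surv, hand$surv, tolerance = 1e-12)

  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  sf_at <- summary(sf, times = km$curve$time)
  expect_equal(km$curve$surv, sf_at$surv, tolerance = 1e-9)
  expect_equal(km$curve$se, sf_at$std.err, tolerance = 1e-9)

  # grouped fit partitions the records
  ev <- make_events(time, event)
  ev$gender <- rep(c("female", "male"), 60)
  kmg <- km_fit(ev, group_by = "gender")
  expect_setequal(kmg$medians$group, c("female", "male"))
  expect_identical(sum(kmg$medians$n), 120L)
})

test_that("percent hazard change rendering is involution-consistent", {
  expect_identical(render_hazard_difference(1), "0% change")
  expect_identical(render_hazard_difference(0.77), "23% decrease")
  expect_identical(render_hazard_difference(1.16), "16% increase")
  expect_identical(render_hazard_difference(1.40), "40% increase")
  expect_identical(render_hazard_difference(0.88), "12% decrease")
  # decrease(x%) <-> HR = 1 - x/100
  for (x in c(5, 23, 50)) {
    expect_identical(render_hazard_difference(1 - x / 100),
                     paste0(x, "% decrease"))
  }
})

test_that("the Cox fit reports effects and a univariate mode", {
  set.seed(10)
  n <- 800
  ev <- make_events(numeric(n), integer(n))
  ev$gender <- sample(c("female", "male"), n, TRUE)
  ev$posterior <- sample(c(TRUE, FALSE), n, TRUE)
  ev$age_ge_40 <- sample(c(TRUE, FALSE), n, TRUE)
  ev$multisurface <- sample(c(TRUE, FALSE), n, TRUE)
  lp <- log(1.5) * (ev$gender == "male")
  ev$time_years <- rexp(n, 0.1 * exp(lp))
  ev$event <- as.integer(ev$time_years < 8)
  ev$time_years <- pmin(ev$time_years, 8)
  fit <- cox_fit(ev)
  expect_setequal(fit$table$term,
                  c("male", "age_40plus", "posterior", "multisurface"))
  mrow <- fit$table[fit$table$term == "male", ]
  expect_true(mrow$hr_lower <= 1.5 && 1.5 <= mrow$hr_upper)
  expect_match(mrow$label, "increase")

  uni <- cox_fit(ev, mode = "univariate")
  expect_identical(nrow(uni$table), 4L)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p.value", "hr") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, n)
})

test_that("Cox recovery: generated effects are covered by their CIs across seeds", {
  # parameter-recovery invariant at reduced per-seed size; events come from
  # the generator's ground truth (the full-pipeline route is covered by the
  # acceptance suite)
  true_beta <- log(c(male = 1.16, age_40plus = 1.40,
                     posterior = 0.77, multisurface = 0.88))
  n_seeds <- 10
  covered <- matrix(NA, n_seeds, 4)
  for (s in seq_len(n_seeds)) {
    cfg <- generator_config(n_patients = 1500, seed = 500 + s,
                            early_failure_weight = 0)
    gt <- generate_practice(cfg)$ground_truth |>
      dplyr::filter(ada_code %in% ORACLE_RESIN_CODES, has_followup,
                    observed_time_years > 0)
    ev <- tibble::tibble(
      restoration = paste0("r", seq_len(nrow(gt))), patient = gt$patient_id,
      time_years = gt$observed_time_years, event = gt$observed_event,
      failure_kind = gt$failure_kind,
      gender = ifelse(gt$male, "male", "female"),
      age_ge_40 = gt$age_ge_40, posterior = gt$posterior,
      multisurface = gt$multisurface)
    tab <- cox_fit(ev)$table
    covered[s, ] <- tab$hr_lower <= exp(true_beta)[tab$term] &
      exp(true_beta)[tab$term] <= tab$hr_upper
  }
  # ~95% nominal coverage; allow two misses per correlate over ten seeds
  expect_true(all(colSums(covered) >= 8))
})

test_that("the smoothed hazard is flat for exponential data and finite in corners", {
  set.seed(4)
  ev <- make_events(rexp(3000, 0.5), rep(1L, 3000))
  hz <- hazard_rate(ev, bandwidth = 1)
  interior <- hz$curve[hz$curve$time > 1.5 & hz$curve$time < 4, ]
  expect_equal(mean(interior$hazard), 0.5, tolerance = 0.1)
  expect_true(all(hz$curve$hazard >= 0))

  single <- hazard_rate(make_events(c(3, 7), c(1L, 0L)), bandwidth = 1)
  expect_true(all(is.finite(single$curve$hazard)))
  expect_error(hazard_rate(ev, bandwidth = 0), "positive")
  expect_error(hazard_rate(make_events(5, 0L)), "at least one failure")
})

test_that("the early-failure mixture produces elevated early hazard", {
  cfg <- generator_config(n_patients = 3000, seed = 61,
                          early_failure_weight = 0.3,
                          early_failure_mean_years = 0.5)
  gt <- generate_practice(cfg)$ground_truth |>
    dplyr::filter(has_followup, observed_time_years > 0)
  ev <- make_events(gt$observed_time_years, gt$observed_event)
  hz <- hazard_rate(ev, bandwidth = 1)
  expect_gt(mean_hazard(hz, 0, 2) / mean_hazard(hz, 2, 5), 1)
})

test_that("correlate summaries partition events and patients correctly", {
  ev <- make_events(c(1, 2, 3), c(1L, 0L, 0L))
  ev$patient <- c("pA", "pA", "pB")
  tab <- summarize_by_correlate(ev)
  fem <- tab[tab$group == "Gender female", ]
  expect_identical(fem$n_patients, 2L)
  expect_identical(fem$n_events, 3L)
  expect_identical(fem$n_failures, 1L)

  pr <- generate_practice(small_config(n_patients = 80, seed = 13))
  store <- materialize_pipeline(pr)
  ev2 <- build_event_table(extract_restoration_cohort(store),
                           patient_demographics(store))
  tab2 <- summarize_by_correlate(ev2)
  # per correlate, groups partition events and failures
  sums <- tab2 |>
    dplyr::group_by(correlate) |>
    dplyr::summarise(ev = sum(n_events), fa = sum(n_failures))
  expect_true(all(sums$ev == nrow(ev2)))
  expect_true(all(sums$fa == sum(ev2$event)))
  # and match a brute-force group-by on the event table
  expect_identical(
    tab2$n_events[tab2$group == "Posterior tooth"],
    sum(ev2$posterior))
  expect_identical(
    tab2$n_failures[tab2$group == "Single surface"],
    sum(ev2$event[!ev2$multisurface]))
})

test_that("plot methods return ggplot objects", {
  set.seed(2)
  ev <- make_events(rexp(60, 0.2), rbinom(60, 1, 0.7))
  ev$gender <- sample(c("female", "male"), 60, TRUE)
  expect_s3_class(autoplot(km_fit(ev, group_by = "gender")), "ggplot")
  expect_s3_class(autoplot(hazard_rate(ev)), "ggplot")
  ev$posterior <- sample(c(TRUE, FALSE), 60, TRUE)
  ev$age_ge_40 <- sample(c(TRUE, FALSE), 60, TRUE)
  ev$multisurface <- sample(c(TRUE, FALSE), 60, TRUE)
  expect_s3_class(autoplot(cox_fit(ev)), "ggplot")
})
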