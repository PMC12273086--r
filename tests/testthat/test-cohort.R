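test_that("the minimal 5+5 pattern qualifies with a window anchored at day 0", {
  v <- visits_of(c(0, 30, 60, 90, 120), cgi = c(4L, 5L, 4L, 3L, 4L),
                 gaf = c(60L, 55L, 65L, 60L, 50L))
  w <- select_window(v)
  expect_identical(w$window_start, 0L)
  expect_identical(w$window_end, 179L)
  expect_length(w$cgi_series$value, 5)
  expect_length(w$gaf_series$value, 5)
})

test_that("the inclusion rule is a conjunction of both rating counts", {
  # 4 CGI-S but 9 GAF in every possible 180-day span: never qualifies
  v <- visits_of(seq(0, 160, by = 20),
                 cgi = c(4L, 5L, 4L, 3L, NA, NA, NA, NA, NA),
                 gaf = rep(60L, 9))
  expect_null(select_window(v))
})

test_that("an early hospitalisation excludes every candidate window", {
  days <- seq(0, 200, by = 10)
  v <- visits_of(days, cgi = rep(4L, length(days)),
                 gaf = rep(60L, length(days)))
  # without the hospitalisation a window exists from day 0
  expect_identical(select_window(v)$window_start, 0L)
  # hospitalisation on day 100: every candidate start s has end s+179 >= 100
  expect_null(select_window(v, first_hosp = 100L))
  # exhaustive-scan oracle over all conceivable starts agrees
  qualifies <- vapply(0:250, function(s) {
    inw <- days >= s & days <= s + 179
    sum(inw) >= 5 && (s + 179) < 100
  }, logical(1))
  expect_false(any(qualifies))
})

test_that("the earliest qualifying window is returned", {
  # sparse early ratings, dense later: day 0 cannot anchor a window, day 40
  # can
  days <- c(0L, 40L, 50L, 60L, 70L, 80L, 300L)
  v <- visits_of(days, cgi = c(4L, 4L, 5L, 4L, 3L, 4L, 5L),
                 gaf = c(60L, 60L, 55L, 65L, 60L, 50L, 60L))
  w <- select_window(v)
  expect_identical(w$window_start, 0L)  # 0..179 holds 6 of each: qualifies
  v2 <- v[v$date != 0L, ]
  expect_identical(select_window(v2)$window_start, 40L)
})

test_that("outcomes follow the event/censor rules", {
  v <- visits_of(c(0, 30, 60, 90, 120), cgi = rep(4L, 5), gaf = rep(60L, 5))
  w <- select_window(v)
  # hospitalisation 30 days after window end -> event at 30
  out <- build_outcome(w, v, hosp_dates = w$window_end + 30L)
  expect_identical(out, list(time = 30L, event = TRUE))
  # no hospitalisation, last visit 90 days after window end -> censored at 90
  v2 <- rbind(v, visits_of(w$window_end + 90L, cgi = 4L, gaf = 60L))
  expect_identical(build_outcome(w, v2), list(time = 90L, event = FALSE))
  # visits continuing 400 days after the end -> capped at 180
  v3 <- rbind(v, visits_of(w$window_end + 400L, cgi = 4L, gaf = 60L))
  expect_identical(build_outcome(w, v3), list(time = 180L, event = FALSE))
  # last visit inside the window -> censor time floored at 0
  expect_identical(build_outcome(w, v), list(time = 0L, event = FALSE))
  # hospitalisation beyond 180 days is not an event
  out4 <- build_outcome(w, v2, hosp_dates = w$window_end + 181L)
  expect_false(out4$event)
  # hospitalisation on/before the window end is a consistency error
  expect_error(build_outcome(w, v, hosp_dates = w$window_end),
               "window selection")
})

test_that("cohort construction partitions patients and is deterministic", {
  sim <- simulate_dataset(sim_config(n_patients = 2000, seed = 21,
                                     baseline_180d_risk = 0.05,
                                     org_logit_sd = 0.3))
  coh <- build_cohort(sim$dataset)
  expect_identical(nrow(coh$table) + nrow(coh$exclusions), 2000L)
  expect_true(all(coh$table$time >= 0 & coh$table$time <= 180))
  expect_true(all(coh$table$time[coh$table$event] >= 1))
  # no selected window overlaps or follows a hospitalisation
  first_hosp <- tapply(sim$dataset$hospitalisations$date,
                       sim$dataset$hospitalisations$patient_id, min)
  m <- match(names(first_hosp), coh$table$patient_id)
  expect_true(all(coh$table$window_end[m[!is.na(m)]] <
                    first_hosp[!is.na(m)]))
  expect_identical(build_cohort(sim$dataset)$table, coh$table)
})

test_that("delaying hospitalisations weakly grows the cohort", {
  sim <- simulate_dataset(sim_config(n_patients = 1500, seed = 9,
                                     baseline_180d_risk = 0.2))
  n0 <- nrow(build_cohort(sim$dataset)$table)
  shifted <- sim$dataset
  shifted$hospitalisations$date <- shifted$hospitalisations$date + 400L
  n1 <- nrow(build_cohort(shifted)$table)
  expect_gte(n1, n0)
})

test_that("a saturated dataset includes every patient", {
  days <- seq(0, 160, by = 40)
  mk <- function(pid) visits_of(days, cgi = rep(3L, 5), gaf = rep(70L, 5),
                                pid = pid)
  pats <- tiny_dataset()$patients
  ds <- ews_dataset(pats, do.call(rbind, lapply(pats$patient_id, mk)),
                    data.frame(patient_id = character(0),
                               date = integer(0)),
                    tiny_dataset()$splits)
  coh <- build_cohort(ds)
  expect_identical(nrow(coh$table), nrow(pats))
  expect_identical(nrow(coh$exclusions), 0L)
})
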