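test_that("concordance matches its definition on canonical cases", {
  tt <- c(10, 20, 30, 40, 50)
  ev <- rep(TRUE, 5)
  expect_equal(c_index(5:1, tt, ev), 1)        # perfect discrimination
  expect_equal(c_index(1:5, tt, ev), 0)        # perfectly wrong
  expect_equal(c_index(rep(0.3, 5), tt, ev), 0.5)  # all risk ties
  expect_error(c_index(c(1, 2), c(5, 9), c(FALSE, FALSE)),
               "no comparable pairs")
})

test_that("concordance equals brute-force pair enumeration", {
  # 6-patient mixed-censoring fixture
  risks <- c(0.9, 0.2, 0.5, 0.5, 0.1, 0.7)
  tt <- c(15, 180, 60, 60, 120, 30)
  ev <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  expect_equal(c_index(risks, tt, ev), cindex_oracle(risks, tt, ev),
               tolerance = 1e-12)
  # and on random data with ties in risks and times
  set.seed(31)
  for (rep in 1:20) {
    n <- 30
    r <- round(runif(n), 1)
    t2 <- sample(1:50, n, replace = TRUE)
    e2 <- runif(n) < 0.5
    if (!any(e2)) e2[1] <- TRUE
    expect_equal(c_index(r, t2, e2), cindex_oracle(r, t2, e2),
                 tolerance = 1e-12)
  }
})

test_that("concordance flips under risk negation without ties", {
  set.seed(5)
  r <- runif(40)
  tt <- sample(1:1000, 40)
  ev <- runif(40) < 0.6
  ev[1] <- TRUE
  expect_equal(c_index(r, tt, ev) + c_index(-r, tt, ev), 1)
})

test_that("operating-point metrics repin predictive values by Bayes' rule", {
  # constructed so that flagging the top 9/110 gives se = 0.5, sp = 0.96
  n <- 110
  risks <- seq(n, 1) / n
  y <- rep(FALSE, n)
  y[1:5] <- TRUE          # flagged events (top 9 flagged)
  y[c(20, 40, 60, 80, 100)] <- TRUE  # missed events
  tm <- threshold_metrics(risks, y, flag_fraction = 9 / 110,
                          prespecified_incidence = 0.02)
  expect_equal(tm$n_flagged, 9)
  expect_equal(tm$sensitivity, 0.5)
  expect_equal(tm$specificity, 0.96)
  expect_equal(tm$ppv, 0.01 / (0.01 + 0.0392), tolerance = 1e-12)
  expect_equal(tm$npv, 0.96 * 0.98 / (0.5 * 0.02 + 0.96 * 0.98),
               tolerance = 1e-12)
})

test_that("a perfect classifier attains PPV = NPV = 1 at any incidence", {
  risks <- c(rep(0.9, 5), rep(0.1, 95))
  y <- c(rep(TRUE, 5), rep(FALSE, 95))
  tm <- threshold_metrics(risks, y, flag_fraction = 0.05,
                          prespecified_incidence = 0.003)
  expect_equal(tm$sensitivity, 1)
  expect_equal(tm$specificity, 1)
  expect_equal(tm$ppv, 1)
  expect_equal(tm$npv, 1)
})

test_that("repinning at the sample prevalence reproduces raw counts", {
  set.seed(12)
  n <- 400
  risks <- runif(n)
  y <- runif(n) < risks  # no censoring
  k <- floor(0.05 * n)
  flagged <- order(-risks)[1:k]
  tm <- threshold_metrics(risks, y, flag_fraction = 0.05,
                          prespecified_incidence = mean(y))
  expect_equal(tm$ppv, mean(y[flagged]), tolerance = 1e-12)
  expect_equal(tm$npv, mean(!y[-flagged]), tolerance = 1e-12)
})

test_that("degenerate operating points are rejected", {
  expect_error(threshold_metrics(runif(10), rep(TRUE, 10),
                                 flag_fraction = 0.05), "zero patients")
  expect_error(threshold_metrics(rep(0.2, 100), rep(TRUE, 100)),
               "constant")
})

test_that("the Brier score has its closed-form values", {
  y <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(brier_score(as.numeric(y), y), 0)      # perfect foresight
  expect_equal(brier_score(rep(0.5, 4), y), 0.25)     # uninformative
  p <- 0.3
  y2 <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_equal(brier_score(rep(p, 10), y2), p * (1 - p))
})

test_that("calibration reduces to event proportions without censoring", {
  set.seed(8)
  n <- 1000
  risks <- runif(n, 0.05, 0.95)
  y <- runif(n) < risks
  cal <- calibration_curve(risks, time = rep(180, n), event = y,
                           bins = 10, B = 50, seed = 2)
  expect_equal(nrow(cal), 10)
  expect_equal(sum(cal$n), n)
  for (b in 1:10) {
    in_b <- rank(risks, ties.method = "first") > (b - 1) * 100 &
      rank(risks, ties.method = "first") <= b * 100
    expect_equal(cal$observed[b], mean(y[in_b]))
  }
  # doubled risks overestimate in the top bins
  cal2 <- calibration_curve(pmin(1, 2 * risks), rep(180, n), y,
                            bins = 10, B = 20, seed = 2)
  expect_true(all(cal2$predicted[8:10] > cal2$observed[8:10]))
})

test_that("subgroup evaluation respects membership rules", {
  fx <- fixture_pipeline()
  f <- fx$features
  risks <- f$functional_severity  # any deterministic score works here
  sg <- subgroup_cindices(risks, f$time, f$event, f)
  expect_identical(nrow(sg$diagnosis), 7L)
  expect_identical(sg$race$subgroup, c("white", "non_white"))
  # non-exclusive membership: counts sum to more than n
  expect_gt(sum(sg$diagnosis$n), nrow(f))
  # unknown race contributes to neither race row
  expect_equal(sum(sg$race$n), sum(f$race_group != "unknown"))
  # the trivial subgroup equals the overall concordance
  all_in <- f
  all_in$dx_mdd <- TRUE
  sg2 <- subgroup_cindices(risks, f$time, f$event, all_in)
  expect_equal(sg2$diagnosis$c_index[sg2$diagnosis$subgroup == "MDD"],
               c_index(risks, f$time, f$event))
})

test_that("the fairness permutation test has the documented support", {
  set.seed(44)
  n <- 500
  race <- sample(c("white", "non_white"), n, replace = TRUE)
  tt <- sample(1:180, n, replace = TRUE)
  ev <- runif(n) < 0.3
  r <- runif(n)
  out <- permutation_fairness_test(r, tt, ev, race, P = 100, seed = 9)
  expect_true(out$p_value %in% ((1:101) / 101))
  # determinism under the seed
  out2 <- permutation_fairness_test(r, tt, ev, race, P = 100, seed = 9)
  expect_identical(out, out2)
  # unknown race is excluded before grouping
  race3 <- race; race3[1:50] <- "unknown"
  out3 <- permutation_fairness_test(r, tt, ev, race3, P = 20, seed = 1)
  expect_true(is.finite(out3$delta))
  expect_error(permutation_fairness_test(r, tt, ev,
                                         rep("white", n), P = 10, seed = 1),
               "non-empty")
})

test_that("extreme group separation attains the minimum p-value", {
  set.seed(6)
  n <- 2000
  race <- rep(c("white", "non_white"), each = n / 2)
  tt <- sample(1:20000, n)  # distinct times: no 0.5-credit risk ties
  ev <- runif(n) < 0.5
  r <- numeric(n)
  r[race == "white"] <- -tt[race == "white"]        # perfect ranking
  r[race == "non_white"] <- runif(n / 2)            # noise
  out <- permutation_fairness_test(r, tt, ev, race, P = 100, seed = 3)
  expect_equal(out$c_white, 1)
  expect_equal(out$p_value, 1 / 101)
})

test_that("paired model comparison behaves at the identity and under signal", {
  set.seed(17)
  n <- 1500
  tt <- sample(1:180, n, replace = TRUE)
  ev <- runif(n) < 0.4
  informative <- -tt + rnorm(n, 0, 20)
  noise <- runif(n)
  same <- compare_models_bootstrap(informative, informative, tt, ev,
                                   B = 50, seed = 2)
  expect_equal(same$delta, 0)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)
  cmp <- compare_models_bootstrap(informative, noise, tt, ev,
                                  B = 200, seed = 2)
  expect_gt(cmp$delta, 0)
  expect_gt(cmp$ci[1], 0)       # CI excludes zero
  expect_lt(cmp$p_value, 0.05)
  cmp2 <- compare_models_bootstrap(informative, noise, tt, ev,
                                   B = 200, seed = 2)
  expect_identical(cmp$ci, cmp2$ci)
  expect_error(compare_models_bootstrap(informative, noise[-1], tt, ev))
})

test_that("ROC curves span (0,0) to (1,1)", {
  set.seed(3)
  r <- runif(200)
  y <- runif(200) < r
  roc <- roc_points(r, y)
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})
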