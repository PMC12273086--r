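# build a minimal feature table with the full covariate complement around
# externally supplied metric columns
synthetic_features <- function(n, time, event, overrides = list(),
                               seed = 1) {
  set.seed(seed)
  f <- data.frame(
    patient_id = sprintf("s%04d", seq_len(n)),
    clinical_severity = runif(n, 2, 6),
    clinical_instability = runif(n, 0, 0.5),
    functional_severity = runif(n, 20, 70),
    functional_instability = runif(n, 0, 3),
    age = runif(n, 18, 70),
    gender = sample(c("female", "male"), n, replace = TRUE),
    org_id = "o1", race_group = "white",
    stringsAsFactors = FALSE)
  for (dx in psyews:::DX_COLS) f[[dx]] <- FALSE
  f$dx_mdd <- TRUE
  f$dx_bd <- runif(n) < 0.3
  f$org_logit_rate <- -4
  f$time <- time
  f$event <- event
  for (nm in names(overrides)) f[[nm]] <- overrides[[nm]]
  f
}

test_that("model specs carry the documented covariate sets", {
  expect_length(model_spec("unadjusted")$covariates, 14)
  expect_length(model_spec("adjusted")$covariates, 15)
  expect_length(model_spec("baseline")$covariates, 10)
  expect_length(model_spec("clinical_benchmark")$covariates, 11)
  expect_true("org_logit_rate" %in% model_spec("adjusted")$covariates)
  expect_false("org_logit_rate" %in% model_spec("unadjusted")$covariates)
  expect_error(model_spec("ridge"))
})

test_that("fitting requires events and rejects collinear covariates", {
  f <- synthetic_features(50, time = rep(180, 50), event = rep(FALSE, 50))
  expect_error(fit_ews_model(f, "unadjusted"), "no events")
  f2 <- synthetic_features(200, time = sample(1:180, 200, TRUE),
                           event = runif(200) < 0.3)
  # duplicate information: functional severity an exact copy of clinical
  f2$functional_severity <- f2$clinical_severity
  expect_error(suppressMessages(fit_ews_model(f2, "unadjusted",
                                              select_sqrt = FALSE)),
               "collinear")
})

test_that("predicted risks respect the baseline identity and bounds", {
  fx <- fixture_pipeline()
  deriv <- fx$features[fx$features$split == "derivation", ]
  m <- suppressMessages(fit_ews_model(deriv, "unadjusted"))
  risks <- predict_risk(m, deriv)
  expect_true(all(risks >= 0 & risks <= 1))
  # a patient sitting at the derivation means of every covariate in the
  # model has linear predictor 0 and risk 1 - S0(180)
  base <- deriv[1, ]
  for (v in psyews:::SCALED_PREDICTORS) {
    key <- if (v %in% psyews:::INSTABILITY_PREDICTORS &&
               isTRUE(m$sqrt_flags[[v]])) paste0("sqrt_", v) else v
    raw <- m$scaling$center[[key]]
    base[[v]] <- if (startsWith(key, "sqrt_")) raw^2 else raw
  }
  base$gender <- "female"
  for (dx in psyews:::DX_COLS) base[[dx]] <- FALSE
  expect_equal(predict_risk(m, base), 1 - m$s0_180, tolerance = 1e-12)
  # monotonicity in a positively weighted predictor
  b <- m$coefficients[["functional_severity_z"]]
  stepped <- base
  stepped$functional_severity <- base$functional_severity +
    sign(b) * m$scaling$scale[["functional_severity"]]
  expect_gt(predict_risk(m, stepped), predict_risk(m, base))
  expect_error(predict_risk(m, base[, setdiff(names(base), "age")]))
})

test_that("models survive a save/load round trip bit-for-bit", {
  fx <- fixture_pipeline()
  deriv <- fx$features[fx$features$split == "derivation", ]
  m <- suppressMessages(fit_ews_model(deriv, "adjusted"))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$scaling$center, m$scaling$center)
  expect_equal(back$s0_180, m$s0_180)
  expect_identical(back$spec$name, m$spec$name)
  expect_identical(predict_risk(back, deriv), predict_risk(m, deriv))
  # tampered schema and version are rejected
  obj <- jsonlite::read_json(path)
  obj$coefficients <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(load_model(path), "missing field")
  obj$coefficients <- list(x = 1)
  obj$format_version <- 99
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(load_model(path), "version")
})

test_that("adjusted collapses to unadjusted when org rates are constant", {
  fx <- fixture_pipeline()
  deriv <- fx$features[fx$features$split == "derivation", ]
  deriv$org_logit_rate <- -4.2
  expect_message(
    m_adj <- fit_ews_model(deriv, "adjusted", select_sqrt = FALSE),
    "org_logit_rate")
  m_un <- suppressMessages(fit_ews_model(deriv, "unadjusted",
                                         select_sqrt = FALSE))
  expect_equal(m_adj$coefficients, m_un$coefficients)
  expect_equal(m_adj$s0_180, m_un$s0_180)
})

test_that("partial likelihood is at a local maximum", {
  fx <- fixture_pipeline()
  deriv <- fx$features[fx$features$split == "derivation", ]
  m <- suppressMessages(fit_ews_model(deriv, "unadjusted",
                                      select_sqrt = FALSE))
  fit <- m$cox_fit
  X <- fit$x
  y <- fit$y
  ll <- function(beta) {
    init <- survival::coxph(survival::Surv(y[, 1], y[, 2]) ~ X,
                            init = beta, ties = "efron",
                            control = survival::coxph.control(iter.max = 0))
    init$loglik[2]
  }
  b_hat <- unname(m$coefficients)
  set.seed(1)
  for (k in 1:5) {
    expect_gte(ll(b_hat), ll(b_hat + rnorm(length(b_hat), 0, 0.05)))
  }
})

test_that("AIC selects the sqrt transform when the truth is sqrt-linear", {
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    n <- 2500
    inst <- runif(n, 0, 4)^2           # skewed instability
    z <- scale(sqrt(inst))[, 1]        # hazard linear in sqrt(instability)
    rate <- 0.004 * exp(1.0 * z)
    t_ev <- rexp(n, rate)
    f <- synthetic_features(n, time = pmin(ceiling(t_ev), 180),
                            event = t_ev <= 180, seed = seed + 100,
                            overrides = list(clinical_instability = inst))
    flags <- suppressMessages(
      select_transforms(f, model_spec("unadjusted"), fit_scaling(f)))
    hits <- hits + flags[["clinical_instability"]]
  }
  expect_gte(hits, 3)
})

test_that("transform selection keeps raw variables on an AIC tie", {
  # two identical candidate designs: sqrt of a 0/1-free constant-ish metric
  # cannot strictly lower AIC when the variable is already its own sqrt
  f <- synthetic_features(400, time = sample(1:180, 400, TRUE),
                          event = runif(400) < 0.25, seed = 5)
  f$clinical_instability <- as.numeric(f$clinical_instability > 0.25)
  f$clinical_instability[1] <- 0.5  # avoid zero-SD sqrt degeneracies
  sc <- fit_scaling(f)
  flags <- suppressMessages(
    select_transforms(f, model_spec("unadjusted"), sc))
  # sqrt of a {0, 0.5, 1} variable is a monotone recoding; AIC changes are
  # tiny and the raw form is kept unless strictly improved
  expect_type(flags, "logical")
  expect_named(flags, c("clinical_instability", "functional_instability"))
})

test_that("the proportional-hazards test reports sensible bookkeeping", {
  fx <- fixture_pipeline()
  deriv <- fx$features[fx$features$split == "derivation", ]
  m <- suppressMessages(fit_ews_model(deriv, "unadjusted"))
  ph <- test_proportional_hazards(m)
  expect_identical(ph$covariate[nrow(ph)], "GLOBAL")
  expect_equal(ph$df[nrow(ph)], sum(ph$df[-nrow(ph)]))
  expect_true(all(ph$p >= 0 & ph$p <= 1))
  # reloaded models have no residuals to test
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  expect_error(test_proportional_hazards(load_model(path)), "refit")
})

test_that("a reversing covariate effect is flagged as non-proportional", {
  set.seed(7)
  n <- 4000
  x <- rnorm(n)
  # effect +1 before t=90, -1 after: a strong proportionality violation
  t1 <- rexp(n, 0.01 * exp(x))
  t2 <- 90 + rexp(n, 0.01 * exp(-x))
  tt <- ifelse(t1 <= 90, t1, t2)
  f <- synthetic_features(n, time = pmin(tt, 180), event = tt <= 180,
                          overrides = list(clinical_severity = x), seed = 8)
  m <- suppressMessages(fit_ews_model(f, "unadjusted", select_sqrt = FALSE))
  ph <- test_proportional_hazards(m)
  expect_lt(ph$p[ph$covariate == "clinical_severity_z"], 0.05)
})
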