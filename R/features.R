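#' Mean severity of a rating series
#'
#' Unweighted arithmetic mean of all ratings inside the measurement window
#' (the inter-visit spacing does not weight the mean).
#'
#' @param values Numeric vector of ratings (at least one).
#' @return The mean rating.
#' @export
mean_severity <- function(values) {
  if (length(values) < 1 || any(is.na(values)))
    stop("mean_severity: needs at least one non-missing rating", call. = FALSE)
  mean(values)
}

#' Invert the GAF scale
#'
#' Maps GAF (1-100, higher = better functioning) to an impairment scale
#' (0-99, higher = more impairment) by \code{100 - gaf}.
#'
#' @param gaf Numeric GAF value(s) in [1, 100].
#' @return \code{100 - gaf}.
#' @export
invert_gaf <- function(gaf) {
  if (any(is.na(gaf) | gaf < 1 | gaf > 100))
    stop("invert_gaf: GAF must be in [1, 100]", call. = FALSE)
  100 - gaf
}

#' Time-adjusted root mean square of successive differences (tRMSSD)
#'
#' Visit-to-visit instability of an irregularly sampled rating series. The
#' default (\code{method = "rate"}) is the root mean square of per-day rates
#' of change,
#' \deqn{\sqrt{\frac{1}{n-1}\sum_{i=1}^{n-1}
#'       \left(\frac{x_{i+1}-x_i}{t_{i+1}-t_i}\right)^2},}
#' in score units per day. \code{method = "sqrt_dt"} divides the squared
#' difference by the gap instead,
#' \eqn{\sqrt{\mathrm{mean}(\Delta x^2/\Delta t)}}, in score units per
#' square-root day. Same-day duplicate ratings are averaged into a single
#' observation before differencing (a zero gap is undefined under either
#' formula).
#'
#' @param days Integer/numeric observation days, non-decreasing.
#' @param values Ratings at those days.
#' @param method \code{"rate"} (default) or \code{"sqrt_dt"}.
#' @return Non-negative instability value; 0 for a constant series.
#' @export
trmssd <- function(days, values, method = c("rate", "sqrt_dt")) {
  method <- match.arg(method)
  if (length(days) != length(values))
    stop("trmssd: days and values must have equal length", call. = FALSE)
  if (any(diff(days) < 0))
    stop("trmssd: days must be non-decreasing", call. = FALSE)
  if (anyDuplicated(days)) {
    values <- as.numeric(tapply(values, days, mean))
    days <- sort(unique(days))
  }
  n <- length(days)
  if (n < 2)
    stop("trmssd: needs at least two distinct observation days", call. = FALSE)
  dx <- diff(values)
  dt <- diff(days)
  sq <- if (method == "rate") (dx / dt)^2 else dx^2 / dt
  sqrt(mean(sq))
}

#' Derive the four predictors for one measurement window
#'
#' Computes clinical severity/instability from the window's CGI-S series and
#' functional severity/instability from the inverted GAF series, and carries
#' the patient's demographics, diagnosis flags and (optionally) the
#' organisation-level hospitalisation log-odds.
#'
#' @param window A \code{MeasurementWindow} as returned by
#'   \code{\link{select_window}}.
#' @param patient One-row patient record (demographics + diagnosis flags).
#' @param org_rates Optional named numeric vector mapping \code{org_id} to
#'   organisation-level logit hospitalisation rate.
#' @param trmssd_method Passed to \code{\link{trmssd}}.
#' @return One-row data frame with \code{clinical_severity},
#'   \code{clinical_instability}, \code{functional_severity},
#'   \code{functional_instability}, demographics, diagnosis flags and
#'   \code{org_logit_rate} (NA when no \code{org_rates} given).
#' @export
derive_features <- function(window, patient, org_rates = NULL,
                            trmssd_method = "rate") {
  inv_gaf <- invert_gaf(window$gaf_series$value)
  out <- data.frame(
    patient_id = window$patient_id,
    clinical_severity = mean_severity(window$cgi_series$value),
    clinical_instability = trmssd(window$cgi_series$day,
                                  window$cgi_series$value,
                                  method = trmssd_method),
    functional_severity = mean_severity(inv_gaf),
    functional_instability = trmssd(window$gaf_series$day, inv_gaf,
                                    method = trmssd_method),
    age = patient$age,
    gender = patient$gender,
    org_id = patient$org_id,
    race_group = patient$race_group,
    stringsAsFactors = FALSE)
  for (dx in DX_COLS) out[[dx]] <- patient[[dx]]
  out$org_logit_rate <- if (!is.null(org_rates))
    unname(org_rates[patient$org_id]) else NA_real_
  out
}

# Predictors that are standardised (continuous); diagnosis flags and gender
# indicators enter the model unscaled.
SCALED_PREDICTORS <- c("clinical_severity", "clinical_instability",
                       "functional_severity", "functional_instability",
                       "age")
INSTABILITY_PREDICTORS <- c("clinical_instability", "functional_instability")

#' Estimate standardisation constants on the derivation split
#'
#' Per-predictor mean and SD for the four severity/instability metrics and
#' age, plus means/SDs of the square-root-transformed instabilities (used
#' when AIC-based transform selection keeps the square root). The constants
#' are part of the frozen model: external validation data is always
#' standardised with derivation constants, never its own.
#'
#' @param features Feature table of the derivation split (raw scale).
#' @return A list of class \code{ews_scaling} with elements \code{center}
#'   and \code{scale} (named vectors over raw and \code{sqrt_}-prefixed
#'   instability predictors).
#' @export
fit_scaling <- function(features) {
  if (nrow(features) < 2)
    stop("fit_scaling: needs at least two rows", call. = FALSE)
  vars <- SCALED_PREDICTORS
  mat <- as.data.frame(features[, vars, drop = FALSE])
  for (v in INSTABILITY_PREDICTORS)
    mat[[paste0("sqrt_", v)]] <- sqrt(features[[v]])
  ctr <- vapply(mat, mean, numeric(1))
  scl <- vapply(mat, stats::sd, numeric(1))
  if (any(zero <- scl == 0))
    stop(sprintf("fit_scaling: predictor(s) with zero SD: %s",
                 paste(names(scl)[zero], collapse = ", ")), call. = FALSE)
  structure(list(center = ctr, scale = scl), class = "ews_scaling")
}

#' Standardise a feature table with frozen constants
#'
#' @param features Feature table (raw scale).
#' @param scaling Constants from \code{\link{fit_scaling}} (derivation
#'   split).
#' @param sqrt_flags Named logical vector over the instability predictors;
#'   TRUE applies the square-root transform (before standardisation).
#' @return \code{features} with added \code{*_z} columns.
#' @export
apply_scaling <- function(features, scaling,
                          sqrt_flags = c(clinical_instability = FALSE,
                                         functional_instability = FALSE)) {
  for (v in SCALED_PREDICTORS) {
    key <- v
    x <- features[[v]]
    if (v %in% INSTABILITY_PREDICTORS && isTRUE(sqrt_flags[[v]])) {
      key <- paste0("sqrt_", v)
      x <- sqrt(x)
    }
    features[[paste0(v, "_z")]] <-
      (x - scaling$center[[key]]) / scaling$scale[[key]]
  }
  features
}

#' Organisation-level hospitalisation rate on the logit scale
#'
#' Continuity-corrected empirical log-odds \code{logit((events + 0.5) /
#' (n + 1))}, finite even for organisations with zero (or all) events.
#'
#' @param events Number of hospitalised patients in the organisation.
#' @param n Number of cohort patients in the organisation (>= 1).
#' @return Log-odds of hospitalisation.
#' @export
org_logit_rate <- function(events, n) {
  if (any(n < 1)) stop("org_logit_rate: n must be >= 1", call. = FALSE)
  if (any(events < 0 | events > n))
    stop("org_logit_rate: events must be in [0, n]", call. = FALSE)
  p <- (events + 0.5) / (n + 1)
  log(p / (1 - p))
}

#' Organisation logit rates from a cohort table
#'
#' @param cohort Cohort table with \code{org_id} and \code{event} columns.
#' @return Named numeric vector of logit rates per organisation.
#' @export
org_rates_from_cohort <- function(cohort) {
  ev <- tapply(cohort$event, cohort$org_id, sum)
  n <- tapply(rep(1L, nrow(cohort)), cohort$org_id, sum)
  stats::setNames(org_logit_rate(as.numeric(ev), as.numeric(n)), names(ev))
}

#' Feature table for a whole cohort
#'
#' @param cohort Cohort object from \code{\link{build_cohort}}.
#' @param patients Patient table of the dataset.
#' @param org_rates Optional named vector of organisation logit rates.
#' @param trmssd_method Passed to \code{\link{trmssd}}.
#' @return Data frame with one feature row per cohort row, plus the outcome
#'   columns \code{time} and \code{event}.
#' @export
derive_feature_table <- function(cohort, patients, org_rates = NULL,
                                 trmssd_method = "rate") {
  w <- cohort$windows
  ids <- vapply(w, `[[`, character(1), "patient_id")
  pidx <- match(ids, patients$patient_id)
  out <- data.frame(
    patient_id = ids,
    clinical_severity = vapply(w, function(x)
      mean_severity(x$cgi_series$value), numeric(1)),
    clinical_instability = vapply(w, function(x)
      trmssd(x$cgi_series$day, x$cgi_series$value, method = trmssd_method),
      numeric(1)),
    functional_severity = vapply(w, function(x)
      mean_severity(invert_gaf(x$gaf_series$value)), numeric(1)),
    functional_instability = vapply(w, function(x)
      trmssd(x$gaf_series$day, invert_gaf(x$gaf_series$value),
             method = trmssd_method), numeric(1)),
    age = patients$age[pidx],
    gender = patients$gender[pidx],
    org_id = patients$org_id[pidx],
    race_group = patients$race_group[pidx],
    stringsAsFactors = FALSE)
  for (dx in DX_COLS) out[[dx]] <- patients[[dx]][pidx]
  out$org_logit_rate <- if (!is.null(org_rates))
    unname(org_rates[out$org_id]) else NA_real_
  m <- match(out$patient_id, cohort$table$patient_id)
  out$time <- cohort$table$time[m]
  out$event <- cohort$table$event[m]
  out
}
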