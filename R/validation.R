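#' Harrell's concordance index for right-censored outcomes
#'
#' Among usable pairs (the shorter observed time ends in an event), the
#' fraction in which the earlier event carries the higher predicted risk;
#' risk ties count 1/2. Computed with \code{survival::concordance} with
#' \code{reverse = TRUE} so that higher risk means shorter time to
#' hospitalisation.
#'
#' @param risks Per-patient risk scores.
#' @param time Observed time (days).
#' @param event Event indicator (logical or 0/1).
#' @return Concordance in [0, 1].
#' @export
c_index <- function(risks, time, event) {
  cc <- survival::concordance(survival::Surv(time, event) ~ risks,
                              reverse = TRUE)
  cnt <- cc$count
  if (sum(cnt[c("concordant", "discordant", "tied.x")]) == 0)
    stop("c_index: no comparable pairs", call. = FALSE)
  unname(cc$concordance)
}

#' Optimism-corrected c-index by bootstrap
#'
#' Harrell's internal-validation procedure: the apparent c-index of the
#' model on its own derivation data, minus the mean optimism over
#' \code{B} bootstrap resamples. Each resample repeats every data-driven
#' modelling step (standardisation and AIC transform selection included),
#' computes the resample model's c-index on the resample and on the
#' original data, and records the difference as that resample's optimism.
#' Resamples without events are redrawn (and counted).
#'
#' @param features Derivation feature table (raw scale, with outcomes).
#' @param spec Model name or \code{\link{model_spec}}.
#' @param B Bootstrap repetitions (default 200).
#' @param seed Integer seed.
#' @return List with \code{apparent}, \code{optimism} (mean),
#'   \code{corrected}, \code{ci} (percentile 2.5/97.5 of apparent minus
#'   per-resample optimism), \code{optimism_b} (per-resample values) and
#'   \code{n_redrawn}.
#' @export
optimism_corrected_cindex <- function(features, spec = "unadjusted",
                                      B = 200, seed = 1) {
  if (is.character(spec)) spec <- model_spec(spec)
  full <- suppressMessages(fit_ews_model(features, spec))
  risks <- predict_risk(full, features)
  apparent <- c_index(risks, features$time, features$event)
  set.seed(seed)
  n <- nrow(features)
  optimism_b <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(features$event[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    boot <- features[idx, , drop = FALSE]
    fit_b <- suppressMessages(fit_ews_model(boot, spec))
    c_boot <- c_index(predict_risk(fit_b, boot), boot$time, boot$event)
    c_orig <- c_index(predict_risk(fit_b, features),
                      features$time, features$event)
    optimism_b[b] <- c_boot - c_orig
  }
  corrected <- apparent - mean(optimism_b)
  list(apparent = apparent, optimism = mean(optimism_b),
       corrected = corrected,
       ci = unname(stats::quantile(apparent - optimism_b,
                                   c(0.025, 0.975))),
       optimism_b = optimism_b, n_redrawn = n_redrawn)
}

#' Operating-point metrics with prevalence-repinned predictive values
#'
#' Flags the top fraction of patients by predicted risk (stable order for
#' ties), computes sensitivity and specificity against observed outcomes,
#' and repins PPV/NPV by Bayes' rule to a prespecified incidence
#' \eqn{\pi}: \eqn{PPV = se\,\pi / (se\,\pi + (1-sp)(1-\pi))} and
#' \eqn{NPV = sp(1-\pi) / ((1-se)\pi + sp(1-\pi))}.
#'
#' @param risks Predicted risks.
#' @param event Observed outcome indicator.
#' @param flag_fraction Fraction of patients flagged (default 0.05).
#' @param prespecified_incidence Incidence \eqn{\pi} used for the
#'   repinning (default 0.02).
#' @return List: \code{sensitivity}, \code{specificity}, \code{ppv},
#'   \code{npv}, \code{n_flagged}, \code{threshold} (lowest flagged risk).
#' @export
threshold_metrics <- function(risks, event, flag_fraction = 0.05,
                              prespecified_incidence = 0.02) {
  n <- length(risks)
  y <- as.logical(event)
  k <- floor(flag_fraction * n)
  if (k < 1)
    stop("threshold_metrics: flag_fraction flags zero patients",
         call. = FALSE)
  if (stats::sd(risks) == 0)
    stop("threshold_metrics: risks are constant", call. = FALSE)
  ord <- order(-risks)  # radix sort: stable for tied risks
  flagged <- logical(n)
  flagged[ord[seq_len(k)]] <- TRUE
  se <- sum(flagged & y) / sum(y)
  sp <- sum(!flagged & !y) / sum(!y)
  pi0 <- prespecified_incidence
  ppv <- se * pi0 / (se * pi0 + (1 - sp) * (1 - pi0))
  npv <- sp * (1 - pi0) / ((1 - se) * pi0 + sp * (1 - pi0))
  list(sensitivity = se, specificity = sp, ppv = ppv, npv = npv,
       n_flagged = k, threshold = min(risks[flagged]))
}

#' Calibration curve with Kaplan-Meier observed risks
#'
#' Splits patients into equal-count bins of predicted risk; the observed
#' risk per bin is one minus the Kaplan-Meier survival at 180 days within
#' the bin (equal to the raw event proportion when there is no censoring),
#' with percentile bootstrap CIs from resampling patients within each bin.
#'
#' @param risks Predicted risks.
#' @param time,event Observed outcome.
#' @param bins Number of bins (default 10).
#' @param B Bootstrap repetitions for the CIs (default 200).
#' @param seed Integer seed.
#' @return Data frame: bin, n, predicted (mean), observed (KM), lower,
#'   upper. Bins with no risk time get NA observed.
#' @export
calibration_curve <- function(risks, time, event, bins = 10, B = 200,
                              seed = 1) {
  n <- length(risks)
  if (n < bins) stop("calibration_curve: fewer patients than bins",
                     call. = FALSE)
  ord <- order(risks)
  bin_id <- integer(n)
  bin_id[ord] <- ceiling(seq_len(n) * bins / n)
  km_risk <- function(tt, ev) {
    if (sum(tt) == 0) return(NA_real_)
    sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    1 - summary(sf, times = 180, extend = TRUE)$surv
  }
  set.seed(seed)
  out <- lapply(seq_len(bins), function(b) {
    in_b <- which(bin_id == b)
    obs <- km_risk(time[in_b], event[in_b])
    boots <- replicate(B, {
      j <- sample(in_b, length(in_b), replace = TRUE)
      km_risk(time[j], event[j])
    })
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
    data.frame(bin = b, n = length(in_b),
               predicted = mean(risks[in_b]), observed = obs,
               lower = unname(ci[1]), upper = unname(ci[2]))
  })
  do.call(rbind, out)
}

#' Brier score
#'
#' Mean squared error of the predicted probabilities against the binary
#' 180-day outcome; patients censored without an event count as
#' non-events (follow-up in the intended setting is nearly complete, so no
#' censoring weighting is applied).
#'
#' @param risks Predicted risks.
#' @param event Observed outcome indicator.
#' @return The Brier score in [0, 1].
#' @export
brier_score <- function(risks, event) {
  mean((risks - as.numeric(event))^2)
}

#' ROC curve points
#'
#' @param risks Predicted risks.
#' @param event Observed outcome indicator.
#' @return Data frame of (fpr, tpr) points from (0,0) to (1,1).
#' @export
roc_points <- function(risks, event) {
  y <- as.logical(event)
  ord <- order(-risks)
  tpr <- cumsum(y[ord]) / sum(y)
  fpr <- cumsum(!y[ord]) / sum(!y)
  keep <- !duplicated(risks[ord], fromLast = TRUE)  # one point per threshold
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' Per-diagnosis and per-race subgroup c-indices
#'
#' Evaluates the (global) model's risks within each diagnostic subgroup
#' (non-exclusive: a patient with two diagnoses contributes to both) and
#' within the white / non-white groups (patients with unknown race appear
#' in neither). Subgroups where the c-index is undefined are marked NA.
#'
#' @param risks Predicted risks.
#' @param time,event Observed outcome.
#' @param features Feature table carrying the diagnosis flags and
#'   \code{race_group}.
#' @return List with \code{diagnosis} and \code{race} data frames
#'   (subgroup, n, events, c_index).
#' @export
subgroup_cindices <- function(risks, time, event, features) {
  eval_in <- function(keep) {
    if (!any(keep)) return(c(n = 0, events = 0, c_index = NA_real_))
    ci <- tryCatch(c_index(risks[keep], time[keep], event[keep]),
                   error = function(e) NA_real_)
    c(n = sum(keep), events = sum(event[keep]), c_index = ci)
  }
  dx_tab <- t(vapply(DX_COLS, function(dx) eval_in(features[[dx]]),
                     numeric(3)))
  race_tab <- t(vapply(c("white", "non_white"),
                       function(g) eval_in(features$race_group == g),
                       numeric(3)))
  list(diagnosis = data.frame(subgroup = toupper(DX_CODES), dx_tab,
                              row.names = NULL),
       race = data.frame(subgroup = c("white", "non_white"), race_tab,
                         row.names = NULL))
}

#' Permutation test comparing c-indices between race groups
#'
#' Observed statistic: absolute difference between the c-index in white and
#' non-white patients (unknown race excluded). Race labels are permuted
#' across the included patients, holding risks and outcomes fixed; the
#' p-value uses the add-one estimator \eqn{(1 + \#\{\Delta_{perm} \ge
#' \Delta_{obs}\}) / (1 + P)} so it can never be zero.
#'
#' @param risks Predicted risks.
#' @param time,event Observed outcome.
#' @param race_group Race labels (\code{white} / \code{non_white} /
#'   \code{unknown}).
#' @param P Number of permutations (default 100).
#' @param seed Integer seed.
#' @return List: \code{c_white}, \code{c_nonwhite}, \code{delta},
#'   \code{p_value}.
#' @export
permutation_fairness_test <- function(risks, time, event, race_group,
                                      P = 100, seed = 1) {
  keep <- race_group %in% c("white", "non_white")
  risks <- risks[keep]; time <- time[keep]; event <- event[keep]
  race <- race_group[keep]
  if (!any(race == "white") || !any(race == "non_white"))
    stop("permutation_fairness_test: both race groups must be non-empty",
         call. = FALSE)
  delta_of <- function(lab) {
    abs(c_index(risks[lab == "white"], time[lab == "white"],
                event[lab == "white"]) -
        c_index(risks[lab == "non_white"], time[lab == "non_white"],
                event[lab == "non_white"]))
  }
  c_w <- c_index(risks[race == "white"], time[race == "white"],
                 event[race == "white"])
  c_nw <- c_index(risks[race == "non_white"], time[race == "non_white"],
                  event[race == "non_white"])
  obs <- abs(c_w - c_nw)
  set.seed(seed)
  perm <- replicate(P, tryCatch(delta_of(sample(race)),
                                error = function(e) NA_real_))
  list(c_white = c_w, c_nonwhite = c_nw, delta = obs,
       p_value = (1 + sum(perm >= obs, na.rm = TRUE)) / (1 + P))
}

#' Paired bootstrap comparison of two models' c-indices
#'
#' Patient-level paired bootstrap of the difference in c-index between two
#' risk vectors over the same patients; percentile 95\% CI and an add-one
#' corrected two-sided p-value for the difference departing from zero.
#'
#' @param risks_a,risks_b Risk vectors of the two models (same patients).
#' @param time,event Observed outcome.
#' @param B Bootstrap repetitions (default 1000).
#' @param seed Integer seed.
#' @return List: \code{delta} (observed c_a - c_b), \code{ci},
#'   \code{p_value}, \code{delta_b} (per-resample values).
#' @export
compare_models_bootstrap <- function(risks_a, risks_b, time, event,
                                     B = 1000, seed = 1) {
  if (length(risks_a) != length(risks_b))
    stop("compare_models_bootstrap: risk vectors differ in length",
         call. = FALSE)
  n <- length(risks_a)
  obs <- c_index(risks_a, time, event) - c_index(risks_b, time, event)
  set.seed(seed)
  delta_b <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(event[idx]) > 0) break
    }
    delta_b[b] <- tryCatch(
      c_index(risks_a[idx], time[idx], event[idx]) -
        c_index(risks_b[idx], time[idx], event[idx]),
      error = function(e) NA_real_)
  }
  ok <- !is.na(delta_b)
  p_lo <- (1 + sum(delta_b[ok] <= 0)) / (1 + sum(ok))
  p_hi <- (1 + sum(delta_b[ok] >= 0)) / (1 + sum(ok))
  list(delta = obs,
       ci = unname(stats::quantile(delta_b[ok], c(0.025, 0.975))),
       p_value = min(1, 2 * min(p_lo, p_hi)),
       delta_b = delta_b)
}
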