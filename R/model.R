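MODEL_NAMES <- c("unadjusted", "adjusted", "baseline", "clinical_benchmark")

#' Specification of one of the four prediction models
#'
#' \code{unadjusted}: the four severity/instability metrics (standardised)
#' plus diagnosis flags, gender and age. \code{adjusted}: the same plus the
#' organisation-level hospitalisation log-odds. \code{baseline}: diagnosis,
#' gender and age only. \code{clinical_benchmark}: baseline plus clinical
#' severity.
#'
#' @param name One of \code{unadjusted}, \code{adjusted}, \code{baseline},
#'   \code{clinical_benchmark}.
#' @return List of class \code{ews_model_spec} with the ordered covariate
#'   names (design-matrix columns).
#' @export
model_spec <- function(name = MODEL_NAMES) {
  name <- match.arg(name)
  metrics <- c("clinical_severity_z", "clinical_instability_z",
               "functional_severity_z", "functional_instability_z")
  demo <- c(DX_COLS, "gender_male", "gender_unknown", "age_z")
  covs <- switch(name,
    unadjusted = c(metrics, demo),
    adjusted = c(metrics, demo, "org_logit_rate"),
    baseline = demo,
    clinical_benchmark = c("clinical_severity_z", demo))
  structure(list(name = name, covariates = covs), class = "ews_model_spec")
}

# Design matrix columns for a spec: standardised metrics, 0/1 diagnosis
# flags, gender indicator contrasts (female reference) and the org term.
build_design <- function(features, spec, scaling,
                         sqrt_flags = c(clinical_instability = FALSE,
                                        functional_instability = FALSE)) {
  f <- apply_scaling(features, scaling, sqrt_flags)
  d <- data.frame(row.names = seq_len(nrow(f)))
  for (cv in spec$covariates) {
    d[[cv]] <- switch(cv,
      gender_male = as.numeric(f$gender == "male"),
      gender_unknown = as.numeric(f$gender == "unknown"),
      org_logit_rate = f$org_logit_rate,
      if (cv %in% DX_COLS) as.numeric(f[[cv]]) else f[[cv]])
    if (is.null(f[[cv]]) && !cv %in%
        c("gender_male", "gender_unknown"))
      stop(sprintf("build_design: missing covariate '%s'", cv),
           call. = FALSE)
    if (anyNA(d[[cv]]))
      stop(sprintf("build_design: covariate '%s' contains missing values",
                   cv), call. = FALSE)
  }
  d$time <- f$time
  d$event <- as.numeric(f$event)
  d
}

.fit_coxph <- function(design, covariates) {
  # drop zero-variance columns (e.g. an absent gender level, or a constant
  # org adjustment when every organisation has the same rate) and binary
  # indicators whose minority level has < 3 patients (inestimable)
  estimable <- function(cv) {
    x <- design[[cv]]
    if (stats::sd(x) == 0) return(FALSE)
    if (all(x %in% c(0, 1)) && min(sum(x == 0), sum(x == 1)) < 3)
      return(FALSE)
    TRUE
  }
  keep <- covariates[vapply(covariates, estimable, logical(1))]
  if (length(dropped <- setdiff(covariates, keep)))
    message("fit_cox: dropping constant covariate(s): ",
            paste(dropped, collapse = ", "))
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(keep, collapse = " + ")))
  # a near-empty indicator level (e.g. the handful of unknown-gender
  # patients, none hospitalised) drifts to -Inf; harmless for prediction
  fit <- withCallingHandlers(
    survival::coxph(fml, data = design, ties = "efron", x = TRUE),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    stop(sprintf("fit_cox: collinear covariate(s): %s",
                 paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                       collapse = ", ")), call. = FALSE)
  fit
}

# Baseline survival at t for the all-zero covariate vector (Breslow-type
# cumulative hazard from the Efron-tied fit).
.s0_at <- function(fit, t = 180) {
  bh <- survival::basehaz(fit, centered = FALSE)
  h <- bh$hazard[bh$time <= t]
  exp(-if (length(h)) max(h) else 0)
}

#' Fit a proportional-hazards prediction model
#'
#' Fits the Cox model for a given specification on a (derivation) feature
#' table: estimates standardisation constants, optionally selects
#' square-root transforms for the instability metrics by AIC, maximises the
#' partial likelihood with Efron tie handling, and stores the 180-day
#' baseline survival needed to emit absolute risks. The returned object is
#' self-contained (frozen scaling + transforms + coefficients) so external
#' validation never re-estimates anything.
#'
#' @param features Derivation feature table from
#'   \code{\link{derive_feature_table}} (raw scale, with \code{time} /
#'   \code{event}).
#' @param spec A \code{\link{model_spec}} or model name.
#' @param select_sqrt Run AIC-based square-root transform selection for the
#'   instability metrics (only where the model specification includes
#'   them).
#' @return Object of class \code{ews_model}: coefficients, scaling,
#'   transform flags, \code{s0_180}, fit metadata (log partial likelihood,
#'   AIC, n, events).
#' @export
fit_ews_model <- function(features, spec = "unadjusted",
                          select_sqrt = TRUE) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (sum(features$event) < 1)
    stop("fit_ews_model: no events in the data", call. = FALSE)
  scaling <- fit_scaling(features)
  flags <- c(clinical_instability = FALSE, functional_instability = FALSE)
  if (select_sqrt)
    flags <- select_transforms(features, spec, scaling)
  design <- build_design(features, spec, scaling, flags)
  fit <- .fit_coxph(design, spec$covariates)
  structure(list(
    spec = spec,
    coefficients = stats::coef(fit),
    scaling = scaling,
    sqrt_flags = flags,
    s0_180 = .s0_at(fit, 180),
    loglik = fit$loglik[2],
    aic = stats::AIC(fit),
    n = fit$n, nevent = fit$nevent,
    cox_fit = fit), class = "ews_model")
}

#' @export
print.ews_model <- function(x, ...) {
  cat(sprintf("<ews_model: %s> n=%d, events=%d, AIC=%.1f, S0(180)=%.4f\n",
              x$spec$name, x$n, x$nevent, x$aic, x$s0_180))
  ci <- tryCatch(stats::confint(x$cox_fit), error = function(e) NULL)
  hr <- exp(x$coefficients)
  tab <- data.frame(HR = round(hr, 3))
  if (!is.null(ci)) {
    tab$`2.5%` <- round(exp(ci[, 1]), 3)
    tab$`97.5%` <- round(exp(ci[, 2]), 3)
  }
  print(tab)
  invisible(x)
}

#' AIC-based square-root transform selection for instability metrics
#'
#' For each instability covariate in the model specification,
#' independently refits the
#' model with that metric square-root transformed (before standardisation,
#' with the other instability at its raw default) and keeps the transform
#' only when the AIC is strictly lower; ties keep the raw variable.
#'
#' @param features Raw feature table with outcomes.
#' @param spec A \code{\link{model_spec}}.
#' @param scaling Constants from \code{\link{fit_scaling}}.
#' @return Named logical vector over the instability predictors.
#' @export
select_transforms <- function(features, spec, scaling) {
  if (is.character(spec)) spec <- model_spec(spec)
  flags <- c(clinical_instability = FALSE, functional_instability = FALSE)
  present <- INSTABILITY_PREDICTORS[paste0(INSTABILITY_PREDICTORS, "_z")
                                    %in% spec$covariates]
  if (!length(present)) return(flags)
  aic_of <- function(fl) {
    d <- build_design(features, spec, scaling, fl)
    stats::AIC(.fit_coxph(d, spec$covariates))
  }
  base_aic <- aic_of(flags)
  for (v in present) {
    trial <- flags
    trial[v] <- TRUE
    if (aic_of(trial) < base_aic) flags[v] <- TRUE
  }
  flags
}

#' Test the proportional-hazards assumption
#'
#' Scaled Schoenfeld residual score test (Grambsch-Therneau) per covariate
#' and globally, on untransformed time.
#'
#' @param model A fitted \code{ews_model} (must carry its \code{cox_fit}).
#' @param transform Time transform passed to \code{survival::cox.zph}
#'   (default \code{"identity"}).
#' @return Data frame with per-covariate and GLOBAL rows: chi-square,
#'   degrees of freedom, p-value.
#' @export
test_proportional_hazards <- function(model, transform = "identity") {
  if (is.null(model$cox_fit))
    stop("test_proportional_hazards: model lacks its fitted cox object (reloaded models must be refit)", call. = FALSE)
  z <- survival::cox.zph(model$cox_fit, transform = transform,
                         global = TRUE)
  out <- as.data.frame(z$table)
  names(out) <- c("chisq", "df", "p")
  out$covariate <- rownames(z$table)
  rownames(out) <- NULL
  out[, c("covariate", "chisq", "df", "p")]
}

#' Predict absolute 6-month hospitalisation risk
#'
#' \code{risk = 1 - S0(180)^exp(lp)} with the linear predictor computed
#' from the model's frozen standardisation constants and transform flags.
#'
#' @param model A fitted or reloaded \code{ews_model}.
#' @param features Feature table (raw scale) for the patients to score.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_risk <- function(model, features) {
  features$time <- features$time %||% 0
  features$event <- features$event %||% 0
  design <- build_design(features, model$spec, model$scaling,
                         model$sqrt_flags)
  used <- names(model$coefficients)
  if (length(miss <- setdiff(used, names(design))))
    stop(sprintf("predict_risk: missing covariate(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  lp <- as.matrix(design[, used, drop = FALSE]) %*% model$coefficients
  as.numeric(1 - model$s0_180^exp(lp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.MODEL_FORMAT_VERSION <- 1L

#' Serialise / restore a fitted model
#'
#' Structured JSON holding everything needed for prediction (coefficients,
#' scaling constants, transform flags, 180-day baseline survival, spec) so
#' that predictions are bit-identical after a round trip. The in-memory
#' \code{cox_fit} object is not serialised.
#'
#' @param model A fitted \code{ews_model}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- list(format_version = .MODEL_FORMAT_VERSION,
              spec_name = model$spec$name,
              covariates = model$spec$covariates,
              coefficients = as.list(model$coefficients),
              scaling = list(center = as.list(model$scaling$center),
                             scale = as.list(model$scaling$scale)),
              sqrt_flags = as.list(model$sqrt_flags),
              s0_180 = model$s0_180,
              loglik = model$loglik, aic = model$aic,
              n = model$n, nevent = model$nevent)
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) ||
      obj$format_version != .MODEL_FORMAT_VERSION)
    stop("load_model: unsupported or missing model format version",
         call. = FALSE)
  req <- c("spec_name", "covariates", "coefficients", "scaling",
           "sqrt_flags", "s0_180")
  if (length(miss <- setdiff(req, names(obj))))
    stop(sprintf("load_model: malformed model file, missing field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  structure(list(
    spec = structure(list(name = obj$spec_name,
                          covariates = obj$covariates),
                     class = "ews_model_spec"),
    coefficients = unlist(obj$coefficients),
    scaling = structure(list(center = unlist(obj$scaling$center),
                             scale = unlist(obj$scaling$scale)),
                        class = "ews_scaling"),
    sqrt_flags = unlist(obj$sqrt_flags),
    s0_180 = obj$s0_180,
    loglik = obj$loglik, aic = obj$aic, n = obj$n, nevent = obj$nevent,
    cox_fit = NULL), class = "ews_model")
}
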