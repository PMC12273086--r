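#' Post-intervention hospitalisation risk under an odds-reducing intervention
#'
#' An intervention (e.g. referral to a crisis resolution team) that reduces
#' the odds of hospitalisation by a given fraction turns a pre-intervention
#' risk \code{p} into \code{odds' / (1 + odds')} with
#' \code{odds' = (1 - odds_reduction) * p / (1 - p)}. The reduction acts on
#' the odds scale, not the risk scale.
#'
#' @param ppv Pre-intervention risk among treated patients (the flagging
#'   strategy's PPV), strictly inside (0, 1).
#' @param odds_reduction Fractional odds reduction in [0, 1).
#' @return Post-intervention risk.
#' @export
treated_risk <- function(ppv, odds_reduction) {
  if (any(ppv <= 0 | ppv >= 1))
    stop("treated_risk: ppv must lie strictly inside (0, 1)", call. = FALSE)
  if (any(odds_reduction < 0 | odds_reduction >= 1))
    stop("treated_risk: odds_reduction must lie in [0, 1)", call. = FALSE)
  odds <- (1 - odds_reduction) * ppv / (1 - ppv)
  odds / (1 + odds)
}

#' Expected hospitalisations prevented by treating flagged patients
#'
#' @param n_treated Number of treated (flagged) individuals.
#' @param ppv Their pre-intervention risk.
#' @param odds_reduction Fractional odds reduction of the intervention.
#' @return Expected number prevented (real; round for a headline count).
#' @export
prevented <- function(n_treated, ppv, odds_reduction) {
  n_treated * (ppv - treated_risk(ppv, odds_reduction))
}

#' Number needed under one strategy to match a prevention target
#'
#' How many individuals must receive the intervention, at a given flagging
#' PPV, to prevent a target number of hospitalisations; rounded to the
#' nearest integer.
#'
#' @param target_prevented Hospitalisations to prevent.
#' @param ppv Flagging PPV of the strategy.
#' @param odds_reduction Fractional odds reduction.
#' @return Integer count of individuals.
#' @export
n_needed <- function(target_prevented, ppv, odds_reduction) {
  per_person <- ppv - treated_risk(ppv, odds_reduction)
  if (per_person <= 0)
    stop("n_needed: intervention prevents nothing per person", call. = FALSE)
  round(target_prevented / per_person)
}

#' Resource saving of a better-targeted strategy
#'
#' @param n_reference Individuals treated under the reference strategy.
#' @param n_needed Individuals needed under the better-targeted strategy
#'   for the same prevention.
#' @return Percentage saving, \code{100 * (n_reference - n_needed) /
#'   n_reference}.
#' @export
saving_fraction <- function(n_reference, n_needed) {
  if (n_reference <= 0)
    stop("saving_fraction: n_reference must be positive", call. = FALSE)
  100 * (n_reference - n_needed) / n_reference
}

#' Intervention-impact comparison of two flagging strategies
#'
#' Reproduces the targeting arithmetic for an odds-reducing intervention:
#' hospitalisations prevented when treating \code{n_treated} individuals
#' flagged at the benchmark PPV and at the model PPV, the number needed
#' under the model strategy to match the benchmark's (rounded) prevention
#' count, and the implied resource saving.
#'
#' @param n_treated Individuals treated under each strategy (default 1000).
#' @param ppv_benchmark,ppv_model Flagging PPVs of the two strategies.
#' @param odds_reduction Fractional odds reduction (default 0.8).
#' @return Data frame with one row per quantity (value + description).
#' @export
impact_scenario <- function(n_treated = 1000, ppv_benchmark = 0.054,
                            ppv_model = 0.098, odds_reduction = 0.8) {
  prev_bench <- prevented(n_treated, ppv_benchmark, odds_reduction)
  prev_model <- prevented(n_treated, ppv_model, odds_reduction)
  target <- round(prev_bench)
  n_need <- n_needed(target, ppv_model, odds_reduction)
  data.frame(
    quantity = c("prevented_benchmark", "prevented_model",
                 "n_needed_model", "saving_percent"),
    value = c(round(prev_bench), round(prev_model), n_need,
              saving_fraction(n_treated, n_need)),
    exact = c(prev_bench, prev_model, n_need,
              saving_fraction(n_treated, n_need)),
    stringsAsFactors = FALSE)
}
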