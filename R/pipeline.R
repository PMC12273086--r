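#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir Output directory for all artifacts.
#' @param sim An \code{\link{ews_sim_config}} to simulate input data, or
#'   \code{NULL} to read an existing dataset from \code{data_dir}.
#' @param data_dir Directory with the four input CSVs (ignored when
#'   \code{sim} is given; when simulating, the simulated CSVs are written
#'   here, defaulting to \code{file.path(out_dir, "data")}).
#' @param seed Global seed for every stochastic stage.
#' @param flag_fraction,prespecified_incidence Operating point (defaults:
#'   top 5\% flagged, predictive values repinned to 2\% incidence).
#' @param b_optimism Bootstrap repetitions for optimism correction and
#'   calibration CIs (default 200).
#' @param p_permutation Permutations for the fairness test (default 100).
#' @param b_compare Bootstrap repetitions for external CIs and model
#'   comparison (default 1000).
#' @param odds_reduction Odds reduction of the illustrative intervention
#'   (default 0.8).
#' @param trmssd_method Instability formula, see \code{\link{trmssd}}.
#' @return List of class \code{ews_pipeline_config}.
#' @export
pipeline_config <- function(out_dir, sim = NULL, data_dir = NULL, seed = 1,
                            flag_fraction = 0.05,
                            prespecified_incidence = 0.02,
                            b_optimism = 200, p_permutation = 100,
                            b_compare = 1000, odds_reduction = 0.8,
                            trmssd_method = "rate") {
  stopifnot(b_optimism >= 1, p_permutation >= 1, b_compare >= 1)
  structure(list(out_dir = out_dir, sim = sim,
                 data_dir = data_dir %||% file.path(out_dir, "data"),
                 seed = as.integer(seed), flag_fraction = flag_fraction,
                 prespecified_incidence = prespecified_incidence,
                 b_optimism = b_optimism, p_permutation = p_permutation,
                 b_compare = b_compare, odds_reduction = odds_reduction,
                 trmssd_method = trmssd_method),
            class = "ews_pipeline_config")
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

# percentile bootstrap CI for an external-sample c-index
.cindex_ci <- function(risks, time, event, B, seed) {
  set.seed(seed)
  n <- length(risks)
  cb <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(event[idx]) > 0) break
    }
    cb[b] <- tryCatch(c_index(risks[idx], time[idx], event[idx]),
                      error = function(e) NA_real_)
  }
  unname(stats::quantile(cb, c(0.025, 0.975), na.rm = TRUE))
}

#' Run the full development-and-validation pipeline
#'
#' Executes simulate (optional) -> cohort construction -> feature
#' derivation -> model fitting (all four specifications, on the derivation
#' split only) -> internal validation (optimism-corrected discrimination,
#' operating point, Brier, calibration) -> external validation ->
#' subgroup/fairness evaluation -> model comparison -> intervention-impact
#' arithmetic, writing every artifact under \code{cfg$out_dir}. The run is
#' a pure function of (input data, config, seed): rerunning with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param cfg An \code{\link{pipeline_config}}.
#' @return The run manifest (also written to \code{manifest.json}),
#'   invisibly; the consolidated results live in \code{report.json}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "ews_pipeline_config"))
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  # stage: data
  if (!is.null(cfg$sim)) {
    sim <- simulate_dataset(cfg$sim)
    ds <- sim$dataset
    write_dataset(ds, cfg$data_dir)
    utils::write.csv(sim$ground_truth,
                     file.path(cfg$data_dir, "ground_truth.csv"),
                     row.names = FALSE)
  } else {
    ds <- read_dataset(cfg$data_dir)
  }

  # stage: cohort
  cohort <- build_cohort(ds)
  utils::write.csv(cohort$table, file.path(out, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$exclusions, file.path(out, "exclusions.csv"),
                   row.names = FALSE)

  # stage: features (org rates computed within each split's own cohort)
  rates <- c(org_rates_from_cohort(
               cohort$table[cohort$table$split == "derivation", ]),
             org_rates_from_cohort(
               cohort$table[cohort$table$split == "validation", ]))
  features <- derive_feature_table(cohort, ds$patients, org_rates = rates,
                                   trmssd_method = cfg$trmssd_method)
  split_of <- cohort$table$split[match(features$patient_id,
                                       cohort$table$patient_id)]
  deriv <- features[split_of == "derivation", , drop = FALSE]
  valid <- features[split_of == "validation", , drop = FALSE]
  utils::write.csv(cbind(features, split = split_of),
                   file.path(out, "features.csv"), row.names = FALSE)

  # stage: fit (derivation split only)
  models <- lapply(stats::setNames(MODEL_NAMES, MODEL_NAMES), function(nm)
    suppressMessages(fit_ews_model(deriv, nm)))
  for (nm in MODEL_NAMES)
    save_model(models[[nm]], file.path(out, paste0("model_", nm, ".json")))
  hr_tables <- lapply(models, function(m) {
    ci <- stats::confint(m$cox_fit)
    data.frame(covariate = names(m$coefficients),
               hr = exp(unname(m$coefficients)),
               lo = exp(unname(ci[, 1])), hi = exp(unname(ci[, 2])),
               p = summary(m$cox_fit)$coefficients[, "Pr(>|z|)"],
               row.names = NULL)
  })
  ph_tests <- lapply(models[c("unadjusted", "adjusted")],
                     test_proportional_hazards)

  # stage: validate
  validate_split <- function(feat, internal, seed_off) {
    res <- list()
    for (nm in MODEL_NAMES) {
      risks <- predict_risk(models[[nm]], feat)
      entry <- list(
        c_apparent = c_index(risks, feat$time, feat$event),
        brier = brier_score(risks, feat$event))
      if (internal && nm %in% c("unadjusted", "adjusted")) {
        oc <- optimism_corrected_cindex(feat, nm, B = cfg$b_optimism,
                                        seed = cfg$seed + seed_off)
        entry$c_corrected <- oc$corrected
        entry$c_corrected_ci <- oc$ci
        entry$optimism <- oc$optimism
      }
      if (!internal)
        entry$c_ci <- .cindex_ci(risks, feat$time, feat$event,
                                 cfg$b_compare, cfg$seed + seed_off + 7L)
      entry <- c(entry, threshold_metrics(
        risks, feat$event, cfg$flag_fraction, cfg$prespecified_incidence))
      res[[nm]] <- entry
    }
    res
  }
  internal <- validate_split(deriv, internal = TRUE, seed_off = 11L)
  external <- validate_split(valid, internal = FALSE, seed_off = 23L)

  risks_d <- lapply(models, predict_risk, features = deriv)
  risks_v <- lapply(models, predict_risk, features = valid)
  calib <- list(
    internal = calibration_curve(risks_d$adjusted, deriv$time, deriv$event,
                                 B = cfg$b_optimism, seed = cfg$seed + 31L),
    external = calibration_curve(risks_v$adjusted, valid$time, valid$event,
                                 B = cfg$b_optimism, seed = cfg$seed + 37L))
  utils::write.csv(cbind(sample = rep(names(calib),
                                      vapply(calib, nrow, 0L)),
                         do.call(rbind, calib)),
                   file.path(out, "calibration.csv"), row.names = FALSE)
  roc <- do.call(rbind, lapply(c("unadjusted", "adjusted"), function(nm) {
    cbind(model = nm, sample = "external",
          roc_points(risks_v[[nm]], valid$event))
  }))
  utils::write.csv(roc, file.path(out, "roc.csv"), row.names = FALSE)

  subgroups <- lapply(risks_v[c("unadjusted", "adjusted")], function(r)
    subgroup_cindices(r, valid$time, valid$event, valid))
  fairness <- lapply(
    stats::setNames(c("unadjusted", "adjusted"),
                    c("unadjusted", "adjusted")),
    function(nm) tryCatch(
      permutation_fairness_test(
        risks_v[[nm]], valid$time, valid$event, valid$race_group,
        P = cfg$p_permutation, seed = cfg$seed + 41L),
      error = function(e) list(c_white = NA_real_, c_nonwhite = NA_real_,
                               delta = NA_real_, p_value = NA_real_,
                               note = conditionMessage(e))))

  comparisons <- list()
  for (a in c("unadjusted", "adjusted"))
    for (b in c("baseline", "clinical_benchmark")) {
      cmp <- compare_models_bootstrap(risks_v[[a]], risks_v[[b]],
                                      valid$time, valid$event,
                                      B = cfg$b_compare,
                                      seed = cfg$seed + 43L)
      comparisons[[paste(a, "vs", b)]] <-
        cmp[c("delta", "ci", "p_value")]
    }

  # stage: impact (from the pipeline's own internally validated PPVs)
  impact <- impact_scenario(
    n_treated = 1000,
    ppv_benchmark = internal$clinical_benchmark$ppv,
    ppv_model = internal$adjusted$ppv,
    odds_reduction = cfg$odds_reduction)

  report <- list(
    cohort = list(
      n_included = nrow(cohort$table),
      n_derivation = nrow(deriv), n_validation = nrow(valid),
      events_derivation = sum(deriv$event),
      events_validation = sum(valid$event),
      exclusions = as.list(table(cohort$exclusions$reason))),
    transforms = lapply(models, function(m) as.list(m$sqrt_flags)),
    hazard_ratios = hr_tables,
    proportional_hazards = ph_tests,
    internal = internal, external = external,
    subgroups = subgroups, fairness = fairness,
    model_comparisons = comparisons,
    impact = impact)
  .write_json(report, file.path(out, "report.json"))

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    config = cfg[setdiff(names(cfg), "sim")],
    sim_config = if (!is.null(cfg$sim)) unclass(cfg$sim),
    row_counts = list(patients = nrow(ds$patients),
                      visits = nrow(ds$visits),
                      hospitalisations = nrow(ds$hospitalisations),
                      cohort = nrow(cohort$table),
                      excluded = nrow(cohort$exclusions)),
    output_digests = as.list(tools::md5sum(sort(files))))
  .write_json(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}

#' Render a human-readable summary of a pipeline run
#'
#' @param out_dir Directory of a completed \code{\link{run_pipeline}} run.
#' @param file Optional path to also write the text to (default
#'   \code{report.txt} inside \code{out_dir}).
#' @return The report text, invisibly; printed to the console.
#' @export
render_report <- function(out_dir, file = file.path(out_dir, "report.txt")) {
  rp <- file.path(out_dir, "report.json")
  if (!file.exists(rp))
    stop("render_report: no report.json found; run the pipeline first",
         call. = FALSE)
  r <- jsonlite::read_json(rp, simplifyVector = TRUE)
  num <- function(x) ifelse(is.null(x) || !length(x), "not computed",
                            sprintf("%.3f", as.numeric(x)))
  lines <- c(
    "== Early-warning score pipeline report ==",
    sprintf("Cohort: %d included (%d derivation / %d validation); events %d / %d",
            r$cohort$n_included, r$cohort$n_derivation,
            r$cohort$n_validation, r$cohort$events_derivation,
            r$cohort$events_validation),
    "",
    "-- Hazard ratios (unadjusted model) --")
  hr <- r$hazard_ratios$unadjusted
  lines <- c(lines, sprintf("  %-26s HR %.2f (95%% CI %.2f-%.2f), p=%.2g",
                            hr$covariate, hr$hr, hr$lo, hr$hi, hr$p))
  for (nm in names(r$internal)) {
    i <- r$internal[[nm]]; e <- r$external[[nm]]
    lines <- c(lines, "",
      sprintf("-- Model: %s --", nm),
      sprintf("  internal c-index: apparent %s, optimism-corrected %s",
              num(i$c_apparent), num(i$c_corrected)),
      sprintf("  external c-index: %s (95%% CI %s-%s)", num(e$c_apparent),
              num(e$c_ci[1]), num(e$c_ci[2])),
      sprintf("  operating point (internal): se %s, sp %s, PPV %s, NPV %s",
              num(i$sensitivity), num(i$specificity), num(i$ppv),
              num(i$npv)),
      sprintf("  Brier: internal %s, external %s", num(i$brier),
              num(e$brier)))
  }
  lines <- c(lines, "", "-- Transdiagnostic c-indices (external, adjusted) --")
  dx <- r$subgroups$adjusted$diagnosis
  lines <- c(lines, sprintf("  %-5s n=%-6d c-index %s", dx$subgroup, dx$n,
                            vapply(dx$c_index, num, "")))
  for (nm in names(r$fairness)) {
    f <- r$fairness[[nm]]
    lines <- c(lines, sprintf(
      "Fairness (%s): c white %s vs non-white %s, permutation p=%s",
      nm, num(f$c_white), num(f$c_nonwhite), num(f$p_value)))
  }
  lines <- c(lines, "", "-- Model comparisons (external, delta c-index) --")
  for (nm in names(r$model_comparisons)) {
    m <- r$model_comparisons[[nm]]
    lines <- c(lines, sprintf("  %-36s %+0.3f (95%% CI %+0.3f to %+0.3f), p=%s",
                              nm, m$delta, m$ci[1], m$ci[2], num(m$p_value)))
  }
  lines <- c(lines, "", "-- Intervention impact --")
  im <- r$impact
  lines <- c(lines, sprintf("  %-20s %.0f", im$quantity, im$value))
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
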