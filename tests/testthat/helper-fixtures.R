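# Shared fixtures, built in code. The medium simulation is memoised so the
# per-file cost is paid once per test run.

.fixture_env <- new.env(parent = emptyenv())

# ~4000-patient realistic simulation + cohort + feature table
fixture_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    sim <- simulate_dataset(preset_paperlike(n_patients = 4000, seed = 42))
    coh <- build_cohort(sim$dataset)
    rates <- c(
      org_rates_from_cohort(coh$table[coh$table$split == "derivation", ]),
      org_rates_from_cohort(coh$table[coh$table$split == "validation", ]))
    feats <- derive_feature_table(coh, sim$dataset$patients,
                                  org_rates = rates)
    feats$split <- coh$table$split[match(feats$patient_id,
                                         coh$table$patient_id)]
    .fixture_env$pipe <- list(sim = sim, cohort = coh, features = feats)
  }
  .fixture_env$pipe
}

# hand-built 3-patient dataset covering the category edge cases
tiny_dataset <- function() {
  patients <- data.frame(
    patient_id = c("a", "b", "c"),
    org_id = c("o1", "o1", "o2"),
    age = c(30, 45.5, 0),
    gender = c("female", "male", "unknown"),
    race_group = c("white", "non_white", "unknown"),
    stringsAsFactors = FALSE)
  dx <- matrix(FALSE, 3, 7, dimnames = list(NULL, psyews:::DX_COLS))
  dx[1, "dx_mdd"] <- TRUE; dx[2, c("dx_bd", "dx_scz")] <- TRUE
  dx[3, "dx_adhd"] <- TRUE
  patients <- cbind(patients, as.data.frame(dx))
  visits <- data.frame(
    patient_id = c("a", "a", "b", "c"),
    date = c(0L, 30L, 10L, 5L),
    cgi_s = c(4L, NA, 6L, 2L),
    gaf = c(60L, 55L, NA, 90L),
    stringsAsFactors = FALSE)
  hosp <- data.frame(patient_id = "b", date = 200L,
                     stringsAsFactors = FALSE)
  splits <- data.frame(org_id = c("o1", "o2"),
                       split = c("derivation", "validation"),
                       stringsAsFactors = FALSE)
  ews_dataset(patients, visits, hosp, splits)
}

# visit table for one patient from parallel vectors
visits_of <- function(days, cgi = NULL, gaf = NULL, pid = "p1") {
  n <- length(days)
  data.frame(patient_id = pid, date = as.integer(days),
             cgi_s = if (is.null(cgi)) rep(NA_integer_, n) else cgi,
             gaf = if (is.null(gaf)) rep(NA_integer_, n) else gaf,
             stringsAsFactors = FALSE)
}

# naive loop oracle for the instability statistic (kept deliberately dumb
# and independent of the package implementation)
trmssd_oracle <- function(days, values, method = "rate") {
  stopifnot(length(days) >= 2)
  acc <- 0
  for (i in seq_len(length(days) - 1)) {
    dx <- values[i + 1] - values[i]
    dt <- days[i + 1] - days[i]
    acc <- acc + if (method == "rate") (dx / dt)^2 else dx^2 / dt
  }
  sqrt(acc / (length(days) - 1))
}

# brute-force concordance oracle: enumerate all ordered pairs
cindex_oracle <- function(risks, time, event) {
  num <- den <- 0
  n <- length(risks)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    # usable pair: i has the event and a strictly shorter time than j's
    # observed time
    if (event[i] && time[i] < time[j]) {
      den <- den + 1
      if (risks[i] > risks[j]) num <- num + 1
      else if (risks[i] == risks[j]) num <- num + 0.5
    }
    # tied times where exactly one is an event: event should rank riskier
    if (event[i] && !event[j] && time[i] == time[j]) {
      den <- den + 1
      if (risks[i] > risks[j]) num <- num + 1
      else if (risks[i] == risks[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}
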