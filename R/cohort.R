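#' Select a patient's qualifying 180-day measurement window
#'
#' Scans candidate window starts anchored at observed visit days and returns
#' the earliest closed 180-day window \code{[start, start + 179]} that
#' contains at least five CGI-S and five GAF ratings and whose end day lies
#' strictly before the patient's first hospitalisation (if any). Any
#' qualifying window can be shifted left to start at an observation day
#' without losing observations, so the scan over visit days is exhaustive.
#'
#' @param visits Data frame of one patient's visits (\code{date},
#'   \code{cgi_s}, \code{gaf}), sorted by \code{date}.
#' @param first_hosp Day of the patient's first hospitalisation, or
#'   \code{NULL}/\code{NA} when never hospitalised.
#' @param min_measurements Minimum count required for each of the two rating
#'   series inside the window (default 5).
#' @return A \code{MeasurementWindow} list (\code{patient_id},
#'   \code{window_start}, \code{window_end}, and the in-window
#'   \code{cgi_series} / \code{gaf_series}, each a list of parallel
#'   \code{day} and \code{value} vectors) or \code{NULL} when no window
#'   qualifies.
#' @export
select_window <- function(visits, first_hosp = NULL, min_measurements = 5) {
  if (nrow(visits) == 0) return(NULL)
  if (is.unsorted(visits$date))
    visits <- visits[order(visits$date), , drop = FALSE]
  .scan_window(visits$patient_id[1], visits$date, visits$cgi_s, visits$gaf,
               first_hosp, min_measurements)
}

# vector-level scan (dates sorted ascending); shared with the simulator and
# cohort builder to avoid per-patient data-frame overhead
.scan_window <- function(pid, dates, cgi, gaf, first_hosp = NULL,
                         min_measurements = 5) {
  has_cgi <- !is.na(cgi)
  has_gaf <- !is.na(gaf)
  cgi_days <- dates[has_cgi]
  gaf_days <- dates[has_gaf]
  if (length(cgi_days) < min_measurements ||
      length(gaf_days) < min_measurements) return(NULL)
  no_hosp <- is.null(first_hosp) || is.na(first_hosp)
  for (s0 in unique(dates)) {
    e0 <- s0 + 179L  # closed interval of 180 days
    if (!no_hosp && e0 >= first_hosp) return(NULL)  # later starts end later
    n_cgi <- sum(cgi_days >= s0 & cgi_days <= e0)
    n_gaf <- sum(gaf_days >= s0 & gaf_days <= e0)
    if (n_cgi >= min_measurements && n_gaf >= min_measurements) {
      in_cgi <- has_cgi & dates >= s0 & dates <= e0
      in_gaf <- has_gaf & dates >= s0 & dates <= e0
      return(list(
        patient_id = pid,
        window_start = as.integer(s0), window_end = as.integer(e0),
        cgi_series = list(day = dates[in_cgi], value = cgi[in_cgi]),
        gaf_series = list(day = dates[in_gaf], value = gaf[in_gaf])))
    }
  }
  NULL
}

#' Build the time-to-event outcome for a selected window
#'
#' The outcome clock starts the day after \code{window_end}. A
#' hospitalisation at \code{window_end + t} with \code{0 < t <= 180} is an
#' event at time \code{t}; otherwise the patient is censored at
#' \code{min(last visit day - window_end, 180)}, floored at 0.
#'
#' @param window A \code{MeasurementWindow}.
#' @param visits The patient's visit table.
#' @param hosp_dates Days of the patient's hospitalisations (possibly
#'   empty).
#' @return List with \code{time} (days in [0, 180]) and \code{event}
#'   (logical).
#' @export
build_outcome <- function(window, visits, hosp_dates = integer(0)) {
  hosp_dates <- hosp_dates[!is.na(hosp_dates)]
  if (length(hosp_dates) && min(hosp_dates) <= window$window_end)
    stop("build_outcome: hospitalisation on/before window end; window selection should have excluded this patient", call. = FALSE)
  if (length(hosp_dates)) {
    t_ev <- min(hosp_dates) - window$window_end
    if (t_ev <= 180) return(list(time = as.integer(t_ev), event = TRUE))
  }
  t_cens <- max(0L, min(max(visits$date) - window$window_end, 180L))
  list(time = as.integer(t_cens), event = FALSE)
}

#' Construct the analysis cohort from a dataset
#'
#' Applies the inclusion rule (a qualifying 180-day measurement window with
#' at least five CGI-S and five GAF ratings, ending before any
#' hospitalisation) to every patient and attaches the 180-day
#' time-to-event outcome. One row per included patient; the exclusion log
#' records why each excluded patient was dropped
#' (\code{insufficient_measurements} when no 180-day span ever holds 5+5
#' ratings, \code{hospitalised_before_window_end} when only the
#' hospitalisation constraint blocks every qualifying span).
#'
#' @param ds A validated \code{\link{ews_dataset}}.
#' @param min_measurements Minimum ratings per series in the window.
#' @return An object of class \code{ews_cohort}: list with \code{table}
#'   (patient_id, org_id, split, window bounds, time, event),
#'   \code{windows} (list of MeasurementWindow) and \code{exclusions}
#'   (patient_id, reason).
#' @export
build_cohort <- function(ds, min_measurements = 5) {
  np <- nrow(ds$patients)
  split_of <- stats::setNames(ds$splits$split, ds$splits$org_id)
  v <- ds$visits[order(ds$visits$patient_id, ds$visits$date), , drop = FALSE]
  vidx <- split(seq_len(nrow(v)), v$patient_id)
  hosp_by <- split(ds$hospitalisations$date, ds$hospitalisations$patient_id)

  windows <- vector("list", np)
  time <- integer(np); event <- logical(np)
  reason <- character(np)  # "" = included
  for (i in seq_len(np)) {
    pid <- ds$patients$patient_id[i]
    j <- vidx[[pid]]
    hosp <- hosp_by[[pid]]
    first_hosp <- if (length(hosp)) min(hosp) else NA
    w <- if (is.null(j)) NULL else
      .scan_window(pid, v$date[j], v$cgi_s[j], v$gaf[j], first_hosp,
                   min_measurements)
    if (is.null(w)) {
      unconstrained <- if (is.null(j) || is.na(first_hosp)) NULL else
        .scan_window(pid, v$date[j], v$cgi_s[j], v$gaf[j], NULL,
                     min_measurements)
      reason[i] <- if (is.null(unconstrained)) "insufficient_measurements"
                   else "hospitalised_before_window_end"
      next
    }
    out <- build_outcome(w, list(date = v$date[j]), hosp)
    windows[[i]] <- w
    time[i] <- out$time; event[i] <- out$event
  }
  inc <- reason == ""
  tab <- data.frame(
    patient_id = ds$patients$patient_id[inc],
    org_id = ds$patients$org_id[inc],
    split = unname(split_of[ds$patients$org_id[inc]]),
    window_start = vapply(windows[inc], `[[`, integer(1), "window_start"),
    window_end = vapply(windows[inc], `[[`, integer(1), "window_end"),
    time = time[inc], event = event[inc], stringsAsFactors = FALSE)
  structure(list(
    table = tab,
    windows = windows[inc],
    exclusions = data.frame(patient_id = ds$patients$patient_id[!inc],
                            reason = reason[!inc],
                            stringsAsFactors = FALSE)),
    class = "ews_cohort")
}

#' @export
print.ews_cohort <- function(x, ...) {
  cat("<ews_cohort>\n")
  n <- nrow(x$table)
  cat(sprintf("  included: %d (%d events, %.2f%%)\n", n, sum(x$table$event),
              if (n) 100 * mean(x$table$event) else NA_real_))
  if (nrow(x$exclusions)) {
    tb <- table(x$exclusions$reason)
    for (r in names(tb)) cat(sprintf("  excluded (%s): %d\n", r, tb[[r]]))
  } else cat("  excluded: 0\n")
  invisible(x)
}
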