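#' @keywords internal
"_PACKAGE"

DX_CODES <- c("mdd", "bd", "gad", "ptsd", "scz", "adhd", "pd")
DX_COLS <- paste0("dx_", DX_CODES)
GENDER_LEVELS <- c("female", "male", "unknown")
RACE_LEVELS <- c("white", "non_white", "unknown")

# Internal date representation: integer day offsets (whole-day arithmetic
# only). On disk dates are ISO-8601 relative to this origin.
.DATE_ORIGIN <- as.Date("2000-01-01")

day_to_date <- function(day) .DATE_ORIGIN + as.integer(day)
date_to_day <- function(date) as.integer(as.Date(date) - .DATE_ORIGIN)

#' Default schema configuration for dataset ingest
#'
#' Describes how on-disk column names map onto the canonical schema and how
#' raw race codings collapse to the three analysis groups
#' (\code{white}, \code{non_white}, \code{unknown}).
#'
#' @param columns Named list of named character vectors, one per table
#'   (\code{patients}, \code{visits}, \code{hospitalisations},
#'   \code{splits}); each maps canonical name -> on-disk name. Defaults to
#'   identity.
#' @param race_map Named character vector mapping raw race strings to one of
#'   \code{white}, \code{non_white}, \code{unknown}. Raw values already in
#'   those three groups pass through; unmapped values raise an error.
#' @return A list of class \code{ews_schema}.
#' @export
ews_schema <- function(columns = list(), race_map = c()) {
  canonical <- list(
    patients = c("patient_id", "org_id", "age", "gender", "race_group", DX_COLS),
    visits = c("patient_id", "date", "cgi_s", "gaf"),
    hospitalisations = c("patient_id", "date"),
    splits = c("org_id", "split")
  )
  cols <- lapply(names(canonical), function(tbl) {
    m <- stats::setNames(canonical[[tbl]], canonical[[tbl]])
    if (!is.null(columns[[tbl]])) m[names(columns[[tbl]])] <- columns[[tbl]]
    m
  })
  names(cols) <- names(canonical)
  structure(list(columns = cols, race_map = race_map), class = "ews_schema")
}

#' Construct a validated dataset
#'
#' Bundles the four tables of the analysis (patients, visits,
#' hospitalisation events, organisation-to-split assignment) into a single
#' validated container. All dates are integer day offsets.
#'
#' @param patients Data frame with columns \code{patient_id}, \code{org_id},
#'   \code{age}, \code{gender}, \code{race_group} and the seven diagnosis
#'   flags \code{dx_mdd} ... \code{dx_pd} (logical).
#' @param visits Data frame with \code{patient_id}, \code{date} (integer
#'   day), and optional integer ratings \code{cgi_s} (1-7), \code{gaf}
#'   (1-100); at least one rating per row.
#' @param hospitalisations Data frame with \code{patient_id}, \code{date}.
#' @param splits Data frame with \code{org_id}, \code{split}
#'   (\code{derivation} or \code{validation}).
#' @return An object of class \code{ews_dataset}.
#' @export
ews_dataset <- function(patients, visits, hospitalisations, splits) {
  ds <- structure(
    list(patients = as.data.frame(patients),
         visits = as.data.frame(visits),
         hospitalisations = as.data.frame(hospitalisations),
         splits = as.data.frame(splits)),
    class = "ews_dataset")
  validate_dataset(ds)
  ds
}

#' @export
print.ews_dataset <- function(x, ...) {
  cat("<ews_dataset>\n")
  cat(sprintf("  patients:         %d (orgs: %d)\n",
              nrow(x$patients), length(unique(x$patients$org_id))))
  cat(sprintf("  visits:           %d\n", nrow(x$visits)))
  cat(sprintf("  hospitalisations: %d\n", nrow(x$hospitalisations)))
  cat(sprintf("  splits:           %d derivation / %d validation orgs\n",
              sum(x$splits$split == "derivation"),
              sum(x$splits$split == "validation")))
  invisible(x)
}

.fail_rows <- function(bad, what, extra = "") {
  idx <- which(bad)
  stop(sprintf("validation error: %s (row%s %s)%s", what,
               if (length(idx) > 1) "s" else "",
               paste(utils::head(idx, 5), collapse = ", "),
               extra), call. = FALSE)
}

#' Validate a dataset against the schema invariants
#'
#' Checks field ranges (CGI-S in 1-7, GAF in 1-100, age >= 0), category
#' levels, the at-least-one-diagnosis rule, referential integrity of visits
#' and hospitalisations, and that every organisation is assigned to exactly
#' one split.
#'
#' @param ds An \code{ews_dataset} (or a plain list with the same tables).
#' @return \code{ds}, invisibly; stops with an informative error otherwise.
#' @export
validate_dataset <- function(ds) {
  p <- ds$patients; v <- ds$visits; h <- ds$hospitalisations; s <- ds$splits
  need <- function(df, cols, tbl) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("schema error: table '%s' is missing column(s): %s",
                   tbl, paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(p, c("patient_id", "org_id", "age", "gender", "race_group", DX_COLS),
       "patients")
  need(v, c("patient_id", "date", "cgi_s", "gaf"), "visits")
  need(h, c("patient_id", "date"), "hospitalisations")
  need(s, c("org_id", "split"), "splits")

  if (anyDuplicated(p$patient_id))
    stop("validation error: duplicated patient_id in patients", call. = FALSE)
  if (any(bad <- !is.finite(p$age) | p$age < 0))
    .fail_rows(bad, "age must be a non-negative number")
  if (any(bad <- !(p$gender %in% GENDER_LEVELS)))
    .fail_rows(bad, sprintf("gender must be one of {%s}",
                            paste(GENDER_LEVELS, collapse = ", ")))
  if (any(bad <- !(p$race_group %in% RACE_LEVELS)))
    .fail_rows(bad, sprintf("race_group must be one of {%s}",
                            paste(RACE_LEVELS, collapse = ", ")))
  for (dx in DX_COLS) {
    if (any(bad <- is.na(p[[dx]]) | !is.logical(p[[dx]])))
      .fail_rows(bad, sprintf("%s must be TRUE/FALSE", dx))
  }
  ndx <- Reduce(`+`, lapply(p[DX_COLS], as.integer))
  if (any(bad <- ndx < 1))
    .fail_rows(bad, "every patient must carry at least one diagnosis flag")

  if (nrow(v)) {
    if (any(bad <- is.na(v$date)))
      .fail_rows(bad, "visit date missing")
    cg <- v$cgi_s
    if (any(bad <- !is.na(cg) & (cg < 1 | cg > 7 | cg != round(cg))))
      .fail_rows(bad, "cgi_s out of range [1,7]")
    gf <- v$gaf
    if (any(bad <- !is.na(gf) & (gf < 1 | gf > 100 | gf != round(gf))))
      .fail_rows(bad, "gaf out of range [1,100]")
    if (any(bad <- is.na(cg) & is.na(gf)))
      .fail_rows(bad, "visit carries neither a CGI-S nor a GAF rating")
    if (any(bad <- !(v$patient_id %in% p$patient_id)))
      .fail_rows(bad, "visit references unknown patient_id")
  }
  if (nrow(h)) {
    if (any(bad <- is.na(h$date)))
      .fail_rows(bad, "hospitalisation date missing")
    if (any(bad <- !(h$patient_id %in% p$patient_id)))
      .fail_rows(bad, "hospitalisation references unknown patient_id")
  }
  if (anyDuplicated(s$org_id))
    stop("validation error: an org_id is assigned to more than one split",
         call. = FALSE)
  if (any(bad <- !(s$split %in% c("derivation", "validation"))))
    .fail_rows(bad, "split must be 'derivation' or 'validation'")
  if (length(miss <- setdiff(unique(p$org_id), s$org_id)))
    stop(sprintf("validation error: org(s) without a split assignment: %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  invisible(ds)
}

.dataset_files <- c(patients = "patients.csv", visits = "visits.csv",
                    hospitalisations = "hospitalisations.csv",
                    splits = "splits.csv")

#' Read a dataset from delimited files
#'
#' Reads the four comma-separated tables (\code{patients.csv},
#' \code{visits.csv}, \code{hospitalisations.csv}, \code{splits.csv}),
#' applies the schema configuration (column remapping, race recoding),
#' converts ISO-8601 dates to integer day offsets, and validates all
#' invariants.
#'
#' @param dir Directory holding the four CSV files, or a named character
#'   vector of explicit paths (names \code{patients}, \code{visits},
#'   \code{hospitalisations}, \code{splits}).
#' @param schema An \code{\link{ews_schema}} configuration.
#' @return A validated \code{\link{ews_dataset}}.
#' @export
read_dataset <- function(dir, schema = ews_schema()) {
  paths <- if (length(dir) == 1 && is.null(names(dir)))
    file.path(dir, .dataset_files) else dir[names(.dataset_files)]
  names(paths) <- names(.dataset_files)
  for (pth in paths) if (!file.exists(pth))
    stop(sprintf("input file not found: %s", pth), call. = FALSE)

  rd <- function(tbl) {
    df <- utils::read.csv(paths[[tbl]], stringsAsFactors = FALSE,
                          colClasses = "character")
    map <- schema$columns[[tbl]]
    miss <- setdiff(unname(map), names(df))
    if (length(miss))
      stop(sprintf("schema error: file '%s' is missing column(s): %s",
                   basename(paths[[tbl]]), paste(miss, collapse = ", ")),
           call. = FALSE)
    out <- df[, unname(map), drop = FALSE]
    names(out) <- names(map)
    out
  }
  p <- rd("patients"); v <- rd("visits"); h <- rd("hospitalisations")
  s <- rd("splits")

  p$age <- as.numeric(p$age)
  for (dx in DX_COLS) p[[dx]] <- as.logical(toupper(p[[dx]]) %in%
                                              c("TRUE", "T", "1"))
  if (length(schema$race_map)) {
    mapped <- p$race_group %in% names(schema$race_map)
    p$race_group[mapped] <- unname(schema$race_map[p$race_group[mapped]])
  }
  v$date <- date_to_day(v$date)
  v$cgi_s <- suppressWarnings(as.integer(ifelse(v$cgi_s == "", NA, v$cgi_s)))
  v$gaf <- suppressWarnings(as.integer(ifelse(v$gaf == "", NA, v$gaf)))
  h$date <- date_to_day(h$date)
  ews_dataset(p, v, h, s)
}

#' Write a dataset to delimited files
#'
#' Inverse of \code{\link{read_dataset}}: emits the four CSV files with
#' ISO-8601 dates and empty cells for absent ratings, such that reading them
#' back reproduces the dataset exactly.
#'
#' @param ds A validated \code{\link{ews_dataset}}.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  validate_dataset(ds)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- stats::setNames(file.path(dir, .dataset_files),
                           names(.dataset_files))
  v <- ds$visits; h <- ds$hospitalisations
  v$date <- format(day_to_date(v$date))
  h$date <- format(day_to_date(h$date))
  wr <- function(df, pth) utils::write.csv(df, pth, row.names = FALSE,
                                           quote = FALSE, na = "")
  wr(ds$patients, paths["patients"])
  wr(v, paths["visits"])
  wr(h, paths["hospitalisations"])
  wr(ds$splits, paths["splits"])
  invisible(paths)
}
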