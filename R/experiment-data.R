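# Containers and CSV readers/writers for the two experiment types:
# acute salinity-tolerance assays (replicate boxes censused at 48/72/96 hr)
# and 30-day common-garden boxes with F1 followed to day 90.

TOL_COLUMNS <- c("replicate_id", "salinity", "n_initial",
                 "alive_48", "alive_72", "alive_96")
BOX_COLUMNS <- c("box_id", "origin", "treatment", "n_males", "n_females",
                 "eggs_total", "days_observed", "n_offspring")
DAILY_COLUMNS <- c("box_id", "day", "sex", "n_alive")
F1_COLUMNS <- c("box_id", "day", "status")

#' Tolerance-experiment dataset
#'
#' Bundles replicate-level census records from an acute salinity-tolerance
#' assay with free-form metadata. Each record is one experimental box:
#' a salinity dose, the number of adults stocked, and the number still
#' alive at the 48, 72 and 96 hour censuses (dead individuals are removed
#' at census, so counts are cumulative survivors).
#'
#' @param records Tibble with columns `replicate_id`, `salinity` (ppt),
#'   `n_initial`, `alive_48`, `alive_72`, `alive_96`, and optionally
#'   `population`.
#' @param metadata Named list of free-form metadata (site, date, seed, ...).
#' @param validate If `TRUE` (default), stop on any invariant violation.
#' @return An object of class `tolerance_dataset`.
#' @export
tolerance_dataset <- function(records, metadata = list(), validate = TRUE) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(TOL_COLUMNS, names(records))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"population" %in% names(records)) {
    records$population <- NA_character_
  }
  records$replicate_id <- as.character(records$replicate_id)
  records$salinity <- as.numeric(records$salinity)
  for (col in c("n_initial", "alive_48", "alive_72", "alive_96")) {
    records[[col]] <- as.integer(records[[col]])
  }
  ds <- structure(list(records = records, metadata = metadata),
                  class = "tolerance_dataset")
  if (validate) stop_on_violations(ds)
  ds
}

#' Common-garden dataset
#'
#' Bundles the three tables describing a common-garden experiment: one
#' row per box (`boxes`), the daily adult census in long format (`daily`:
#' `box_id`, `day`, `sex`, `n_alive` with day 0 holding the stocking
#' counts), and the F1 time-to-event records (`f1`: one row per offspring
#' event, `status` either `"death"` or `"censored"`).
#'
#' @param boxes Tibble with columns `box_id`, `origin`, `treatment` (ppt,
#'   0 = the freshwater treatment), `n_males`, `n_females`, `eggs_total`,
#'   `days_observed`, `n_offspring`.
#' @param daily Long tibble of daily adult counts by sex (`sex` in
#'   `"M"`/`"F"`).
#' @param f1 Tibble of F1 longevity events (day in 1..90).
#' @param metadata Named list of free-form metadata.
#' @param validate If `TRUE` (default), stop on any invariant violation.
#' @return An object of class `garden_dataset`.
#' @export
garden_dataset <- function(boxes, daily, f1 = NULL, metadata = list(),
                           validate = TRUE) {
  boxes <- tibble::as_tibble(boxes)
  daily <- tibble::as_tibble(daily)
  if (is.null(f1)) {
    f1 <- tibble::tibble(box_id = character(), day = numeric(),
                         status = character())
  }
  f1 <- tibble::as_tibble(f1)
  for (spec in list(list(boxes, BOX_COLUMNS, "boxes"),
                    list(daily, DAILY_COLUMNS, "daily"),
                    list(f1, F1_COLUMNS, "f1"))) {
    missing <- setdiff(spec[[2]], names(spec[[1]]))
    if (length(missing) > 0) {
      stop("missing required column(s) in ", spec[[3]], " table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  boxes$box_id <- as.character(boxes$box_id)
  daily$box_id <- as.character(daily$box_id)
  f1$box_id <- as.character(f1$box_id)
  boxes$treatment <- as.numeric(boxes$treatment)
  for (col in c("n_males", "n_females", "eggs_total", "days_observed",
                "n_offspring")) {
    boxes[[col]] <- as.integer(boxes[[col]])
  }
  daily$day <- as.integer(daily$day)
  daily$n_alive <- as.integer(daily$n_alive)
  f1$day <- as.integer(f1$day)
  f1$status <- as.character(f1$status)
  dup <- unique(boxes$box_id[duplicated(boxes$box_id)])
  if (length(dup) > 0) {
    stop("duplicate box_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  ds <- structure(list(boxes = boxes, daily = daily, f1 = f1,
                       metadata = metadata),
                  class = "garden_dataset")
  if (validate) stop_on_violations(ds)
  ds
}

#' @export
print.tolerance_dataset <- function(x, ...) {
  cat("<tolerance_dataset> ", nrow(x$records), " replicate boxes, ",
      length(unique(x$records$salinity)), " salinity levels\n", sep = "")
  invisible(x)
}

#' @export
print.garden_dataset <- function(x, ...) {
  cat("<garden_dataset> ", nrow(x$boxes), " boxes (",
      paste(sort(unique(x$boxes$origin)), collapse = "/"), ") at ",
      length(unique(x$boxes$treatment)), " treatments\n", sep = "")
  invisible(x)
}

apply_schema <- function(df, schema, table) {
  if (is.null(schema)) return(df)
  stopifnot(is.character(schema), !is.null(names(schema)))
  missing <- setdiff(unname(schema), names(df))
  if (length(missing) > 0) {
    stop("schema column(s) not found in ", table, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (canonical in names(schema)) {
    names(df)[names(df) == schema[[canonical]]] <- canonical
  }
  df
}

#' Read a tolerance-experiment CSV
#'
#' Reads a comma-separated table (UTF-8, one header row) of tolerance
#' census records and returns a validated [tolerance_dataset()]. Row
#' order is preserved and no rows are dropped silently: the record count
#' always equals the number of data rows, or an error is raised.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (e.g. `salinity`) to the names used in the file.
#' @param strict If `TRUE` (default) any invariant violation is an error;
#'   if `FALSE`, violations are downgraded to warnings.
#' @param metadata Metadata list stored on the returned dataset.
#' @return A [tolerance_dataset()].
#' @export
read_tolerance_csv <- function(path, schema = NULL, strict = TRUE,
                               metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- apply_schema(df, schema, "tolerance table")
  if (nrow(df) == 0) {
    warning("tolerance table ", path, " has a header but no data rows",
            call. = FALSE)
    df <- tibble::tibble(replicate_id = character(), salinity = numeric(),
                         n_initial = integer(), alive_48 = integer(),
                         alive_72 = integer(), alive_96 = integer())
  }
  ds <- tolerance_dataset(df, metadata = metadata, validate = FALSE)
  enforce_validation(ds, strict)
  ds
}

#' Write a tolerance-experiment CSV
#'
#' @param ds A [tolerance_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tolerance_csv <- function(ds, path) {
  stopifnot(inherits(ds, "tolerance_dataset"))
  readr::write_csv(ds$records, path, progress = FALSE)
  invisible(path)
}

#' Read a common-garden experiment from its three CSV tables
#'
#' The garden design is stored as a wide box table joined to a long daily
#' census table (30-day series do not fit one row cleanly) and a long F1
#' event table.
#'
#' @param boxes_path,daily_path,f1_path Paths to the three CSV files.
#'   `f1_path` may be `NULL` when no F1 follow-up was recorded.
#' @param schema Optional named character vector renaming box-table
#'   columns (canonical name -> file name).
#' @param strict If `TRUE` (default), treatments outside the design set
#'   and any invariant violation are errors; if `FALSE` they are warnings.
#' @param allowed_treatments Design treatment levels in ppt (0 = FW).
#' @param metadata Metadata list stored on the returned dataset.
#' @return A [garden_dataset()].
#' @export
read_garden_csv <- function(boxes_path, daily_path, f1_path = NULL,
                            schema = NULL, strict = TRUE,
                            allowed_treatments = c(0, 1, 3, 5, 11),
                            metadata = list()) {
  for (p in c(boxes_path, daily_path, f1_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  boxes <- readr::read_csv(boxes_path, show_col_types = FALSE, progress = FALSE)
  boxes <- apply_schema(boxes, schema, "box table")
  daily <- readr::read_csv(daily_path, show_col_types = FALSE, progress = FALSE)
  f1 <- if (is.null(f1_path)) NULL else {
    readr::read_csv(f1_path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(boxes) == 0) {
    warning("box table ", boxes_path, " has a header but no data rows",
            call. = FALSE)
  }
  bad <- setdiff(unique(boxes$treatment), allowed_treatments)
  if (length(bad) > 0) {
    msg <- paste0("treatment level(s) outside the design set {",
                  paste(allowed_treatments, collapse = ","), "}: ",
                  paste(bad, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  ds <- garden_dataset(boxes, daily, f1, metadata = metadata,
                       validate = FALSE)
  enforce_validation(ds, strict)
  ds
}

#' Write a common-garden dataset to its three CSV tables
#'
#' @param ds A [garden_dataset()].
#' @param boxes_path,daily_path,f1_path Output paths.
#' @return The three paths, invisibly.
#' @export
write_garden_csv <- function(ds, boxes_path, daily_path, f1_path) {
  stopifnot(inherits(ds, "garden_dataset"))
  readr::write_csv(ds$boxes, boxes_path, progress = FALSE)
  readr::write_csv(ds$daily, daily_path, progress = FALSE)
  readr::write_csv(ds$f1, f1_path, progress = FALSE)
  invisible(c(boxes_path, daily_path, f1_path))
}

#' Validate a dataset against its type invariants
#'
#' Violations are returned as data, not raised: one row per broken rule
#' with the offending record id, the rule name, and a human-readable
#' message. An empty result means every invariant holds.
#'
#' @param ds A [tolerance_dataset()] or [garden_dataset()].
#' @param ... Unused.
#' @return Tibble with columns `record_id`, `rule`, `message`.
#' @export
validate_dataset <- function(ds, ...) UseMethod("validate_dataset")

violation <- function(record_id, rule, message) {
  tibble::tibble(record_id = as.character(record_id), rule = rule,
                 message = message)
}

no_violations <- function() {
  tibble::tibble(record_id = character(), rule = character(),
                 message = character())
}

#' @export
validate_dataset.tolerance_dataset <- function(ds, ...) {
  r <- ds$records
  out <- list(no_violations())
  dup <- unique(r$replicate_id[duplicated(r$replicate_id)])
  if (length(dup) > 0) {
    out[[length(out) + 1]] <- violation(dup, "unique_replicate_id",
                                        "duplicated replicate_id")
  }
  bad <- r$replicate_id[!is.na(r$salinity) & r$salinity < 0]
  if (length(bad) > 0) {
    out[[length(out) + 1]] <- violation(bad, "salinity_nonnegative",
                                        "salinity must be >= 0 ppt")
  }
  bad <- r$replicate_id[r$n_initial <= 0]
  if (length(bad) > 0) {
    out[[length(out) + 1]] <- violation(bad, "n_initial_positive",
                                        "n_initial must be a positive count")
  }
  for (col in c("alive_48", "alive_72", "alive_96")) {
    bad <- r$replicate_id[r[[col]] < 0 | r[[col]] > r$n_initial]
    if (length(bad) > 0) {
      out[[length(out) + 1]] <- violation(
        bad, "alive_within_bounds",
        paste0(col, " must lie in [0, n_initial]"))
    }
  }
  bad <- r$replicate_id[r$alive_72 > r$alive_48 | r$alive_96 > r$alive_72]
  if (length(bad) > 0) {
    out[[length(out) + 1]] <- violation(
      bad, "counts_nonincreasing",
      "survivor counts must be non-increasing across 48 -> 72 -> 96 hr")
  }
  dplyr::bind_rows(out)
}

#' @export
validate_dataset.garden_dataset <- function(ds, ...) {
  b <- ds$boxes
  d <- ds$daily
  f1 <- ds$f1
  out <- list(no_violations())
  dup <- unique(b$box_id[duplicated(b$box_id)])
  if (length(dup) > 0) {
    out[[length(out) + 1]] <- violation(dup, "unique_box_id",
                                        "duplicated box_id")
  }
  bad <- b$box_id[b$eggs_total < 0 | b$n_offspring < 0]
  if (length(bad) > 0) {
    out[[length(out) + 1]] <- violation(bad, "counts_nonnegative",
                                        "eggs_total and n_offspring must be >= 0")
  }
  bad <- b$box_id[b$days_observed < 1 | b$days_observed > 30]
  if (length(bad) > 0) {
    out[[length(out) + 1]] <- violation(bad, "days_observed_range",
                                        "days_observed must lie in [1, 30]")
  }
  initial_of <- function(box, sex) {
    i <- match(box, b$box_id)
    ifelse(sex == "M", b$n_males[i], b$n_females[i])
  }
  for (box in b$box_id) {
    for (sx in c("M", "F")) {
      series <- d[d$box_id == box & d$sex == sx, ]
      series <- series[order(series$day), ]
      if (nrow(series) == 0) next
      ini <- initial_of(box, sx)
      day0 <- series$n_alive[series$day == 0]
      if (length(day0) == 1 && day0 != ini) {
        out[[length(out) + 1]] <- violation(
          box, "day0_equals_initial",
          sprintf("day-0 %s count (%d) differs from initial (%d)",
                  sx, day0, ini))
      }
      if (any(diff(series$n_alive) > 0)) {
        out[[length(out) + 1]] <- violation(
          box, "daily_nonincreasing",
          sprintf("daily %s counts increase within the series", sx))
      }
      if (any(series$n_alive > ini | series$n_alive < 0)) {
        out[[length(out) + 1]] <- violation(
          box, "daily_within_bounds",
          sprintf("daily %s counts outside [0, initial]", sx))
      }
    }
  }
  if (nrow(f1) > 0) {
    bad <- unique(f1$box_id[f1$day < 1 | f1$day > 90])
    if (length(bad) > 0) {
      out[[length(out) + 1]] <- violation(
        bad, "f1_day_range", "F1 event days must lie in [1, 90]")
    }
    bad <- unique(f1$box_id[!f1$status %in% c("death", "censored")])
    if (length(bad) > 0) {
      out[[length(out) + 1]] <- violation(
        bad, "f1_status", "F1 status must be 'death' or 'censored'")
    }
    orphan <- setdiff(unique(f1$box_id), b$box_id)
    if (length(orphan) > 0) {
      out[[length(out) + 1]] <- violation(
        orphan, "f1_known_box", "F1 record references an unknown box_id")
    }
  }
  dplyr::bind_rows(out)
}

stop_on_violations <- function(ds) enforce_validation(ds, strict = TRUE)

enforce_validation <- function(ds, strict) {
  v <- validate_dataset(ds)
  if (nrow(v) == 0) return(invisible(v))
  msg <- paste0("validation failed for ", nrow(v), " record(s):\n",
                paste(sprintf("  [%s] %s: %s", v$rule, v$record_id,
                              v$message),
                      collapse = "\n"))
  if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  invisible(v)
}
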