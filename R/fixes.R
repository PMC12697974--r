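# core_model: GNSS fix streams, the radial-accuracy filter, calendar-day
# accounting, and the study compliance rule.

#' Construct a tibble of GNSS fixes
#'
#' A fix is one device location report: position (WGS84 degrees), Unix epoch
#' time in seconds, and the reported radial accuracy in metres. Fixes are the
#' unit of input to every other part of the engine.
#'
#' @param participant_id Character vector of opaque participant identifiers
#'   (in practice the study invite code).
#' @param lat,lon Numeric, decimal degrees WGS84.
#' @param t Numeric, Unix epoch seconds.
#' @param accuracy_m Numeric, non-negative radial accuracy in metres.
#' @return A tibble with columns `participant_id`, `lat`, `lon`, `t`,
#'   `accuracy_m`, validated against the fix invariants.
#' @examples
#' gnss_fixes("p1", lat = 43.0, lon = -81.2, t = 1700000000, accuracy_m = 8)
#' @export
gnss_fixes <- function(participant_id, lat, lon, t, accuracy_m) {
  fixes <- tibble::tibble(
    participant_id = as.character(participant_id),
    lat = as.numeric(lat),
    lon = as.numeric(lon),
    t = as.numeric(t),
    accuracy_m = as.numeric(accuracy_m)
  )
  validate_fixes(fixes)
}

#' Validate a fix table against the fix invariants
#'
#' Checks latitude/longitude ranges, finite timestamps, and non-negative
#' accuracy. Returns the input invisibly unchanged so it can sit in a pipe.
#'
#' @param fixes A data frame with columns `participant_id`, `lat`, `lon`,
#'   `t`, `accuracy_m`.
#' @return The validated fixes, as a tibble.
#' @export
validate_fixes <- function(fixes) {
  fixes <- tibble::as_tibble(fixes)
  needed <- c("participant_id", "lat", "lon", "t", "accuracy_m")
  missing <- setdiff(needed, names(fixes))
  if (length(missing)) {
    rlang::abort(paste0("fixes are missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "gemaflow_schema_error")
  }
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      i <- which(cond | is.na(cond))[1]
      rlang::abort(sprintf("invalid fix at row %d: %s", i, what),
                   class = "gemaflow_schema_error")
    }
  }
  bad(!is.finite(fixes$lat) | fixes$lat < -90 | fixes$lat > 90,
      "lat outside [-90, 90]")
  bad(!is.finite(fixes$lon) | fixes$lon < -180 | fixes$lon > 180,
      "lon outside [-180, 180]")
  bad(!is.finite(fixes$t), "non-finite timestamp")
  bad(!is.finite(fixes$accuracy_m) | fixes$accuracy_m < 0,
      "negative or non-finite accuracy_m")
  fixes
}

#' Drop fixes whose reported radial accuracy exceeds a threshold
#'
#' The platform filters out location points that exceed the configured radial
#' inaccuracy (default 30 m). "Exceed" is read strictly: a fix reporting
#' exactly the threshold is retained. Order is preserved; the input must be
#' time-sorted within each participant.
#'
#' @param fixes A fix tibble (see [gnss_fixes()]), sorted by `t` within
#'   participant.
#' @param max_radial_m Maximum retained radial accuracy in metres
#'   (default 30).
#' @return The retained fixes, in input order.
#' @examples
#' f <- gnss_fixes("p1", 43, -81.2, c(0, 120), c(30, 31))
#' filter_accuracy(f) # keeps the 30 m fix, drops the 31 m fix
#' @export
filter_accuracy <- function(fixes, max_radial_m = 30) {
  fixes <- validate_fixes(fixes)
  if (!is.numeric(max_radial_m) || length(max_radial_m) != 1 ||
      !is.finite(max_radial_m) || max_radial_m <= 0) {
    rlang::abort("configuration error: max_radial_m must be a positive number",
                 class = "gemaflow_config_error")
  }
  check_sorted(fixes$participant_id, fixes$t)
  dplyr::filter(fixes, .data$accuracy_m <= max_radial_m)
}

#' Count distinct local calendar days with at least one fix
#'
#' Study compliance asks for at least 7 unique (not necessarily consecutive)
#' days' worth of locations. A "day" is a local calendar date in the study
#' timezone, so a fix at 23:59 and one at 00:01 the next local day count as
#' two days.
#'
#' @param fixes A fix tibble.
#' @param tz IANA timezone name used to derive local dates.
#' @return A tibble with one row per participant: `participant_id`,
#'   `n_days`.
#' @examples
#' f <- gnss_fixes("p1", 43, -81.2, c(0, 3600, 86400 * 2), 5)
#' unique_location_days(f, "UTC")
#' @export
unique_location_days <- function(fixes, tz) {
  fixes <- validate_fixes(fixes)
  check_timezone(tz)
  if (nrow(fixes) == 0) {
    return(tibble::tibble(participant_id = character(), n_days = integer()))
  }
  fixes |>
    dplyr::mutate(.date = local_date(.data$t, tz)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_days = dplyr::n_distinct(.data$.date),
                     .groups = "drop")
}

#' Study compliance criteria
#'
#' A participant is compliant when they transmitted locations on at least
#' `min_unique_days` distinct local days, completed at least
#' `min_momentary_responses` momentary survey prompts, and (if required)
#' completed the exit survey.
#'
#' @param min_unique_days Minimum distinct location days (default 7).
#' @param min_momentary_responses Minimum answered momentary prompts
#'   (default 1).
#' @param require_exit_survey Whether the exit survey must be completed
#'   (default TRUE).
#' @return A list of class `gemaflow_criteria`.
#' @export
compliance_criteria <- function(min_unique_days = 7,
                                min_momentary_responses = 1,
                                require_exit_survey = TRUE) {
  if (min_unique_days < 0 || min_momentary_responses < 0) {
    rlang::abort("configuration error: criteria counts must be >= 0",
                 class = "gemaflow_config_error")
  }
  structure(
    list(min_unique_days = as.integer(min_unique_days),
         min_momentary_responses = as.integer(min_momentary_responses),
         require_exit_survey = isTRUE(require_exit_survey)),
    class = "gemaflow_criteria"
  )
}

#' Apply the compliance rule
#'
#' Vectorised over participants: TRUE iff all three criteria are met.
#'
#' @param days Integer vector: distinct location days per participant.
#' @param momentary_responses Integer vector: answered momentary prompts.
#' @param exit_survey_done Logical vector: exit survey completed.
#' @param criteria A [compliance_criteria()] object.
#' @return Logical vector.
#' @examples
#' is_compliant(c(7, 6, 10), c(1, 5, 0), c(TRUE, TRUE, TRUE))
#' @export
is_compliant <- function(days, momentary_responses, exit_survey_done,
                         criteria = compliance_criteria()) {
  stopifnot(inherits(criteria, "gemaflow_criteria"))
  days >= criteria$min_unique_days &
    momentary_responses >= criteria$min_momentary_responses &
    (!criteria$require_exit_survey | exit_survey_done)
}

#' Sampling policy of the device
#'
#' The app transmits a fix every `interval_s` seconds while the device is in
#' motion, and pauses collection once it has been motionless for longer than
#' `pause_after_motionless_s` seconds. The engine itself only consumes
#' whatever fixes arrive; this policy object drives the simulator and the
#' visit gap rule defaults.
#'
#' @param interval_s Sampling interval in seconds (default 120).
#' @param pause_after_motionless_s Stillness duration after which sampling
#'   pauses, in seconds (default 600). Must be >= `interval_s`.
#' @return A list of class `gemaflow_sampling`.
#' @export
sampling_policy <- function(interval_s = 120, pause_after_motionless_s = 600) {
  if (interval_s <= 0 || pause_after_motionless_s < interval_s) {
    rlang::abort(
      "configuration error: need interval_s > 0 and pause_after_motionless_s >= interval_s",
      class = "gemaflow_config_error")
  }
  structure(list(interval_s = interval_s,
                 pause_after_motionless_s = pause_after_motionless_s),
            class = "gemaflow_sampling")
}

#' Read and write fix streams
#'
#' Fix streams interchange as CSV with header
#' `participant_id,lat,lon,t,accuracy_m`, or as JSON-lines with the same
#' keys. The format is chosen from the file extension (`.csv` vs
#' `.jsonl`/`.ndjson`/`.json`).
#'
#' @param path File path.
#' @param fixes A fix tibble.
#' @return `read_fixes()` returns a validated fix tibble; `write_fixes()`
#'   returns `path` invisibly.
#' @export
read_fixes <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             participant_id = readr::col_character(),
                             lat = readr::col_double(),
                             lon = readr::col_double(),
                             t = readr::col_double(),
                             accuracy_m = readr::col_double()))
  } else {
    out <- read_jsonl(path)
    out$participant_id <- as.character(out$participant_id)
  }
  validate_fixes(out)
}

#' @rdname read_fixes
#' @export
write_fixes <- function(fixes, path) {
  fixes <- validate_fixes(fixes)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(fixes, path, progress = FALSE)
  } else {
    write_jsonl(fixes, path)
  }
  invisible(path)
}

#' JSON-lines primitives
#'
#' One JSON object per line; timestamps stay integer epoch seconds, no
#' locale-dependent formatting anywhere. Used by every log writer.
#'
#' @param df A data frame (list-columns serialise as nested arrays).
#' @param path File path.
#' @return `write_jsonl()` returns `path` invisibly; `read_jsonl()` a
#'   tibble.
#' @export
write_jsonl <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df)) {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, , drop = FALSE]), auto_unbox = TRUE,
                       digits = NA, null = "null")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(tibble::tibble())
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    x[vapply(x, is.null, logical(1))] <- NA
    tibble::as_tibble(x)
  })
  dplyr::bind_rows(rows)
}
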