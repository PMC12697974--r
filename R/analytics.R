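# analytics: the monitor-server analogue. Adherence/latency tables by
# prompt kind, cohort location summaries, recruitment funnel arithmetic,
# and survey scale scoring (WHO-5 well-being, PROMIS Sleep Disturbance).

#' Adherence and latency by prompt kind
#'
#' For each prompt kind (rule), computes per-participant adherence
#' (answered / sent), then reports the across-participant mean and sample
#' standard deviation (n - 1) of those proportions as percentages.
#' Participants who were sent zero prompts of a kind do not enter that
#' row's adherence statistics. Latency is measured delivery to submission
#' in whole minutes (floor) over all accepted responses of the kind; its
#' median and standard deviation are reported across responses.
#'
#' @param prompts A prompt tibble (statuses finalised).
#' @param responses The accepted-response tibble.
#' @return A tibble of class `gemaflow_adherence`: `prompt_kind`, `n_sent`,
#'   `n_participants_sent`, `adherence_pct_mean`, `adherence_pct_sd`,
#'   `latency_median_min`, `latency_sd_min`. Latency columns are `NA` for
#'   kinds with no accepted responses.
#' @examples
#' # two participants sent 2 prompts each, answering 2/2 and 1/2:
#' # adherence mean 75%, sample SD 35.36%
#' @export
adherence_table <- function(prompts, responses) {
  orphans <- setdiff(responses$prompt_id, prompts$prompt_id)
  if (length(orphans)) {
    rlang::abort(paste0("linkage error: response(s) reference unknown prompt_id: ",
                        paste(utils::head(orphans, 5), collapse = ", ")),
                 class = "gemaflow_linkage_error")
  }
  if (!nrow(prompts)) {
    out <- tibble::tibble(prompt_kind = character(), n_sent = integer(),
                          n_participants_sent = integer(),
                          adherence_pct_mean = numeric(),
                          adherence_pct_sd = numeric(),
                          latency_median_min = numeric(),
                          latency_sd_min = numeric())
    class(out) <- c("gemaflow_adherence", class(out))
    return(out)
  }
  answered <- prompts$prompt_id %in% responses$prompt_id
  per_part <- prompts |>
    dplyr::mutate(answered = answered) |>
    dplyr::group_by(.data$rule_id, .data$participant_id) |>
    dplyr::summarise(sent = dplyr::n(), ans = sum(.data$answered),
                     .groups = "drop") |>
    dplyr::mutate(adherence = .data$ans / .data$sent)
  adh <- per_part |>
    dplyr::group_by(prompt_kind = .data$rule_id) |>
    dplyr::summarise(
      n_sent = sum(.data$sent),
      n_participants_sent = dplyr::n(),
      adherence_pct_mean = 100 * mean(.data$adherence),
      adherence_pct_sd = 100 * stats::sd(.data$adherence),
      .groups = "drop")
  lat <- responses |>
    dplyr::mutate(latency_min = floor(.data$latency_s / 60)) |>
    dplyr::group_by(prompt_kind = .data$rule_id) |>
    dplyr::summarise(latency_median_min = stats::median(.data$latency_min),
                     latency_sd_min = stats::sd(.data$latency_min),
                     .groups = "drop")
  out <- dplyr::left_join(adh, lat, by = "prompt_kind")
  # preserve protocol rule order where recoverable from the prompt log
  ord <- match(out$prompt_kind, unique(prompts$rule_id))
  out <- out[order(ord), ]
  class(out) <- c("gemaflow_adherence", class(out))
  out
}

#' Cohort location totals
#'
#' Counts unique fixes (duplicate records with identical participant, time
#' and position count once), per-participant totals, and the cohort mean
#' rounded half away from zero to the nearest integer.
#'
#' @param fixes A fix tibble.
#' @return A one-row tibble: `n_fixes`, `n_participants`,
#'   `mean_fixes_per_participant`, plus a `per_participant` list-column
#'   holding the per-participant count tibble.
#' @export
summary_counts <- function(fixes) {
  fixes <- validate_fixes(fixes)
  uniq <- dplyr::distinct(fixes, .data$participant_id, .data$t, .data$lat,
                          .data$lon)
  per <- uniq |> dplyr::count(.data$participant_id, name = "n_fixes")
  tibble::tibble(
    n_fixes = nrow(uniq),
    n_participants = nrow(per),
    mean_fixes_per_participant = if (nrow(per))
      round_half_up(nrow(uniq) / nrow(per)) else NA_real_,
    per_participant = list(per))
}

scale_specs <- list(
  WHO5 = list(n_items = 5L, min = 0L, max = 5L),       # raw score 0-25
  PROMIS_SD = list(n_items = 8L, min = 1L, max = 5L))  # raw score 8-40

#' Score a survey scale
#'
#' Raw scoring by item summation. WHO-5 well-being: five items scored 0-5,
#' total 0-25, higher is better well-being. PROMIS Sleep Disturbance:
#' eight items scored 1-5, total 8-40, lower is better sleep quality.
#'
#' @param scale "WHO5" or "PROMIS_SD".
#' @param items Integer vector of item scores.
#' @return A one-row tibble: `scale`, `raw`.
#' @examples
#' score_scale("WHO5", c(5, 5, 5, 5, 5)) # raw 25
#' @export
score_scale <- function(scale = c("WHO5", "PROMIS_SD"), items) {
  scale <- match.arg(scale)
  spec <- scale_specs[[scale]]
  items <- as.numeric(items)
  if (length(items) != spec$n_items) {
    rlang::abort(sprintf("scoring error: %s needs %d items, got %d",
                         scale, spec$n_items, length(items)),
                 class = "gemaflow_scoring_error")
  }
  bad <- which(!is.finite(items) | items != round(items) |
                 items < spec$min | items > spec$max)
  if (length(bad)) {
    rlang::abort(sprintf("scoring error: %s item %d out of range [%d, %d]",
                         scale, bad[1], spec$min, spec$max),
                 class = "gemaflow_scoring_error")
  }
  tibble::tibble(scale = scale, raw = as.integer(sum(items)))
}

#' Recruitment funnel arithmetic
#'
#' Stage counts must be non-increasing (invited >= consented >= installed
#' >= compliant). Reports each stage count, the stage-to-stage percentage,
#' and the percentage of the first stage, rounded half away from zero to
#' the nearest integer.
#'
#' @param invited,consented,installed,compliant Stage counts.
#' @return A tibble: `stage`, `n`, `pct_of_previous`, `pct_of_first`.
#' @examples
#' funnel_report(1379, 96, 55, 38) # consent rate 7%
#' @export
funnel_report <- function(invited, consented, installed, compliant) {
  n <- c(invited = invited, consented = consented, installed = installed,
         compliant = compliant)
  if (any(diff(n) > 0)) {
    rlang::abort("consistency error: funnel stage counts must be non-increasing",
                 class = "gemaflow_config_error")
  }
  stages <- names(n)
  n <- unname(n)
  prev <- c(NA, n[-length(n)])
  tibble::tibble(
    stage = stages,
    n = n,
    pct_of_previous = round_half_up(100 * n / prev),
    pct_of_first = round_half_up(100 * n / n[1]))
}

#' Video attachment rate of engagement prompts
#'
#' The share of engagement-type prompts whose response included a video.
#' Whether the denominator includes the follow-up variant of the engagement
#' prompt is ambiguous in field reporting, so both readings are returned.
#'
#' @param prompts A prompt tibble.
#' @param responses The accepted-response tibble (with `attachments`).
#' @param engagement_kinds Prompt kinds counted as engagement-type
#'   (default `c("DWELL")`); the wide reading adds `"FOLLOWUP_DWELL"`.
#' @return A tibble with one row per denominator reading: `denominator`,
#'   `n_prompts`, `n_videos`, `video_pct`.
#' @export
video_rate <- function(prompts, responses,
                       engagement_kinds = c("DWELL")) {
  with_videos <- responses[responses$attachments > 0, ]
  one <- function(kinds, label) {
    sent <- prompts[prompts$kind %in% kinds, ]
    vids <- with_videos[with_videos$prompt_id %in% sent$prompt_id, ]
    tibble::tibble(denominator = label, n_prompts = nrow(sent),
                   n_videos = nrow(vids),
                   video_pct = if (nrow(sent))
                     round_half_up(100 * nrow(vids) / nrow(sent)) else NA_real_)
  }
  dplyr::bind_rows(
    one(engagement_kinds, "engagement"),
    one(c(engagement_kinds, "FOLLOWUP_DWELL"), "engagement_plus_followup"))
}

#' Per-participant compliance summary
#'
#' Combines location-day counts, momentary response counts and exit-survey
#' completion into the compliance flag.
#'
#' @param fixes A fix tibble (filtered).
#' @param responses Accepted responses.
#' @param exit_done Named logical vector (participant -> exit survey done),
#'   or a single value recycled to the cohort.
#' @param criteria A [compliance_criteria()].
#' @param tz IANA timezone for day counting.
#' @return A tibble: `participant_id`, `n_days`, `n_responses`,
#'   `exit_survey_done`, `compliant`.
#' @export
compliance_summary <- function(fixes, responses, exit_done = TRUE,
                               criteria = compliance_criteria(),
                               tz = "America/Toronto") {
  days <- unique_location_days(fixes, tz)
  resp <- responses |> dplyr::count(.data$participant_id, name = "n_responses")
  ids <- union(days$participant_id, resp$participant_id)
  out <- tibble::tibble(participant_id = sort(ids)) |>
    dplyr::left_join(days, by = "participant_id") |>
    dplyr::left_join(resp, by = "participant_id") |>
    dplyr::mutate(n_days = dplyr::coalesce(.data$n_days, 0L),
                  n_responses = dplyr::coalesce(.data$n_responses, 0L))
  exit_vec <- if (length(exit_done) == 1 && is.null(names(exit_done))) {
    rep(isTRUE(exit_done), nrow(out))
  } else {
    dplyr::coalesce(as.logical(exit_done[out$participant_id]), FALSE)
  }
  out$exit_survey_done <- exit_vec
  out$compliant <- is_compliant(out$n_days, out$n_responses,
                                out$exit_survey_done, criteria)
  out
}

#' Write an adherence report
#'
#' CSV with one row per prompt kind, plus an optional JSON summary.
#'
#' @param adherence A `gemaflow_adherence` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_adherence <- function(adherence, path) {
  readr::write_csv(tibble::as_tibble(adherence), path, progress = FALSE)
  invisible(path)
}
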