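# cli_io: protocol configuration loading, the end-to-end pipeline wiring
# simulator -> filter -> engine -> scheduler -> masking -> analytics, and
# the run manifest. Protocol files are JSON (this build has no YAML parser
# available); all timestamps serialise as integer epoch seconds.

#' Load a protocol configuration file
#'
#' Reads a JSON protocol: rule list plus engine settings, with defaults
#' applied (30 m accuracy filter, one-hour expiry, the morning/evening
#' ParkSeek windows, 12 h visit gap). Schema violations are reported with
#' field paths.
#'
#' Expected shape:
#' \preformatted{
#' {
#'   "timezone": "America/Toronto",
#'   "max_radial_m": 30,
#'   "max_gap_s": 43200,
#'   "surveys": ["WHO5"],
#'   "criteria": {"min_unique_days": 7, "min_momentary_responses": 1,
#'                "require_exit_survey": true},
#'   "rules": [
#'     {"rule_id": "morning", "kind": "TIME_WINDOW",
#'      "window_start": "09:00", "window_end": "10:00",
#'      "survey_ref": "WHO5"},
#'     {"rule_id": "engagement", "kind": "DWELL", "min_dwell_s": 600,
#'      "geofence_class": "park", "survey_ref": "WHO5"}
#'   ]
#' }
#' }
#'
#' @param path Path to a JSON protocol file.
#' @return A `gemaflow_protocol`.
#' @export
load_protocol <- function(path) {
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    rlang::abort(paste0("load error at <root>: not valid JSON (",
                                        conditionMessage(e), ")"),
                                 class = "gemaflow_config_error")
                  })
  if (is.null(cfg$rules) || !length(cfg$rules)) {
    rlang::abort("load error at rules: at least one rule is required",
                 class = "gemaflow_config_error")
  }
  build_rule <- function(r, i) {
    at <- function(field) sprintf("rules[%d].%s", i, field)
    if (is.null(r$rule_id)) {
      rlang::abort(paste0("load error at ", at("rule_id"), ": missing"),
                   class = "gemaflow_config_error")
    }
    kind <- r$kind %||% NA_character_
    expiry_s <- r$expiry_s %||% 3600
    survey_ref <- r$survey_ref %||% "survey"
    switch(
      as.character(kind),
      TIME_WINDOW = rule_time_window(
        r$rule_id,
        window_start = r$window_start %||% "09:00",
        window_end = r$window_end %||% "10:00",
        max_per_day = r$max_per_day %||% 1,
        expiry_s = expiry_s, survey_ref = survey_ref),
      DWELL = rule_dwell(
        r$rule_id, min_dwell_s = r$min_dwell_s %||% 600,
        geofence_class = r$geofence_class %||% "park",
        expiry_s = expiry_s, survey_ref = survey_ref),
      FOLLOWUP_DWELL = rule_followup_dwell(
        r$rule_id, min_dwell_s = r$min_dwell_s %||% 2700,
        geofence_class = r$geofence_class %||% "park",
        expiry_s = expiry_s, survey_ref = survey_ref),
      EXIT = rule_exit(
        r$rule_id, geofence_class = r$geofence_class %||% "park",
        expiry_s = expiry_s, survey_ref = survey_ref),
      RESPONSE_CONTINGENT = rule_response_contingent(
        r$rule_id, source_rule_id = r$source_rule_id,
        item = r$trigger$item, op = r$trigger$op, value = r$trigger$value,
        delay_s = r$delay_s %||% 0,
        expiry_s = expiry_s, survey_ref = survey_ref),
      rlang::abort(paste0("load error at ", at("kind"),
                          ": unknown rule kind '", kind, "'"),
                   class = "gemaflow_config_error"))
  }
  rules <- lapply(seq_along(cfg$rules),
                  function(i) build_rule(cfg$rules[[i]], i))
  crit <- cfg$criteria %||% list()
  protocol(
    rules,
    timezone = cfg$timezone %||% "America/Toronto",
    max_radial_m = cfg$max_radial_m %||% 30,
    max_gap_s = cfg$max_gap_s %||% 43200,
    criteria = compliance_criteria(
      min_unique_days = crit$min_unique_days %||% 7,
      min_momentary_responses = crit$min_momentary_responses %||% 1,
      require_exit_survey = crit$require_exit_survey %||% TRUE),
    surveys = unlist(cfg$surveys) %||% NULL,
    delivery_delay_s = cfg$delivery_delay_s %||% 0)
}

#' Write a protocol configuration file
#'
#' Serialises a protocol back to the JSON shape [load_protocol()] reads.
#'
#' @param protocol A `gemaflow_protocol`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "gemaflow_protocol"))
  r <- protocol$rules
  rules <- lapply(seq_len(nrow(r)), function(i) {
    base <- list(rule_id = r$rule_id[i], kind = r$kind[i],
                 expiry_s = r$expiry_s[i], survey_ref = r$survey_ref[i])
    extra <- switch(
      r$kind[i],
      TIME_WINDOW = list(window_start = r$window_start[i],
                         window_end = r$window_end[i],
                         max_per_day = r$max_per_day[i]),
      DWELL = ,
      FOLLOWUP_DWELL = list(min_dwell_s = r$min_dwell_s[i],
                            geofence_class = r$geofence_class[i]),
      EXIT = list(geofence_class = r$geofence_class[i]),
      RESPONSE_CONTINGENT = list(source_rule_id = r$source_rule_id[i],
                                 trigger = r$trigger[[i]],
                                 delay_s = r$delay_s[i]),
      list())
    c(base, extra)
  })
  out <- list(timezone = protocol$timezone,
              max_radial_m = protocol$max_radial_m,
              max_gap_s = protocol$max_gap_s,
              surveys = protocol$surveys,
              criteria = unclass(protocol$criteria),
              delivery_delay_s = protocol$delivery_delay_s,
              rules = rules)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline and write an artifact bundle
#'
#' simulate -> accuracy filter -> visit detection -> prompt evaluation ->
#' response acceptance -> masked storage -> analytics, deterministic given
#' the seed. Writes `fences.geojson`, `fixes.csv` (masked coordinates when
#' a secret is given — true positions then never reach storage),
#' `truth_visits.jsonl`, `events.jsonl`, `prompts.jsonl`,
#' `responses.jsonl`, `visits.jsonl`, `adherence.csv`, `summary.json` and
#' `manifest.json` under `out_dir`.
#'
#' @param cfg A [sim_config()].
#' @param protocol A `gemaflow_protocol`.
#' @param out_dir Output directory (created if needed); NULL to skip
#'   writing files.
#' @param profile A [behavior_profile()].
#' @param fences Optional pre-built fence set; defaults to
#'   [generate_geofences()] seeded from `cfg$seed`.
#' @param mask_secret Optional masking secret; when given, the stored fix
#'   file holds masked coordinates only.
#' @return A list of class `gemaflow_run`: the cohort plus `adherence`,
#'   `summary`, `video`, and `manifest`.
#' @export
run_pipeline <- function(cfg, protocol = parkseek_protocol(),
                         out_dir = NULL, profile = parkseek_profile(),
                         fences = NULL, mask_secret = NULL) {
  t_start <- Sys.time()
  fences <- fences %||% generate_geofences(seed = cfg$seed)
  cohort <- simulate_cohort(cfg, profile, fences, protocol)
  adherence <- adherence_table(cohort$prompts, cohort$responses)
  summary <- summary_counts(cohort$filtered)
  video <- video_rate(cohort$prompts, cohort$responses)
  manifest <- list(
    package = "gemaflow",
    version = as.character(utils::packageVersion("gemaflow")),
    seed = cfg$seed,
    config_hash = hex8(fnv1a32(paste(
      deparse(unclass(cfg)), deparse(unclass(protocol$rules)),
      collapse = ""))),
    n_participants = cfg$n_participants,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = NA_character_)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_geofences(fences, p("fences.geojson"))
    if (!is.null(mask_secret)) {
      key <- mask_key(mask_secret)
      write_masked(mask_fixes(cohort$filtered, key), p("fixes.csv"))
    } else {
      write_fixes(cohort$filtered, p("fixes.csv"))
    }
    write_jsonl(cohort$truth_visits, p("truth_visits.jsonl"))
    write_jsonl(cohort$visits, p("visits.jsonl"))
    write_events(cohort$events, p("events.jsonl"))
    write_jsonl(cohort$prompts, p("prompts.jsonl"))
    write_jsonl(dplyr::select(cohort$responses, -"items"),
                p("responses.jsonl"))
    write_adherence(adherence, p("adherence.csv"))
    jsonlite::write_json(
      list(n_fixes = summary$n_fixes,
           n_participants = summary$n_participants,
           mean_fixes_per_participant = summary$mean_fixes_per_participant,
           n_prompts = nrow(cohort$prompts),
           n_responses = nrow(cohort$responses)),
      p("summary.json"), auto_unbox = TRUE, digits = NA)
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  structure(c(cohort, list(adherence = adherence, summary = summary,
                           video = video, manifest = manifest)),
            class = c("gemaflow_run", "gemaflow_cohort"))
}
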