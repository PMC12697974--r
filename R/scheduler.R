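# prompt_scheduler: declarative prompt rules evaluated against the merged
# fix/event/response stream. The evaluator is a fold over time-ordered
# records with explicit state, so feeding the stream in chunks (streaming)
# and all at once (batch) produce byte-identical prompt logs.

#' Prompt rule constructors
#'
#' A protocol is a set of declarative rules. Five kinds exist:
#' \describe{
#'   \item{TIME_WINDOW}{a prompt at the first fix whose local wall-clock time
#'     falls in `[window_start, window_end)`, at most `max_per_day` per local
#'     date. No fix in the window means no prompt that day: prompting is
#'     conditional on the device having transmitted a location in the slot.}
#'   \item{DWELL}{one prompt per visit, at the moment the device has been
#'     inside a fence of `geofence_class` for `min_dwell_s` seconds.}
#'   \item{FOLLOWUP_DWELL}{one prompt per visit at `min_dwell_s` (typically
#'     45 min), only in visits whose DWELL event fired.}
#'   \item{EXIT}{one prompt per visit when the device exits the fence.}
#'   \item{RESPONSE_CONTINGENT}{a prompt queued whenever an accepted response
#'     to `source_rule_id` satisfies an optional item comparison, delivered
#'     `delay_s` seconds after submission.}
#' }
#' Every prompt expires `expiry_s` seconds (default 3600) after delivery.
#'
#' @param rule_id Unique rule identifier; also the prompt-kind label used by
#'   the analytics.
#' @param window_start,window_end Local clock times "HH:MM"; the window is
#'   half-open `[start, end)`.
#' @param max_per_day Maximum prompts per local date (default 1).
#' @param min_dwell_s Dwell threshold in seconds.
#' @param geofence_class Fence class the rule binds to (default "park"), so
#'   a protocol generalises across fence sets.
#' @param source_rule_id Rule whose accepted responses trigger a
#'   response-contingent prompt.
#' @param item,op,value Optional item comparison for response-contingent
#'   triggers: item index (1-based), comparison operator ("<", "<=", "==",
#'   ">=", ">"), and value.
#' @param delay_s Delivery delay after the triggering submission (default 0).
#' @param expiry_s Seconds from delivery to expiry (default 3600).
#' @param survey_ref Opaque survey identifier the prompt links to.
#' @return A one-row rule tibble.
#' @name prompt_rules
NULL

new_rule <- function(rule_id, kind, survey_ref, expiry_s,
                     window_start = NA_character_, window_end = NA_character_,
                     max_per_day = NA_integer_, min_dwell_s = NA_real_,
                     geofence_class = NA_character_,
                     source_rule_id = NA_character_, trigger = list(NULL),
                     delay_s = 0) {
  if (!is.numeric(expiry_s) || expiry_s <= 0) {
    rlang::abort(sprintf("configuration error in rule '%s': expiry_s must be > 0", rule_id),
                 class = "gemaflow_config_error")
  }
  tibble::tibble(rule_id = as.character(rule_id), kind = kind,
                 window_start = window_start, window_end = window_end,
                 max_per_day = as.integer(max_per_day),
                 min_dwell_s = as.numeric(min_dwell_s),
                 geofence_class = geofence_class,
                 source_rule_id = source_rule_id,
                 trigger = trigger, delay_s = as.numeric(delay_s),
                 expiry_s = as.numeric(expiry_s),
                 survey_ref = as.character(survey_ref))
}

#' @rdname prompt_rules
#' @export
rule_time_window <- function(rule_id, window_start = "09:00",
                             window_end = "10:00", max_per_day = 1,
                             expiry_s = 3600, survey_ref = "survey") {
  if (parse_hhmm(window_start) >= parse_hhmm(window_end)) {
    rlang::abort(sprintf("configuration error in rule '%s': window_start must be before window_end", rule_id),
                 class = "gemaflow_config_error")
  }
  new_rule(rule_id, "TIME_WINDOW", survey_ref, expiry_s,
           window_start = window_start, window_end = window_end,
           max_per_day = max_per_day)
}

#' @rdname prompt_rules
#' @export
rule_dwell <- function(rule_id, min_dwell_s = 600, geofence_class = "park",
                       expiry_s = 3600, survey_ref = "survey") {
  if (min_dwell_s <= 0) {
    rlang::abort(sprintf("configuration error in rule '%s': min_dwell_s must be > 0", rule_id),
                 class = "gemaflow_config_error")
  }
  new_rule(rule_id, "DWELL", survey_ref, expiry_s,
           min_dwell_s = min_dwell_s, geofence_class = geofence_class)
}

#' @rdname prompt_rules
#' @export
rule_followup_dwell <- function(rule_id, min_dwell_s = 2700,
                                geofence_class = "park", expiry_s = 3600,
                                survey_ref = "survey") {
  if (min_dwell_s <= 0) {
    rlang::abort(sprintf("configuration error in rule '%s': min_dwell_s must be > 0", rule_id),
                 class = "gemaflow_config_error")
  }
  new_rule(rule_id, "FOLLOWUP_DWELL", survey_ref, expiry_s,
           min_dwell_s = min_dwell_s, geofence_class = geofence_class)
}

#' @rdname prompt_rules
#' @export
rule_exit <- function(rule_id, geofence_class = "park", expiry_s = 3600,
                      survey_ref = "survey") {
  new_rule(rule_id, "EXIT", survey_ref, expiry_s,
           geofence_class = geofence_class)
}

#' @rdname prompt_rules
#' @export
rule_response_contingent <- function(rule_id, source_rule_id, item = NULL,
                                     op = NULL, value = NULL, delay_s = 0,
                                     expiry_s = 3600, survey_ref = "survey") {
  if (!is.null(op) && !op %in% c("<", "<=", "==", ">=", ">")) {
    rlang::abort(sprintf("configuration error in rule '%s': unsupported comparison '%s'", rule_id, op),
                 class = "gemaflow_config_error")
  }
  trig <- list(item = item, op = op, value = value)
  new_rule(rule_id, "RESPONSE_CONTINGENT", survey_ref, expiry_s,
           source_rule_id = source_rule_id, trigger = list(trig),
           delay_s = delay_s)
}

#' Assemble a study protocol
#'
#' The protocol is the declarative instruction set of one study arm: prompt
#' rules, the participant timezone, the accuracy filter, the visit gap rule,
#' the compliance criteria, and the set of survey identifiers rules may
#' reference.
#'
#' @param rules A list of rule tibbles (see [prompt_rules]) or one bound
#'   rule tibble.
#' @param timezone IANA timezone for local-time windows and day counting.
#' @param max_radial_m Accuracy-filter threshold in metres (default 30).
#' @param max_gap_s Visit gap rule in seconds (default 43200).
#' @param criteria [compliance_criteria()] object.
#' @param surveys Character vector of known survey identifiers; every rule's
#'   `survey_ref` must be among them (configuration error otherwise).
#' @param delivery_delay_s Fixed delivery delay added to every trigger time
#'   (default 0: delivery is modelled as instantaneous).
#' @return A list of class `gemaflow_protocol`.
#' @export
protocol <- function(rules, timezone = "America/Toronto", max_radial_m = 30,
                     max_gap_s = 43200, criteria = compliance_criteria(),
                     surveys = NULL, delivery_delay_s = 0) {
  if (is.data.frame(rules)) rules <- list(rules)
  rules <- dplyr::bind_rows(rules)
  if (!nrow(rules)) {
    rlang::abort("configuration error: protocol needs at least one rule",
                 class = "gemaflow_config_error")
  }
  if (anyDuplicated(rules$rule_id)) {
    rlang::abort(sprintf("configuration error: duplicate rule_id '%s'",
                         rules$rule_id[duplicated(rules$rule_id)][1]),
                 class = "gemaflow_config_error")
  }
  check_timezone(timezone)
  surveys <- surveys %||% unique(rules$survey_ref)
  unknown <- setdiff(rules$survey_ref, surveys)
  if (length(unknown)) {
    rlang::abort(sprintf("configuration error: unknown survey_ref '%s'", unknown[1]),
                 class = "gemaflow_config_error")
  }
  rc <- rules$source_rule_id[rules$kind == "RESPONSE_CONTINGENT"]
  if (length(rc) && !all(rc %in% rules$rule_id)) {
    rlang::abort("configuration error: response-contingent rule references unknown source_rule_id",
                 class = "gemaflow_config_error")
  }
  structure(list(rules = rules, timezone = timezone,
                 max_radial_m = max_radial_m, max_gap_s = max_gap_s,
                 criteria = criteria, surveys = surveys,
                 delivery_delay_s = delivery_delay_s),
            class = "gemaflow_protocol")
}

# Dwell thresholds the visit detector needs, read off the protocol's rules.
protocol_thresholds <- function(protocol) {
  r <- protocol$rules
  dwell <- r$min_dwell_s[r$kind == "DWELL"]
  fup <- r$min_dwell_s[r$kind == "FOLLOWUP_DWELL"]
  list(dwell_s = if (length(dwell)) min(dwell) else 600,
       followup_s = if (length(fup)) min(fup) else 2700)
}

#' Create an empty scheduler state
#'
#' State carries the markers that make streaming evaluation equal batch
#' evaluation: which (rule, participant, date) triples already received a
#' time-window prompt, which (rule, visit) pairs already fired, and which
#' responses already triggered a chained prompt.
#'
#' @param protocol A `gemaflow_protocol`.
#' @return A list of class `gemaflow_sched_state`.
#' @export
scheduler_state <- function(protocol) {
  stopifnot(inherits(protocol, "gemaflow_protocol"))
  structure(list(protocol = protocol,
                 tw_sent = integer(),       # named counts: rule|participant|date
                 visit_sent = character(),  # keys rule|visit
                 rc_sent = character()),    # keys rule|source prompt id
            class = "gemaflow_sched_state")
}

prompt_tibble <- function(prompt_id = character(), participant_id = character(),
                          rule_id = character(), kind = character(),
                          geofence_id = character(), visit_id = character(),
                          trigger_t = numeric(), delivery_t = numeric(),
                          expiry_t = numeric(), survey_ref = character()) {
  tibble::tibble(prompt_id = prompt_id, participant_id = participant_id,
                 rule_id = rule_id, kind = kind, geofence_id = geofence_id,
                 visit_id = visit_id, trigger_t = trigger_t,
                 delivery_t = delivery_t, expiry_t = expiry_t,
                 survey_ref = survey_ref,
                 status = rep("PENDING", length(prompt_id)))
}

#' Evaluate protocol rules over a stream chunk
#'
#' The low-level streaming evaluator: feed any time-ordered chunk of fixes,
#' geofence events and accepted responses together with the current state;
#' receive the prompts triggered by that chunk and the updated state.
#' [schedule_prompts()] is the batch wrapper that feeds everything at once.
#'
#' @param state A [scheduler_state()].
#' @param fixes Fix tibble chunk (may be NULL/empty).
#' @param events Event tibble chunk from [detect_visits()] (may be NULL).
#' @param responses Accepted-response tibble chunk (may be NULL); used by
#'   response-contingent rules.
#' @param fences Optional `gemaflow_fences` used to resolve geofence classes
#'   (required when the protocol has location-contingent rules and events
#'   are fed).
#' @return A list with `prompts` (tibble of newly emitted prompts, in
#'   deterministic time order) and `state` (updated).
#' @export
evaluate_rules <- function(state, fixes = NULL, events = NULL,
                           responses = NULL, fences = NULL) {
  stopifnot(inherits(state, "gemaflow_sched_state"))
  proto <- state$protocol
  rules <- proto$rules
  tz <- proto$timezone
  ddelay <- proto$delivery_delay_s
  out <- list()

  has <- function(x) !is.null(x) && nrow(x) > 0

  fence_class <- NULL
  if (!is.null(fences)) {
    fence_class <- stats::setNames(fences$class, fences$geofence_id)
  }
  if (has(events)) {
    needs_class <- rules$kind %in% c("DWELL", "FOLLOWUP_DWELL", "EXIT")
    if (any(needs_class)) {
      if (is.null(fence_class)) {
        rlang::abort("configuration error: location-contingent rules need `fences` to resolve geofence classes",
                     class = "gemaflow_config_error")
      }
      missing_cls <- setdiff(rules$geofence_class[needs_class],
                             unname(fence_class))
      if (length(missing_cls)) {
        rlang::abort(sprintf("configuration error: rule references unknown geofence class '%s'",
                             missing_cls[1]),
                     class = "gemaflow_config_error")
      }
    }
  }

  if (has(fixes)) {
    check_sorted(fixes$participant_id, fixes$t)
    tw <- rules[rules$kind == "TIME_WINDOW", ]
    if (nrow(tw) && nrow(fixes)) {
      dates <- local_date(fixes$t, tz)
      sod <- local_seconds_of_day(fixes$t, tz)
      for (i in seq_len(nrow(tw))) {
        ws <- parse_hhmm(tw$window_start[i]); we <- parse_hhmm(tw$window_end[i])
        elig <- which(sod >= ws & sod < we)
        if (!length(elig)) next
        cand <- tibble::tibble(participant_id = fixes$participant_id[elig],
                               t = fixes$t[elig], date = dates[elig])
        keys <- paste(tw$rule_id[i], cand$participant_id, cand$date, sep = "|")
        # respect max_per_day across chunks: counts persist in state
        take <- unlist(lapply(split(seq_len(nrow(cand)), keys), function(ix) {
          key <- keys[ix[1]]
          prior <- if (key %in% names(state$tw_sent)) state$tw_sent[[key]] else 0L
          utils::head(ix, max(0L, tw$max_per_day[i] - prior))
        }), use.names = FALSE)
        take <- sort(take)
        cand <- cand[take, ]; keys <- keys[take]
        if (!nrow(cand)) next
        add <- table(keys)
        for (key in names(add)) {
          state$tw_sent[[key]] <- (if (key %in% names(state$tw_sent))
            state$tw_sent[[key]] else 0L) + as.integer(add[[key]])
        }
        out[[length(out) + 1L]] <- prompt_tibble(
          prompt_id = vapply(seq_len(nrow(cand)), function(k)
            make_uuid("prompt", tw$rule_id[i], cand$participant_id[k],
                      cand$t[k]), character(1)),
          participant_id = cand$participant_id,
          rule_id = rep(tw$rule_id[i], nrow(cand)),
          kind = rep("TIME_WINDOW", nrow(cand)),
          geofence_id = rep(NA_character_, nrow(cand)),
          visit_id = rep(NA_character_, nrow(cand)),
          trigger_t = cand$t,
          delivery_t = cand$t + ddelay,
          expiry_t = cand$t + ddelay + tw$expiry_s[i],
          survey_ref = rep(tw$survey_ref[i], nrow(cand)))
      }
    }
  }

  if (has(events)) {
    ev_map <- c(DWELL = "DWELL", FOLLOWUP_DWELL = "FOLLOWUP_DWELL",
                EXIT = "EXIT")
    loc <- rules[rules$kind %in% names(ev_map), ]
    for (i in seq_len(nrow(loc))) {
      sel <- events[events$kind == ev_map[[loc$kind[i]]] &
                      fence_class[events$geofence_id] %in% loc$geofence_class[i], ]
      if (!nrow(sel)) next
      keys <- paste(loc$rule_id[i], sel$visit_id, sep = "|")
      new <- !keys %in% state$visit_sent
      sel <- sel[new, ]; keys <- keys[new]
      if (!nrow(sel)) next
      state$visit_sent <- c(state$visit_sent, keys)
      out[[length(out) + 1L]] <- prompt_tibble(
        prompt_id = vapply(seq_len(nrow(sel)), function(k)
          make_uuid("prompt", loc$rule_id[i], sel$visit_id[k], sel$t[k]),
          character(1)),
        participant_id = sel$participant_id,
        rule_id = rep(loc$rule_id[i], nrow(sel)),
        kind = rep(loc$kind[i], nrow(sel)),
        geofence_id = sel$geofence_id,
        visit_id = sel$visit_id,
        trigger_t = sel$t,
        delivery_t = sel$t + ddelay,
        expiry_t = sel$t + ddelay + loc$expiry_s[i],
        survey_ref = rep(loc$survey_ref[i], nrow(sel)))
    }
  }

  if (has(responses)) {
    rc <- rules[rules$kind == "RESPONSE_CONTINGENT", ]
    for (i in seq_len(nrow(rc))) {
      sel <- responses[responses$rule_id == rc$source_rule_id[i], ]
      if (!nrow(sel)) next
      trig <- rc$trigger[[i]]
      if (!is.null(trig$item)) {
        keep <- vapply(seq_len(nrow(sel)), function(k) {
          items <- sel$items[[k]]
          length(items) >= trig$item &&
            do.call(trig$op, list(items[trig$item], trig$value))
        }, logical(1))
        sel <- sel[keep, ]
      }
      if (!nrow(sel)) next
      keys <- paste(rc$rule_id[i], sel$prompt_id, sep = "|")
      new <- !keys %in% state$rc_sent
      sel <- sel[new, ]; keys <- keys[new]
      if (!nrow(sel)) next
      state$rc_sent <- c(state$rc_sent, keys)
      trig_t <- sel$submit_t + rc$delay_s[i]
      out[[length(out) + 1L]] <- prompt_tibble(
        prompt_id = vapply(seq_len(nrow(sel)), function(k)
          make_uuid("prompt", rc$rule_id[i], sel$prompt_id[k]), character(1)),
        participant_id = sel$participant_id,
        rule_id = rep(rc$rule_id[i], nrow(sel)),
        kind = rep("RESPONSE_CONTINGENT", nrow(sel)),
        geofence_id = rep(NA_character_, nrow(sel)),
        visit_id = rep(NA_character_, nrow(sel)),
        trigger_t = trig_t,
        delivery_t = trig_t + ddelay,
        expiry_t = trig_t + ddelay + rc$expiry_s[i],
        survey_ref = rep(rc$survey_ref[i], nrow(sel)))
    }
  }

  prompts <- if (length(out)) dplyr::bind_rows(out) else prompt_tibble()
  prompts <- dplyr::arrange(prompts, .data$participant_id, .data$trigger_t,
                            .data$rule_id)
  list(prompts = prompts, state = state)
}

#' Batch prompt scheduling
#'
#' Evaluates a whole study's stream at once: equivalent to streaming the
#' same records through [evaluate_rules()] in any time-ordered chunking.
#'
#' @param fixes Accuracy-filtered, time-sorted fix tibble.
#' @param events Event tibble from [detect_visits()].
#' @param protocol A `gemaflow_protocol`.
#' @param fences The `gemaflow_fences` tibble (needed for
#'   location-contingent rules).
#' @param responses Optional accepted responses (for response-contingent
#'   rules evaluated post hoc).
#' @return A prompt tibble: `prompt_id` (UUID-format, deterministic),
#'   `participant_id`, `rule_id`, `kind`, `geofence_id`, `visit_id`,
#'   `trigger_t`, `delivery_t`, `expiry_t`, `survey_ref`, `status`.
#' @export
schedule_prompts <- function(fixes, events, protocol, fences = NULL,
                             responses = NULL) {
  st <- scheduler_state(protocol)
  evaluate_rules(st, fixes = fixes, events = events, responses = responses,
                 fences = fences)$prompts
}

#' Record a survey submission against a prompt
#'
#' A submission is accepted iff it arrives in `[delivery_t, expiry_t]` and
#' the prompt is still pending. Late submissions expire the prompt and are
#' rejected; a second submission to an answered prompt is rejected as a
#' duplicate. A submission timestamped before delivery is a clock
#' inconsistency and errors.
#'
#' @param prompts The prompt tibble.
#' @param prompt_id Identifier of the prompt being answered.
#' @param submit_t Submission epoch seconds.
#' @param items Integer item scores of the survey (list or vector).
#' @param attachments Count of audio/photo/video attachments (default 0).
#' @return A list: `status` ("ACCEPTED", "REJECTED_EXPIRED",
#'   "REJECTED_DUPLICATE"), `prompts` (updated tibble), and `response` (a
#'   one-row response tibble when accepted, else NULL).
#' @export
accept_response <- function(prompts, prompt_id, submit_t, items = integer(),
                            attachments = 0L) {
  i <- match(prompt_id, prompts$prompt_id)
  if (is.na(i)) {
    rlang::abort(sprintf("linkage error: unknown prompt_id '%s'", prompt_id),
                 class = "gemaflow_linkage_error")
  }
  if (submit_t < prompts$delivery_t[i]) {
    rlang::abort(sprintf("clock inconsistency: submission at %0.f precedes delivery at %0.f",
                         submit_t, prompts$delivery_t[i]),
                 class = "gemaflow_clock_error")
  }
  if (prompts$status[i] == "ANSWERED") {
    return(list(status = "REJECTED_DUPLICATE", prompts = prompts,
                response = NULL))
  }
  if (submit_t > prompts$expiry_t[i]) {
    prompts$status[i] <- "EXPIRED"
    return(list(status = "REJECTED_EXPIRED", prompts = prompts,
                response = NULL))
  }
  prompts$status[i] <- "ANSWERED"
  resp <- tibble::tibble(
    prompt_id = prompt_id,
    participant_id = prompts$participant_id[i],
    rule_id = prompts$rule_id[i],
    kind = prompts$kind[i],
    submit_t = submit_t,
    latency_s = submit_t - prompts$delivery_t[i],
    items = list(as.integer(unlist(items))),
    attachments = as.integer(attachments))
  list(status = "ACCEPTED", prompts = prompts, response = resp)
}

#' Process a batch of submissions
#'
#' Applies [accept_response()] to each submission in submission-time order.
#'
#' @param prompts The prompt tibble.
#' @param submissions Tibble with columns `prompt_id`, `submit_t`, and
#'   optionally `items` (list-column) and `attachments`.
#' @return A list: `prompts` (updated), `responses` (accepted responses),
#'   `statuses` (per-submission outcome, in input order).
#' @export
process_submissions <- function(prompts, submissions) {
  n <- nrow(submissions)
  statuses <- character(n)
  resp <- vector("list", n)
  ord <- order(submissions$submit_t)
  for (k in ord) {
    r <- accept_response(
      prompts, submissions$prompt_id[k], submissions$submit_t[k],
      items = if ("items" %in% names(submissions)) submissions$items[[k]] else integer(),
      attachments = if ("attachments" %in% names(submissions)) submissions$attachments[k] else 0L)
    prompts <- r$prompts
    statuses[k] <- r$status
    if (!is.null(r$response)) resp[[k]] <- r$response
  }
  responses <- dplyr::bind_rows(resp[!vapply(resp, is.null, logical(1))])
  if (!nrow(responses)) {
    responses <- tibble::tibble(prompt_id = character(),
                                participant_id = character(),
                                rule_id = character(), kind = character(),
                                submit_t = numeric(), latency_s = numeric(),
                                items = list(), attachments = integer())
  }
  list(prompts = prompts, responses = responses, statuses = statuses)
}

#' Expire pending prompts
#'
#' Marks every PENDING prompt whose expiry time has passed as EXPIRED.
#'
#' @param prompts The prompt tibble.
#' @param now Epoch seconds of "now" (default `Inf`: end-of-study closure).
#' @return The updated prompt tibble.
#' @export
finalize_prompts <- function(prompts, now = Inf) {
  exp <- prompts$status == "PENDING" & prompts$expiry_t < now
  prompts$status[exp] <- "EXPIRED"
  prompts
}

#' Invite-code registry
#'
#' Participants are identified by an opaque invite code that binds all their
#' data to one study arm's protocol. Codes must be unique across arms.
#'
#' @param code Character vector of invite codes.
#' @param arm Character vector of arm identifiers (recycled).
#' @return A tibble of class `gemaflow_registry`.
#' @export
invite_registry <- function(code = character(), arm = character()) {
  out <- tibble::tibble(code = as.character(code),
                        arm = rep_len(as.character(arm), length(code)))
  if (anyDuplicated(out$code)) {
    rlang::abort(sprintf("configuration error: duplicate invite code '%s' across arms",
                         out$code[duplicated(out$code)][1]),
                 class = "gemaflow_config_error")
  }
  class(out) <- c("gemaflow_registry", class(out))
  out
}

#' @rdname invite_registry
#' @param registry An existing registry.
#' @export
assign_invite_code <- function(registry, code, arm) {
  invite_registry(c(registry$code, code), c(registry$arm, rep_len(arm, length(code))))
}

#' Resolve the study arm of an invite code
#'
#' @param registry A `gemaflow_registry`.
#' @param code Invite code(s) to resolve.
#' @return Character vector of arm ids; unknown codes error (data from
#'   unknown codes is rejected, never silently accepted).
#' @export
arm_for_code <- function(registry, code) {
  i <- match(code, registry$code)
  if (anyNA(i)) {
    rlang::abort(sprintf("rejected: unknown invite code '%s'", code[is.na(i)][1]),
                 class = "gemaflow_rejected_error")
  }
  registry$arm[i]
}

#' Keep only records from enrolled invite codes
#'
#' Joins the registry onto a data frame keyed by `participant_id` (the
#' invite code); records from unknown codes are dropped with a warning
#' listing the rejected codes.
#'
#' @param data A tibble with a `participant_id` column.
#' @param registry A `gemaflow_registry`.
#' @return The input restricted to enrolled codes, with an `arm` column.
#' @export
filter_enrolled <- function(data, registry) {
  unknown <- setdiff(unique(data$participant_id), registry$code)
  if (length(unknown)) {
    rlang::warn(paste0("rejected data from unknown invite code(s): ",
                       paste(unknown, collapse = ", ")))
  }
  dplyr::inner_join(data,
                    tibble::tibble(participant_id = registry$code,
                                   arm = registry$arm),
                    by = "participant_id")
}
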