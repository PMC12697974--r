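# prompt scheduler: window rules, event rules, expiry, chaining, streaming

tz <- "America/Toronto"
epoch <- function(d, hms) as.numeric(as.POSIXct(paste(d, hms), tz = tz))

morning_only <- protocol(rule_time_window("morning", "09:00", "10:00",
                                          survey_ref = "WHO5"),
                         timezone = tz)

test_that("a time-window rule fires once, at the first in-window fix", {
  f <- gnss_fixes("p1", 43, -81.2,
                  t = c(epoch("2023-08-01", "08:30:00"),
                        epoch("2023-08-01", "09:05:00"),
                        epoch("2023-08-01", "09:40:00")),
                  accuracy_m = 5)
  pr <- schedule_prompts(f, NULL, morning_only)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$trigger_t, epoch("2023-08-01", "09:05:00"))
  expect_equal(pr$expiry_t - pr$delivery_t, 3600)

  # no fix inside the window -> no prompt that day
  g <- gnss_fixes("p1", 43, -81.2,
                  t = c(epoch("2023-08-02", "08:30:00"),
                        epoch("2023-08-02", "12:00:00")),
                  accuracy_m = 5)
  expect_equal(nrow(schedule_prompts(g, NULL, morning_only)), 0)

  # half-open window: a fix at exactly 10:00 does not qualify
  h <- gnss_fixes("p1", 43, -81.2, t = epoch("2023-08-03", "10:00:00"),
                  accuracy_m = 5)
  expect_equal(nrow(schedule_prompts(h, NULL, morning_only)), 0)

  # one prompt per rule per participant per local date, across days
  i <- gnss_fixes("p1", 43, -81.2,
                  t = c(epoch("2023-08-04", "09:10:00"),
                        epoch("2023-08-04", "09:30:00"),
                        epoch("2023-08-05", "09:10:00")),
                  accuracy_m = 5)
  pr2 <- schedule_prompts(i, NULL, morning_only)
  expect_equal(nrow(pr2), 2)
})

test_that("a 50-minute park visit yields engagement, follow-up and exit prompts", {
  sq <- rbind(c(0, 0), c(0.01, 0), c(0.01, 0.01), c(0, 0.01), c(0, 0))
  fences <- geofences("park_1", list(list(list(sq))), class = "park")
  t0 <- epoch("2023-08-01", "14:00:00")
  inside <- gnss_fixes("p1", 0.005, 0.005, t0 + seq(0, 50 * 60, 120), 5)
  outside <- gnss_fixes("p1", 0.05, 0.05, t0 + 52 * 60, 5)
  f <- dplyr::bind_rows(inside, outside)
  det <- detect_visits(f, fences)
  pr <- schedule_prompts(f, det$events, parkseek_protocol(), fences)
  pr_loc <- pr[pr$kind != "TIME_WINDOW", ]
  expect_setequal(pr_loc$rule_id, c("engagement", "followup", "exit"))
  expect_equal(pr_loc$trigger_t[pr_loc$rule_id == "engagement"], t0 + 600)
  expect_equal(pr_loc$trigger_t[pr_loc$rule_id == "followup"], t0 + 2760)
  expect_equal(pr_loc$trigger_t[pr_loc$rule_id == "exit"], t0 + 52 * 60)
  # one prompt of each kind per visit
  expect_equal(anyDuplicated(paste(pr_loc$rule_id, pr_loc$visit_id)), 0)
})

test_that("responses are accepted only inside the expiry window, once", {
  f <- gnss_fixes("p1", 43, -81.2, epoch("2023-08-01", "09:10:00"), 5)
  pr <- schedule_prompts(f, NULL, morning_only)
  d <- pr$delivery_t[1]

  r <- accept_response(pr, pr$prompt_id[1], d + 59 * 60, items = c(1, 2, 3, 4, 5))
  expect_equal(r$status, "ACCEPTED")
  expect_equal(r$response$latency_s, 59 * 60)
  expect_equal(r$prompts$status[1], "ANSWERED")

  # one hour and one minute after delivery: expired
  r2 <- accept_response(pr, pr$prompt_id[1], d + 61 * 60)
  expect_equal(r2$status, "REJECTED_EXPIRED")
  expect_equal(r2$prompts$status[1], "EXPIRED")

  # exactly at expiry: still accepted
  r3 <- accept_response(pr, pr$prompt_id[1], d + 3600)
  expect_equal(r3$status, "ACCEPTED")

  # duplicate submission
  r4 <- accept_response(r$prompts, pr$prompt_id[1], d + 100)
  expect_equal(r4$status, "REJECTED_DUPLICATE")

  # clock inconsistency
  expect_error(accept_response(pr, pr$prompt_id[1], d - 1),
               class = "gemaflow_clock_error")
  # unknown prompt
  expect_error(accept_response(pr, "nope", d), class = "gemaflow_linkage_error")
})

test_that("response-contingent rules chain off accepted responses", {
  proto <- protocol(list(
    rule_time_window("morning", "09:00", "10:00", survey_ref = "WHO5"),
    rule_response_contingent("wellness_followup", "morning",
                             item = 1, op = "<=", value = 2,
                             delay_s = 1800, survey_ref = "WHO5")),
    timezone = tz)
  f <- gnss_fixes(c("p1", "p2"), 43, -81.2,
                  c(epoch("2023-08-01", "09:10:00"),
                    epoch("2023-08-01", "09:20:00")), 5)
  st <- scheduler_state(proto)
  ev1 <- evaluate_rules(st, fixes = f)
  expect_equal(nrow(ev1$prompts), 2)
  # p1 scores low on item 1 (triggers), p2 scores high (does not)
  sub <- tibble::tibble(
    prompt_id = ev1$prompts$prompt_id,
    submit_t = ev1$prompts$delivery_t + 300,
    items = list(c(1L, 4L, 4L, 4L, 4L), c(5L, 5L, 5L, 5L, 5L)),
    attachments = 0L)
  acc <- process_submissions(ev1$prompts, sub)
  ev2 <- evaluate_rules(ev1$state, responses = acc$responses)
  expect_equal(nrow(ev2$prompts), 1)
  expect_equal(ev2$prompts$participant_id, "p1")
  expect_equal(ev2$prompts$trigger_t,
               acc$responses$submit_t[acc$responses$participant_id == "p1"] + 1800)
  # feeding the same responses again does not re-trigger
  ev3 <- evaluate_rules(ev2$state, responses = acc$responses)
  expect_equal(nrow(ev3$prompts), 0)
})

test_that("evaluation is deterministic and streaming equals batch", {
  co <- shared_cohort
  proto <- co$protocol
  batch1 <- schedule_prompts(co$filtered, co$events, proto, co$fences)
  batch2 <- schedule_prompts(co$filtered, co$events, proto, co$fences)
  expect_identical(batch1, batch2)

  # stream in day-sized chunks: identical prompt log
  cuts <- seq(min(co$filtered$t) - 1, max(co$filtered$t) + 86400, by = 86400)
  st <- scheduler_state(proto)
  parts <- list()
  for (k in seq_len(length(cuts) - 1)) {
    fx <- co$filtered[co$filtered$t > cuts[k] & co$filtered$t <= cuts[k + 1], ]
    ev <- co$events[co$events$t > cuts[k] & co$events$t <= cuts[k + 1], ]
    out <- evaluate_rules(st, fixes = fx, events = ev, fences = co$fences)
    st <- out$state
    parts[[k]] <- out$prompts
  }
  streamed <- dplyr::bind_rows(parts)
  ord <- order(streamed$participant_id, streamed$trigger_t, streamed$rule_id)
  expect_equal(as.data.frame(streamed[ord, ]),
               as.data.frame(batch1[order(batch1$participant_id,
                                          batch1$trigger_t,
                                          batch1$rule_id), ]),
               ignore_attr = TRUE)
})

test_that("protocol validation catches configuration errors at load", {
  expect_error(rule_time_window("m", "10:00", "09:00"),
               class = "gemaflow_config_error")
  expect_error(rule_dwell("d", min_dwell_s = 0),
               class = "gemaflow_config_error")
  expect_error(rule_time_window("m", expiry_s = 0),
               class = "gemaflow_config_error")
  expect_error(protocol(list(rule_exit("x"), rule_exit("x"))),
               class = "gemaflow_config_error")
  expect_error(protocol(rule_exit("x", survey_ref = "S1"), surveys = "S2"),
               class = "gemaflow_config_error")
  expect_error(protocol(rule_exit("x"), timezone = "Mars/Olympus"),
               class = "gemaflow_config_error")
  # rule bound to a class absent from the fence set: error at evaluation
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  fences <- geofences("z", list(list(list(sq))), class = "commercial")
  proto <- protocol(rule_exit("exit", geofence_class = "park"))
  ev <- tibble::tibble(kind = "EXIT", participant_id = "p",
                       geofence_id = "z", t = 0, visit_id = "v")
  expect_error(schedule_prompts(NULL, ev, proto, fences),
               class = "gemaflow_config_error")
})

test_that("invite codes bind participants to arms and reject unknown codes", {
  reg <- invite_registry(c("AAA", "BBB"), c("control", "intervention"))
  reg <- assign_invite_code(reg, "CCC", "control")
  expect_equal(arm_for_code(reg, c("AAA", "CCC")), c("control", "control"))
  expect_error(arm_for_code(reg, "ZZZ"), class = "gemaflow_rejected_error")
  expect_error(assign_invite_code(reg, "AAA", "intervention"),
               class = "gemaflow_config_error")
  # data from unknown codes is dropped, enrolled data keeps its arm
  f <- gnss_fixes(c("AAA", "ZZZ"), 43, -81.2, c(0, 0), 5)
  expect_warning(kept <- filter_enrolled(f, reg), "ZZZ")
  expect_equal(kept$participant_id, "AAA")
  expect_equal(kept$arm, "control")
})
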