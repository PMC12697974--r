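# analytics: adherence/latency table, location totals, scale scoring,
# recruitment funnel

fake_prompts <- function(pid, rule, n, t0 = 0) {
  tibble::tibble(
    prompt_id = sprintf("%s-%s-%d", pid, rule, seq_len(n)),
    participant_id = pid, rule_id = rule, kind = "TIME_WINDOW",
    geofence_id = NA_character_, visit_id = NA_character_,
    trigger_t = t0 + seq_len(n), delivery_t = t0 + seq_len(n),
    expiry_t = t0 + seq_len(n) + 3600, survey_ref = "WHO5",
    status = "PENDING")
}
fake_response <- function(prompts, i, latency_s) {
  tibble::tibble(prompt_id = prompts$prompt_id[i],
                 participant_id = prompts$participant_id[i],
                 rule_id = prompts$rule_id[i], kind = prompts$kind[i],
                 submit_t = prompts$delivery_t[i] + latency_s,
                 latency_s = latency_s, items = list(integer()),
                 attachments = 0L)
}

test_that("adherence is the participant-mean of answered/sent with sample SD", {
  p <- dplyr::bind_rows(fake_prompts("a", "morning", 2),
                        fake_prompts("b", "morning", 2))
  # a answers 2/2, b answers 1/2 -> mean 75%, sample SD of {100, 50} = 35.36%
  r <- dplyr::bind_rows(fake_response(p, 1, 60), fake_response(p, 2, 120),
                        fake_response(p, 3, 300))
  tab <- adherence_table(p, r)
  expect_equal(tab$n_sent, 4)
  expect_equal(tab$n_participants_sent, 2)
  expect_equal(tab$adherence_pct_mean, 75)
  expect_equal(tab$adherence_pct_sd, 35.35534, tolerance = 1e-6)
  # latency in whole floored minutes: {1, 2, 5} -> median 2
  expect_equal(tab$latency_median_min, 2)
})

test_that("participants sent no prompts of a kind stay out of that row", {
  p <- dplyr::bind_rows(fake_prompts("a", "morning", 2),
                        fake_prompts("b", "evening", 2))
  r <- fake_response(p, 1, 59)  # 59 s floors to 0 minutes
  tab <- adherence_table(p, r)
  expect_equal(tab$n_participants_sent,
               c(morning = 1, evening = 1), ignore_attr = TRUE)
  m <- tab[tab$prompt_kind == "morning", ]
  expect_equal(m$adherence_pct_mean, 50)
  expect_equal(m$latency_median_min, 0)
  # a kind with zero accepted responses: adherence 0, latency unavailable
  e <- tab[tab$prompt_kind == "evening", ]
  expect_equal(e$adherence_pct_mean, 0)
  expect_true(is.na(e$latency_median_min))
  # orphan responses are a linkage error
  bad <- fake_response(p, 1, 60); bad$prompt_id <- "ghost"
  expect_error(adherence_table(p, bad), class = "gemaflow_linkage_error")
})

test_that("n_sent per kind conserves the scheduler's prompt count", {
  co <- shared_cohort
  tab <- adherence_table(co$prompts, co$responses)
  expect_equal(sum(tab$n_sent), nrow(co$prompts))
  expect_equal(sum(tab$n_sent * NA^0), nrow(co$prompts)) # no NA rows
  # no latency ever exceeds the one-hour expiry
  expect_lte(max(co$responses$latency_s), 3600)
})

test_that("location totals count unique fixes and round the mean half-up", {
  f <- gnss_fixes(rep(c("a", "b"), c(3, 2)), 43, -81,
                  t = c(0, 120, 120, 0, 60), accuracy_m = 5)
  # the duplicated (a, t=120) record counts once: 4 unique fixes
  s <- summary_counts(f)
  expect_equal(s$n_fixes, 4)
  expect_equal(s$n_participants, 2)
  expect_equal(s$mean_fixes_per_participant, 2)
  expect_equal(s$per_participant[[1]]$n_fixes, c(2, 2))
  # single participant: mean equals the count
  s1 <- summary_counts(f[f$participant_id == "a", ])
  expect_equal(s1$mean_fixes_per_participant, 2)
})

test_that("WHO-5 and PROMIS-SD scores are item sums within range", {
  expect_equal(score_scale("WHO5", c(5, 5, 5, 5, 5))$raw, 25)
  expect_equal(score_scale("WHO5", c(0, 0, 0, 0, 0))$raw, 0)
  expect_equal(score_scale("PROMIS_SD", rep(5, 8))$raw, 40)
  expect_equal(score_scale("PROMIS_SD", rep(1, 8))$raw, 8)
  # wrong item count / out-of-range items name the offender
  expect_error(score_scale("WHO5", rep(3, 4)), "needs 5 items",
               class = "gemaflow_scoring_error")
  expect_error(score_scale("WHO5", c(3, 6, 3, 3, 3)), "item 2",
               class = "gemaflow_scoring_error")
  expect_error(score_scale("PROMIS_SD", c(0, rep(3, 7))), "item 1",
               class = "gemaflow_scoring_error")
  # permutation invariance and additivity
  set.seed(31)
  for (k in 1:10) {
    items <- sample(0:5, 5, replace = TRUE)
    expect_equal(score_scale("WHO5", items)$raw,
                 score_scale("WHO5", sample(items))$raw)
    expect_equal(score_scale("WHO5", items)$raw, sum(items))
  }
})

test_that("funnel percentages match hand arithmetic and are scale-invariant", {
  fr <- funnel_report(1379, 96, 55, 38)
  expect_equal(fr$pct_of_previous[fr$stage == "consented"], 7)
  expect_equal(fr$n, c(1379, 96, 55, 38))
  # compliant / consented = 38/96 -> 40%
  expect_equal(round_half_up(100 * fr$n[4] / fr$n[2]), 40)
  # degenerate: constant counts -> all stage rates 100
  expect_true(all(funnel_report(5, 5, 5, 5)$pct_of_previous[-1] == 100))
  # scale invariance
  fr10 <- funnel_report(13790, 960, 550, 380)
  expect_equal(fr10$pct_of_previous, fr$pct_of_previous)
  # increasing counts are inconsistent
  expect_error(funnel_report(10, 12, 5, 3), class = "gemaflow_config_error")
})

test_that("video rates report both denominator readings", {
  co <- shared_cohort
  vr <- video_rate(co$prompts, co$responses)
  expect_equal(vr$denominator, c("engagement", "engagement_plus_followup"))
  expect_true(all(vr$n_videos <= vr$n_prompts))
  expect_gte(vr$n_prompts[2], vr$n_prompts[1])
})

test_that("compliance summary combines days, responses and the exit survey", {
  tz <- "UTC"
  f <- gnss_fixes(rep(c("a", "b"), c(8, 3)), 43, -81,
                  t = c(86400 * (0:7) + 100, 86400 * (0:2) + 100),
                  accuracy_m = 5)
  r <- tibble::tibble(participant_id = c("a", "b"), prompt_id = c("x", "y"),
                      rule_id = "morning", kind = "TIME_WINDOW",
                      submit_t = 1, latency_s = 1,
                      items = list(integer(), integer()), attachments = 0L)
  cs <- compliance_summary(f, r, exit_done = TRUE, tz = tz)
  expect_equal(cs$compliant, c(TRUE, FALSE))  # b has only 3 unique days
})
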