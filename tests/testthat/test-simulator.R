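# cohort simulator: fence generator contract, motion gating, determinism,
# ground-truth consistency

test_that("the fence generator emits valid convex, concave, holed and multi-part parks", {
  f <- generate_geofences(n_parks = 5, n_landuse = 25, seed = 9)
  parks <- f[f$class == "park", ]
  shapes <- vapply(parks$attributes, function(a) a$shape, character(1))
  expect_true(all(c("convex", "concave", "holed", "multipart") %in% shapes))
  # multi-part park really is a MultiPolygon; holed park has an inner ring
  expect_gte(length(parks$geometry[[which(shapes == "multipart")[1]]]), 2)
  expect_gte(length(parks$geometry[[which(shapes == "holed")[1]]][[1]]), 2)
  # land-use tiles tile the town and include a residential class
  expect_true("residential" %in% f$class)
  expect_equal(sum(f$class != "park"), 25)
  # every anchor is inside its own park (by the engine's own predicate
  # and by the independent oracle)
  a_lat <- vapply(parks$attributes, function(a) a$anchor_lat, numeric(1))
  a_lon <- vapply(parks$attributes, function(a) a$anchor_lon, numeric(1))
  pf <- parks; class(pf) <- class(f)
  inside <- fence_contains(pf, a_lat, a_lon)
  expect_true(all(diag(inside)))
  expect_true(all(diag(oracle_contains(pf, a_lat, a_lon))))
  # determinism: same seed, identical FeatureCollection
  f2 <- generate_geofences(n_parks = 5, n_landuse = 25, seed = 9)
  expect_identical(f$geometry, f2$geometry)
  expect_identical(f$class, f2$class)
})

test_that("sampling pauses 10 minutes into stillness and resumes on motion", {
  # walk for 20 min, stand still for 3 h, walk again
  t_walk1 <- seq(0, 1200, by = 60)
  t_still <- 1200 + 3 * 3600
  t_walk2 <- seq(t_still, t_still + 600, by = 60)
  track <- tibble::tibble(
    t = c(t_walk1, t_still, t_walk2[-1]),
    lat = c(43 + t_walk1 * 1e-5, rep(43 + 1200 * 1e-5, 1),
            43 + 1200 * 1e-5 + (t_walk2[-1] - t_still) * 1e-5),
    lon = -81)
  fx <- motion_gated_fixes(track, sampling_policy(interval_s = 120,
                                                  pause_after_motionless_s = 600))
  # no fixes between (motion end + 600 s) and motion resumption
  gap <- fx$t[fx$t > 1200 + 600 & fx$t < t_still]
  expect_length(gap, 0)
  # but sampling continued through the first 10 min of stillness
  expect_true(any(fx$t > 1200 & fx$t <= 1800))
  # and resumed with motion
  expect_true(any(fx$t >= t_still))
  # cadence while moving is the sampling interval
  expect_true(all(diff(fx$t[fx$t <= 1200]) == 120))
})

test_that("cohort simulation is deterministic in the seed", {
  cfg <- sim_config(n_participants = 2, study_days = 3, seed = 77)
  f <- generate_geofences(n_parks = 4, n_landuse = 16, seed = 5)
  a <- simulate_cohort(cfg, parkseek_profile(), f)
  b <- simulate_cohort(cfg, parkseek_profile(), f)
  expect_identical(as.data.frame(a$fixes), as.data.frame(b$fixes))
  expect_identical(as.data.frame(a$prompts), as.data.frame(b$prompts))
  expect_identical(as.data.frame(a$responses[, c("prompt_id", "submit_t")]),
                   as.data.frame(b$responses[, c("prompt_id", "submit_t")]))
  c <- simulate_cohort(sim_config(n_participants = 2, study_days = 3,
                                  seed = 78), parkseek_profile(), f)
  expect_false(identical(as.data.frame(a$fixes), as.data.frame(c$fixes)))
})

test_that("a certain responder yields 100% adherence on morning prompts", {
  profile <- behavior_profile(
    park_visits_per_day = 0,
    response_probability = c(morning = 1, evening = 0, engagement = 0,
                             followup = 0, exit = 0),
    p_morning_active = 1, p_evening_active = 0)
  cfg <- sim_config(n_participants = 3, study_days = 5, seed = 21)
  co <- simulate_cohort(cfg, profile, shared_fences)
  morning <- co$prompts[co$prompts$rule_id == "morning", ]
  # active every morning -> a prompt every participant-day
  expect_equal(nrow(morning), 15)
  expect_true(all(morning$status == "ANSWERED"))
  adh <- adherence_table(co$prompts, co$responses)
  expect_equal(adh$adherence_pct_mean[adh$prompt_kind == "morning"], 100)
  expect_equal(adh$adherence_pct_sd[adh$prompt_kind == "morning"], 0)
})

test_that("simulated accuracy exercises the 30 m filter without gutting the stream", {
  co <- shared_cohort
  frac_dropped <- 1 - nrow(co$filtered) / nrow(co$fixes)
  expect_gt(frac_dropped, 0.005)
  expect_lt(frac_dropped, 0.15)
})

test_that("detected visits agree with ground-truth intervals for clear stays", {
  co <- shared_cohort
  truth <- co$truth_visits
  truth$dwell <- truth$exit_t - truth$entry_t
  long <- truth[truth$dwell >= 12 * 60, ]
  expect_gte(nrow(long), 5)  # the shared cohort always has clear stays
  tol <- co$cfg$sampling$interval_s + 60
  matched <- vapply(seq_len(nrow(long)), function(i) {
    v <- co$visits[co$visits$participant_id == long$participant_id[i] &
                     co$visits$geofence_id == long$geofence_id[i], ]
    v <- v[!is.na(v$exit_t), ]
    any(abs(v$entry_t - long$entry_t[i]) <= tol &
          abs(v$exit_t - long$exit_t[i]) <= tol)
  }, logical(1))
  expect_gte(mean(matched), 0.95)
})

test_that("follow-up prompts never outnumber engagement prompts", {
  co <- shared_cohort
  n <- table(factor(co$prompts$rule_id,
                    levels = c("engagement", "followup", "exit")))
  expect_lte(n[["followup"]], n[["engagement"]])
  expect_lte(n[["engagement"]], nrow(co$visits))
})
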