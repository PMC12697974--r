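# cohort_simulator: synthetic geofences, motion-gated GNSS trajectories,
# ground-truth visit intervals, and per-prompt response behaviour. The
# generator's defaults are the study conditions the engine assumes (38
# participants, 14 days, two-minute motion-gated sampling, 30 m accuracy
# tail), so every other module is testable without any data download.

town_meta <- function(fences) {
  attr(fences, "town") %||% {
    bb <- do.call(rbind, fences$bbox)
    list(center_lon = mean(c(min(bb[, 1]), max(bb[, 3]))),
         center_lat = mean(c(min(bb[, 2]), max(bb[, 4]))))
  }
}

# metre offsets from town centre -> degrees
m_to_deg <- function(x_m, y_m, center_lon, center_lat) {
  list(lon = center_lon + x_m / (M_PER_DEG * cos(center_lat * pi / 180)),
       lat = center_lat + y_m / M_PER_DEG)
}

# radial (star-shaped, hence simple) polygon ring in metre offsets
radial_ring <- function(cx, cy, radii, rot = 0) {
  k <- length(radii)
  ang <- rot + seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  ring <- cbind(cx + radii * cos(ang), cy + radii * sin(ang))
  rbind(ring, ring[1, , drop = FALSE])
}

#' Generate a synthetic town of geofences
#'
#' Builds a square grid of land-use tiles (classes residential, commercial,
#' industrial, institutional; residential dominates) and `n_parks` park
#' polygons. With `complexity = "full"` the parks include at least one
#' convex, one concave, one holed (annulus) and one multi-part
#' (MultiPolygon) geometry, exercising the full containment predicate. Each
#' park carries `anchor_lon`/`anchor_lat`/`safe_radius_m` properties: a
#' point and radius guaranteed interior, which the trajectory simulator
#' strolls within.
#'
#' @param n_parks Number of parks (>= 1; `complexity = "full"` needs >= 4).
#' @param n_landuse Number of land-use tiles (default 49).
#' @param complexity "full" (default) or "simple" (convex parks only).
#' @param seed Integer seed; the same seed yields an identical fence set.
#' @param center_lon,center_lat Town centre (default a mid-latitude Ontario
#'   location).
#' @param path Optional path: when given, the FeatureCollection is also
#'   written there as GeoJSON.
#' @return A `gemaflow_fences` tibble with a `town` attribute.
#' @export
generate_geofences <- function(n_parks = 6, n_landuse = 49,
                               complexity = c("full", "simple"), seed = 1,
                               center_lon = -81.25, center_lat = 42.98,
                               path = NULL) {
  complexity <- match.arg(complexity)
  stopifnot(n_parks >= 1, n_landuse >= 1)
  if (complexity == "full" && n_parks < 4) {
    rlang::abort("complexity = 'full' needs n_parks >= 4",
                 class = "gemaflow_config_error")
  }
  tile_m <- 600
  g <- ceiling(sqrt(n_landuse))
  half <- g * tile_m / 2
  conv <- function(ring_m) {
    d <- m_to_deg(ring_m[, 1], ring_m[, 2], center_lon, center_lat)
    cbind(d$lon, d$lat)
  }
  with_seed(derive_seed("fences", seed), {
    # land-use tiles, row-major from the south-west corner
    classes <- c("residential", "commercial", "industrial", "institutional")
    tile_class <- sample(classes, n_landuse, replace = TRUE,
                         prob = c(0.6, 0.2, 0.1, 0.1))
    tile_class[1] <- "residential"
    ids <- character(0); geoms <- list(); cls <- character(0); attrs <- list()
    for (i in seq_len(n_landuse)) {
      row <- (i - 1) %/% g; col <- (i - 1) %% g
      x0 <- -half + col * tile_m; y0 <- -half + row * tile_m
      ring <- rbind(c(x0, y0), c(x0 + tile_m, y0),
                    c(x0 + tile_m, y0 + tile_m), c(x0, y0 + tile_m),
                    c(x0, y0))
      ids <- c(ids, sprintf("zone_%03d", i))
      cls <- c(cls, tile_class[i])
      geoms[[length(geoms) + 1L]] <- list(list(conv(ring)))
      attrs[[length(attrs) + 1L]] <- list()
    }
    # parks: centres on a jittered sub-grid, separated enough not to overlap
    max_r <- 240
    pk_pos <- list()
    tries <- 0
    while (length(pk_pos) < n_parks && tries < 2000) {
      tries <- tries + 1
      cand <- stats::runif(2, -half + max_r + 60, half - max_r - 60)
      ok <- all(vapply(pk_pos, function(p)
        sqrt(sum((p - cand)^2)) > 2 * max_r + 120, logical(1)))
      if (ok) pk_pos[[length(pk_pos) + 1L]] <- cand
    }
    if (length(pk_pos) < n_parks) {
      rlang::abort("could not place parks without overlap; reduce n_parks",
                   class = "gemaflow_config_error")
    }
    shapes <- if (complexity == "full") {
      c("convex", "concave", "holed", "multipart",
        sample(c("convex", "concave"), max(0, n_parks - 4), replace = TRUE))
    } else rep("convex", n_parks)
    for (i in seq_len(n_parks)) {
      cx <- pk_pos[[i]][1]; cy <- pk_pos[[i]][2]
      rot <- stats::runif(1, 0, 2 * pi)
      shape <- shapes[i]
      if (shape == "convex") {
        radii <- stats::runif(14, 140, 200)
        parts <- list(list(radial_ring(cx, cy, radii, rot)))
        anchor <- c(cx, cy); safe_r <- 0.55 * min(radii)
      } else if (shape == "concave") {
        radii <- rep(c(220, 90), 9) * stats::runif(18, 0.9, 1.1)
        parts <- list(list(radial_ring(cx, cy, radii, rot)))
        anchor <- c(cx, cy); safe_r <- 0.5 * min(radii)
      } else if (shape == "holed") {
        outer <- stats::runif(16, 190, 240)
        hole_r <- 70
        parts <- list(list(radial_ring(cx, cy, outer, rot),
                           radial_ring(cx, cy, rep(hole_r, 12), rot)))
        mid <- (min(outer) + hole_r) / 2
        anchor <- c(cx + mid, cy)
        safe_r <- 0.45 * (min(outer) - hole_r) / 2 +
          0.0 # margin to both the hole and the outer ring
      } else { # multipart: two disjoint lobes
        r1 <- stats::runif(10, 90, 120); r2 <- stats::runif(10, 80, 110)
        off <- 170
        parts <- list(list(radial_ring(cx - off, cy, r1, rot)),
                      list(radial_ring(cx + off, cy, r2, rot)))
        anchor <- c(cx - off, cy); safe_r <- 0.55 * min(r1)
      }
      a <- m_to_deg(anchor[1], anchor[2], center_lon, center_lat)
      ids <- c(ids, sprintf("park_%02d", i))
      cls <- c(cls, "park")
      geoms[[length(geoms) + 1L]] <- lapply(parts, function(p) lapply(p, conv))
      attrs[[length(attrs) + 1L]] <- list(anchor_lon = a$lon,
                                          anchor_lat = a$lat,
                                          safe_radius_m = safe_r,
                                          shape = shape)
    }
    fences <- geofences(ids, geoms, cls, attrs)
    attr(fences, "town") <- list(center_lon = center_lon,
                                 center_lat = center_lat, half_m = half)
    if (!is.null(path)) write_geofences(fences, path)
    fences
  })
}

#' Behaviour profile of a simulated participant
#'
#' Encodes the behavioural structure the analytics must be able to recover:
#' park visit frequency, dwell-time distribution, per-prompt-kind response
#' propensities and latency medians, video attachment propensity, and the
#' motion parameters that interact with the device's motion-gated sampling.
#'
#' @param park_visits_per_day Poisson rate of park trips per day
#'   (default 0.9).
#' @param dwell_meanlog,dwell_sdlog Lognormal parameters of park dwell time
#'   in minutes (defaults `log(5)` and 1.4, putting ~31% of visits past the
#'   10-minute engagement threshold and ~6% past 45 minutes).
#' @param response_probability Named probabilities of answering, by rule id.
#' @param latency_median_min Named median response latencies in minutes, by
#'   rule id.
#' @param latency_sdlog Lognormal sdlog of latency (default 0.9).
#' @param attachment_probability Probability an answered engagement prompt
#'   includes a video (default 0.23).
#' @param p_morning_active,p_evening_active Probability the participant
#'   moves (and therefore transmits a fix) during the morning / evening
#'   window on a given day (default 0.7 each).
#' @param walk_speed_mps,vehicle_speed_mps Travel speeds (1.3 / 8 m/s).
#' @param motionless_threshold_mps Speed below which the simulated device
#'   counts as motionless (default 0.1 m/s; a simulator assumption — the
#'   engine itself never needs one).
#' @return A list of class `gemaflow_profile`.
#' @export
behavior_profile <- function(
    park_visits_per_day = 0.9,
    dwell_meanlog = log(5), dwell_sdlog = 1.4,
    response_probability = c(morning = 0.61, evening = 0.68,
                             engagement = 0.47, followup = 0.50,
                             exit = 0.44),
    latency_median_min = c(morning = 3, evening = 4, engagement = 2,
                           followup = 9, exit = 4),
    latency_sdlog = 0.9,
    attachment_probability = 0.23,
    p_morning_active = 0.7, p_evening_active = 0.7,
    walk_speed_mps = 1.3, vehicle_speed_mps = 8,
    motionless_threshold_mps = 0.1) {
  stopifnot(park_visits_per_day >= 0,
            all(response_probability >= 0 & response_probability <= 1),
            attachment_probability >= 0, attachment_probability <= 1)
  structure(as.list(environment()), class = "gemaflow_profile")
}

#' Simulation configuration
#'
#' @param n_participants Cohort size (default 38, the compliant ParkSeek
#'   cohort).
#' @param study_days Study length in days (default 14).
#' @param start_date Local date ("YYYY-MM-DD") of the first study day.
#' @param timezone IANA timezone of the cohort.
#' @param sampling A [sampling_policy()].
#' @param gnss_noise_m Rayleigh scale of positional error in metres
#'   (default 5).
#' @param accuracy_meanlog,accuracy_sdlog Lognormal parameters of the
#'   reported radial accuracy in metres (defaults `log(8)` and 0.7, putting
#'   ~3% of fixes past the 30 m filter).
#' @param seed Integer master seed.
#' @return A list of class `gemaflow_simconfig`.
#' @export
sim_config <- function(n_participants = 38, study_days = 14,
                       start_date = "2023-08-14",
                       timezone = "America/Toronto",
                       sampling = sampling_policy(),
                       gnss_noise_m = 5,
                       accuracy_meanlog = log(8), accuracy_sdlog = 0.7,
                       seed = 1) {
  stopifnot(n_participants >= 0, study_days >= 1)
  check_timezone(timezone)
  structure(as.list(environment()), class = "gemaflow_simconfig")
}

# first s in (0, 1] at which segment A->B crosses any ring of `parts`
# (degree coordinates); numeric(0) when no crossing.
segment_crossings <- function(parts, ax, ay, bx, by) {
  ss <- numeric(0)
  for (part in parts) {
    for (ring in part) {
      m <- nrow(ring) - 1L
      x1 <- ring[1:m, 1]; y1 <- ring[1:m, 2]
      x2 <- ring[2:(m + 1), 1]; y2 <- ring[2:(m + 1), 2]
      dx <- bx - ax; dy <- by - ay
      ex <- x2 - x1; ey <- y2 - y1
      den <- dx * ey - dy * ex
      ok <- den != 0
      s <- ((x1 - ax) * ey - (y1 - ay) * ex) / den
      u <- ((x1 - ax) * dy - (y1 - ay) * dx) / den
      hit <- ok & s > 0 & s <= 1 & u >= 0 & u < 1
      ss <- c(ss, s[hit])
    }
  }
  sort(ss)
}

#' Emit motion-gated fixes from a continuous track
#'
#' Replays the device sampling policy over a dense trajectory: a fix every
#' `interval_s` seconds while the device moves at or above the motionless
#' threshold, continuing for `pause_after_motionless_s` seconds into a
#' still period, then silence until motion resumes.
#'
#' @param track Tibble with columns `t` (epoch seconds, sorted), `lat`,
#'   `lon`; positions between points are interpolated linearly.
#' @param sampling A [sampling_policy()].
#' @param motionless_threshold_mps Stillness speed threshold (m/s).
#' @return A tibble `t`, `lat`, `lon` of emitted (noise-free) fixes.
#' @export
motion_gated_fixes <- function(track, sampling = sampling_policy(),
                               motionless_threshold_mps = 0.1) {
  stopifnot(nrow(track) >= 1)
  track <- track[!duplicated(track$t), , drop = FALSE]
  if (nrow(track) == 1) {
    return(tibble::tibble(t = track$t, lat = track$lat, lon = track$lon))
  }
  tt <- track$t
  seg_d <- haversine_m(track$lat[-nrow(track)], track$lon[-nrow(track)],
                       track$lat[-1], track$lon[-1])
  seg_dt <- diff(tt)
  moving <- seg_d / pmax(seg_dt, 1e-9) >= motionless_threshold_mps
  # the grid runs one pause-length past the end of the track, so stillness
  # at the end of the day is sampled the same way as stillness mid-day
  cand <- seq(tt[1], tt[length(tt)] + sampling$pause_after_motionless_s,
              by = sampling$interval_s)
  seg <- pmin(pmax(findInterval(cand, tt), 1L), length(moving))
  in_motion <- moving[seg] & cand < tt[length(tt)]
  # end time of the most recent moving segment at or before each candidate
  move_end <- ifelse(moving, tt[-1], -Inf)
  last_move_end <- pmin(cummax(c(-Inf, move_end))[seg], cand)
  # a device that was never yet in motion has not started transmitting
  emit <- in_motion |
    (is.finite(last_move_end) &
       (cand - last_move_end) <= sampling$pause_after_motionless_s)
  cand <- cand[emit]
  tibble::tibble(
    t = cand,
    lat = stats::approx(tt, track$lat, xout = cand, rule = 2)$y,
    lon = stats::approx(tt, track$lon, xout = cand, rule = 2)$y)
}

# Build one participant's dense track plus ground-truth visit intervals.
# All positions in degrees; times epoch seconds. Returns list(track, truth).
simulate_participant_track <- function(pid, home, parks, cfg, profile, tz) {
  day0 <- as.Date(cfg$start_date)
  pts_t <- numeric(0); pts_lat <- numeric(0); pts_lon <- numeric(0)
  truth <- list()
  lat_scale <- M_PER_DEG
  lon_scale <- M_PER_DEG * cos(home$lat * pi / 180)
  add <- function(t, lat, lon) {
    pts_t <<- c(pts_t, t); pts_lat <<- c(pts_lat, lat)
    pts_lon <<- c(pts_lon, lon)
  }
  putter <- function(t0, dur, clat, clon) {
    k <- ceiling(dur / 60)
    ang <- cumsum(stats::runif(k, 0.5, 1.5))
    r <- 30
    add(t0 + 60 * (seq_len(k) - 1),
        clat + r * sin(ang) / lat_scale,
        clon + r * cos(ang) / lon_scale)
  }
  line <- function(t0, t1, lat0, lon0, lat1, lon1) {
    k <- max(2, ceiling((t1 - t0) / 60))
    s <- seq(0, 1, length.out = k)
    add(t0 + s * (t1 - t0), lat0 + s * (lat1 - lat0),
        lon0 + s * (lon1 - lon0))
  }
  stroll <- function(t0, dur, clat, clon, safe_r) {
    k <- max(2, ceiling(dur / 60))
    ang <- cumsum(stats::runif(k, 0.4, 1.2))
    rho <- 0.7 * safe_r
    add(t0 + seq(0, dur, length.out = k),
        clat + rho * sin(ang) / lat_scale,
        clon + rho * cos(ang) / lon_scale)
  }
  for (d in seq_len(cfg$study_days)) {
    date <- as.character(day0 + (d - 1))
    sod0 <- local_epoch(date, 0, tz)
    # morning putter around home
    if (stats::runif(1) < profile$p_morning_active) {
      t0 <- sod0 + stats::runif(1, 31200, 35400) # 08:40-09:50
      putter(t0, 900, home$lat, home$lon)
    }
    # park trips between 10:30 and 18:30
    n_trips <- min(stats::rpois(1, profile$park_visits_per_day), 3L)
    cursor <- sod0 + 37800
    for (trip in seq_len(n_trips)) {
      park <- parks[sample.int(nrow(parks), 1), ]
      att <- park$attributes[[1]]
      dist <- haversine_m(home$lat, home$lon, att$anchor_lat, att$anchor_lon)
      speed <- if (dist < 1500) profile$walk_speed_mps else profile$vehicle_speed_mps
      travel <- dist / speed
      dwell <- 60 * min(max(stats::rlnorm(1, profile$dwell_meanlog,
                                          profile$dwell_sdlog), 1), 240)
      depart <- cursor + stats::runif(1, 0, 3600)
      arrive <- depart + travel
      leave <- arrive + dwell
      back <- leave + travel
      if (back > sod0 + 66600) break
      line(depart, arrive, home$lat, home$lon, att$anchor_lat, att$anchor_lon)
      stroll(arrive, dwell, att$anchor_lat, att$anchor_lon, att$safe_radius_m)
      line(leave, back, att$anchor_lat, att$anchor_lon, home$lat, home$lon)
      # ground truth: boundary crossings along the straight approach/return
      s_in <- segment_crossings(park$geometry[[1]], home$lon, home$lat,
                                att$anchor_lon, att$anchor_lat)
      s_out <- segment_crossings(park$geometry[[1]], att$anchor_lon,
                                 att$anchor_lat, home$lon, home$lat)
      entry_true <- depart + (if (length(s_in)) min(s_in) else 1) * travel
      exit_true <- leave + (if (length(s_out)) min(s_out) else 0) * travel
      truth[[length(truth) + 1L]] <- tibble::tibble(
        participant_id = pid, geofence_id = park$geofence_id,
        entry_t = entry_true, exit_t = exit_true)
      cursor <- back + 900
    }
    # evening putter
    if (stats::runif(1) < profile$p_evening_active) {
      t0 <- sod0 + stats::runif(1, 67800, 71400) # 18:50-19:50
      putter(t0, 900, home$lat, home$lon)
    }
  }
  ord <- order(pts_t)
  track <- tibble::tibble(t = pts_t[ord], lat = pts_lat[ord],
                          lon = pts_lon[ord])
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(participant_id = character(), geofence_id = character(),
                   entry_t = numeric(), exit_t = numeric())
  list(track = track, truth = truth)
}

#' Simulate a study cohort end-to-end
#'
#' Generates per-participant trajectories over the study period (home
#' putter episodes in the morning and evening windows, Poisson park trips
#' with lognormal dwell), replays the motion-gated sampling policy, adds
#' Rayleigh GNSS noise and a reported-accuracy distribution with a tail
#' beyond the filter threshold, then runs the engine (filter, visit
#' detection, prompt scheduling) and draws responses per prompt from the
#' behaviour profile. Ground-truth visit intervals are recorded from the
#' continuous trajectory, independent of what the engine detects.
#'
#' @param cfg A [sim_config()].
#' @param profile A [behavior_profile()].
#' @param fences A `gemaflow_fences` tibble (see [generate_geofences()]).
#' @param protocol A `gemaflow_protocol` (default [parkseek_protocol()]).
#' @param detect_classes Fence classes passed to visit detection (default
#'   "park"; pass NULL for all classes — needed for time-use analytics).
#' @return A list of class `gemaflow_cohort`: `fixes` (raw), `filtered`,
#'   `truth_visits`, `visits`, `events`, `prompts`, `responses`, plus the
#'   inputs (`fences`, `protocol`, `cfg`, `profile`).
#' @export
simulate_cohort <- function(cfg, profile, fences,
                            protocol = parkseek_protocol(),
                            detect_classes = "park") {
  stopifnot(inherits(cfg, "gemaflow_simconfig"),
            inherits(profile, "gemaflow_profile"),
            inherits(fences, "gemaflow_fences"),
            inherits(protocol, "gemaflow_protocol"))
  tz <- protocol$timezone
  parks <- fences[fences$class == "park", ]
  res <- fences[fences$class == "residential", ]
  if (!nrow(parks) || !nrow(res)) {
    rlang::abort("fences must include at least one park and one residential zone",
                 class = "gemaflow_config_error")
  }
  fix_list <- list(); truth_list <- list()
  with_seed(derive_seed("cohort", cfg$seed), {
    for (p in seq_len(cfg$n_participants)) {
      pid <- sprintf("p%03d", p)
      tile <- res[sample.int(nrow(res), 1), ]
      bb <- tile$bbox[[1]]
      home <- list(lat = stats::runif(1, bb[2] + (bb[4] - bb[2]) * 0.2,
                                      bb[4] - (bb[4] - bb[2]) * 0.2),
                   lon = stats::runif(1, bb[1] + (bb[3] - bb[1]) * 0.2,
                                      bb[3] - (bb[3] - bb[1]) * 0.2))
      sim <- simulate_participant_track(pid, home, parks, cfg, profile, tz)
      if (!nrow(sim$track)) next
      gated <- motion_gated_fixes(sim$track, cfg$sampling,
                                  profile$motionless_threshold_mps)
      n <- nrow(gated)
      if (!n) next
      # Rayleigh positional noise + independently reported accuracy
      r <- cfg$gnss_noise_m * sqrt(-2 * log(stats::runif(n)))
      ang <- stats::runif(n, 0, 2 * pi)
      lat_scale <- M_PER_DEG
      lon_scale <- M_PER_DEG * cos(gated$lat * pi / 180)
      fix_list[[p]] <- tibble::tibble(
        participant_id = pid,
        lat = gated$lat + r * sin(ang) / lat_scale,
        lon = gated$lon + r * cos(ang) / lon_scale,
        t = round(gated$t),
        accuracy_m = stats::rlnorm(n, cfg$accuracy_meanlog,
                                   cfg$accuracy_sdlog))
      truth_list[[p]] <- sim$truth
    }
    fixes <- dplyr::bind_rows(fix_list)
    if (!nrow(fixes)) {
      fixes <- gnss_fixes(character(), numeric(), numeric(), numeric(),
                          numeric())
    }
    fixes <- dplyr::distinct(fixes, .data$participant_id, .data$t,
                             .keep_all = TRUE)
    truth <- dplyr::bind_rows(truth_list)
    filtered <- filter_accuracy(fixes, protocol$max_radial_m)
    det_fences <- if (is.null(detect_classes)) fences else
      fences[fences$class %in% detect_classes, ]
    class(det_fences) <- class(fences)
    thr <- protocol_thresholds(protocol)
    det <- detect_visits(filtered, det_fences, protocol$max_gap_s,
                         thr$dwell_s, thr$followup_s)
    prompts <- schedule_prompts(filtered, det$events, protocol, fences)
    resp <- simulate_responses(prompts, profile, protocol)
    structure(list(fixes = fixes, filtered = filtered, truth_visits = truth,
                   visits = det$visits, events = det$events,
                   prompts = resp$prompts, responses = resp$responses,
                   fences = fences, protocol = protocol, cfg = cfg,
                   profile = profile),
              class = "gemaflow_cohort")
  })
}

#' Draw simulated responses to a prompt log
#'
#' Each prompt is answered with the profile's per-rule probability; latency
#' is lognormal about the configured median, truncated at the prompt's
#' expiry (inverse-CDF draw, so the configured probability is exactly the
#' propensity to answer before expiry). Answered engagement prompts attach
#' a video with the profile's attachment probability. Submissions are then
#' replayed through [process_submissions()] and remaining prompts expired.
#'
#' @param prompts A prompt tibble from [schedule_prompts()].
#' @param profile A [behavior_profile()]; `response_probability` and
#'   `latency_median_min` must name every rule_id present.
#' @param protocol The protocol (for survey item simulation).
#' @return A list: `prompts` (with final statuses) and `responses`.
#' @export
simulate_responses <- function(prompts, profile, protocol) {
  n <- nrow(prompts)
  if (!n) {
    pr <- process_submissions(prompts, tibble::tibble(prompt_id = character(),
                                                      submit_t = numeric()))
    return(list(prompts = pr$prompts, responses = pr$responses))
  }
  pvec <- profile$response_probability[prompts$rule_id]
  med <- profile$latency_median_min[prompts$rule_id]
  if (anyNA(pvec) || anyNA(med)) {
    rlang::abort("profile must configure response_probability and latency_median_min for every rule_id",
                 class = "gemaflow_config_error")
  }
  answered <- stats::runif(n) < pvec
  # truncated lognormal latency via inverse CDF
  expiry_min <- (prompts$expiry_t - prompts$delivery_t) / 60
  pmax_u <- stats::plnorm(expiry_min, log(med), profile$latency_sdlog)
  u <- stats::runif(n) * pmax_u
  lat_min <- stats::qlnorm(pmin(u, 1 - 1e-12), log(med), profile$latency_sdlog)
  submit_t <- prompts$delivery_t + pmin(round(lat_min * 60),
                                        prompts$expiry_t - prompts$delivery_t)
  items <- lapply(seq_len(n), function(i) {
    who5 <- sample(0:5, 5, replace = TRUE)
    if (prompts$survey_ref[i] == "WHO5_PROMIS") {
      c(who5, sample(1:5, 8, replace = TRUE))
    } else who5
  })
  attach_n <- ifelse(prompts$kind == "DWELL" & answered,
                     stats::rbinom(n, 1, profile$attachment_probability), 0L)
  subs <- tibble::tibble(prompt_id = prompts$prompt_id,
                         submit_t = submit_t, items = items,
                         attachments = as.integer(attach_n))[answered, ]
  pr <- process_submissions(prompts, subs)
  pr$prompts <- finalize_prompts(pr$prompts)
  list(prompts = pr$prompts, responses = pr$responses)
}

#' ParkSeek-replica presets
#'
#' Simulator inputs mirroring the published field study's design: 38
#' participants for 14 days, five prompt rules (morning and evening windows,
#' a 10-minute park engagement prompt, a 45-minute follow-up, a park exit
#' prompt, all with one-hour expiry), response probabilities
#' (0.61, 0.68, 0.47, 0.50, 0.44) and median latencies (3, 4, 2, 9, 4)
#' minutes by rule. These are explicitly inputs to the simulator, not
#' reproductions of the field results.
#'
#' @param seed Integer seed (for [parkseek_sim_config()]).
#' @return [parkseek_protocol()] returns a `gemaflow_protocol`;
#'   [parkseek_profile()] a `gemaflow_profile`; [parkseek_sim_config()] a
#'   `gemaflow_simconfig`.
#' @export
parkseek_protocol <- function() {
  protocol(
    list(
      rule_time_window("morning", "09:00", "10:00", survey_ref = "WHO5_PROMIS"),
      rule_time_window("evening", "19:00", "20:00", survey_ref = "WHO5"),
      rule_dwell("engagement", 600, "park", survey_ref = "WHO5_VIDEO"),
      rule_followup_dwell("followup", 2700, "park", survey_ref = "WHO5_VIDEO"),
      rule_exit("exit", "park", survey_ref = "WHO5")),
    timezone = "America/Toronto",
    surveys = c("WHO5", "WHO5_PROMIS", "WHO5_VIDEO"))
}

#' @rdname parkseek_protocol
#' @export
parkseek_profile <- function() behavior_profile()

#' @rdname parkseek_protocol
#' @export
parkseek_sim_config <- function(seed = 1) sim_config(seed = seed)
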