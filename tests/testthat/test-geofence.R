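# geofence engine: containment predicate and visit state machine

square <- function(x0, y0, side = 1) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side), c(x0, y0))
}

test_that("containment is even-odd with an inclusive boundary", {
  f <- geofences("sq", list(list(list(square(0, 0)))), class = "park")
  expect_true(fence_contains(f, lat = 0.5, lon = 0.5)[1, 1])   # centroid
  expect_true(fence_contains(f, lat = 0.5, lon = 0)[1, 1])     # on an edge
  expect_true(fence_contains(f, lat = 1, lon = 1)[1, 1])       # on a vertex
  expect_false(fence_contains(f, lat = 0.5, lon = 1.5)[1, 1])  # outside
})

test_that("holes are excluded and multipolygons union their parts", {
  ann_out <- square(0, 0, 3)
  ann_hole <- square(1, 1, 1)
  ann <- geofences("annulus", list(list(list(ann_out, ann_hole))),
                   class = "park")
  expect_false(fence_contains(ann, lat = 1.5, lon = 1.5)[1, 1]) # in the hole
  expect_true(fence_contains(ann, lat = 0.5, lon = 0.5)[1, 1])  # in the band
  expect_true(fence_contains(ann, lat = 1, lon = 1)[1, 1])      # hole edge

  mp <- geofences("two_lobes",
                  list(list(list(square(0, 0)), list(square(5, 5)))),
                  class = "park")
  expect_true(fence_contains(mp, lat = 0.5, lon = 0.5)[1, 1])
  expect_true(fence_contains(mp, lat = 5.5, lon = 5.5)[1, 1])
  expect_false(fence_contains(mp, lat = 3, lon = 3)[1, 1])
})

test_that("invalid rings are rejected at load time", {
  open_ring <- square(0, 0)[1:4, ]                   # not closed
  expect_error(geofences("bad", list(list(list(open_ring)))),
               class = "gemaflow_geometry_error")
  tri <- rbind(c(0, 0), c(1, 0), c(0, 0))            # < 4 vertices
  expect_error(geofences("bad", list(list(list(tri)))),
               class = "gemaflow_geometry_error")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  expect_error(geofences("bad", list(list(list(bowtie)))),
               class = "gemaflow_geometry_error")
  expect_error(geofences(c("a", "a"),
                         list(list(list(square(0, 0))),
                              list(list(square(2, 2))))),
               class = "gemaflow_geometry_error")
})

test_that("geofences round-trip through GeoJSON", {
  f <- geofences(c("a", "b"),
                 list(list(list(square(0, 0, 2), square(0.5, 0.5, 0.5))),
                      list(list(square(4, 4)), list(square(7, 7)))),
                 class = c("park", "residential"),
                 attributes = list(list(name = "central"), list()))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geofences(f, path)
  g <- read_geofences(path)
  expect_equal(g$geofence_id, f$geofence_id)
  expect_equal(g$class, f$class)
  expect_equal(g$geometry, f$geometry)
  expect_equal(g$attributes[[1]]$name, "central")
  # and the written file is standard enough for shapely to parse (oracle)
  expect_silent(oracle_contains(f, lat = c(1, 5), lon = c(1, 5)))
})

test_that("containment agrees with the shapely oracle on random complex polygons", {
  # small in-suite version; the full 100 x 10^4 sweep is an acceptance test
  set.seed(202)
  kinds <- rep(c("concave", "holed", "multipart"), each = 4)
  geoms <- lapply(kinds, random_test_polygon)
  fences <- geofences(sprintf("poly_%02d", seq_along(geoms)), geoms)
  pts <- lapply(seq_along(geoms), function(j) {
    bb <- fences$bbox[[j]]
    pad <- c(diff(bb[c(1, 3)]), diff(bb[c(2, 4)])) * 0.1
    data.frame(g = j,
               lon = runif(800, bb[1] - pad[1], bb[3] + pad[1]),
               lat = runif(800, bb[2] - pad[2], bb[4] + pad[2]))
  })
  pts <- do.call(rbind, pts)
  mine <- fence_contains(fences, pts$lat, pts$lon)
  mine_own <- mine[cbind(seq_len(nrow(pts)), pts$g)]
  oracle <- oracle_contains(fences, pts$lat, pts$lon, groups = pts$g)
  agree <- mine_own == oracle
  expect_gte(mean(agree), 0.999)
  # any disagreement sits essentially on a boundary
  for (i in which(!agree)) {
    expect_lt(boundary_dist(fences$geometry[[pts$g[i]]],
                            pts$lon[i], pts$lat[i]), 1e-6)
  }
})

park_fence <- function() {
  geofences("park_1", list(list(list(square(0, 0, 0.01)))), class = "park")
}

in_fix <- function(t, pid = "p1") {
  gnss_fixes(pid, lat = 0.005, lon = 0.005, t = t, accuracy_m = 5)
}
out_fix <- function(t, pid = "p1") {
  gnss_fixes(pid, lat = 0.05, lon = 0.05, t = t, accuracy_m = 5)
}

test_that("a 12-minute stay yields one visit with ENTRY at 0 and DWELL at 10 min", {
  f <- in_fix(seq(0, 12 * 60, by = 120))
  det <- detect_visits(f, park_fence())
  expect_equal(nrow(det$visits), 1)
  expect_equal(det$visits$entry_t, 0)
  expect_true(is.na(det$visits$exit_t))    # stream ended inside: open visit
  ev <- det$events
  expect_equal(ev$kind, c("ENTRY", "DWELL"))
  expect_equal(ev$t[ev$kind == "DWELL"], 600)
})

test_that("leaving before 10 minutes yields EXIT at the first outside fix, no DWELL", {
  f <- dplyr::bind_rows(in_fix(seq(0, 8 * 60, by = 120)),
                        out_fix(10 * 60))
  det <- detect_visits(f, park_fence())
  expect_equal(nrow(det$visits), 1)
  expect_equal(det$visits$exit_t, 600)
  expect_setequal(det$events$kind, c("ENTRY", "EXIT"))
})

test_that("a silent in-fence gap within max_gap_s is continuous presence", {
  # inside at t=0, 30 min of silence (device motionless), inside at t=30min
  f <- in_fix(c(0, 30 * 60))
  det <- detect_visits(f, park_fence(), max_gap_s = 12 * 3600)
  expect_equal(nrow(det$visits), 1)
  # DWELL fires at the first fix with elapsed >= 10 min: the t=30min fix
  expect_equal(det$events$t[det$events$kind == "DWELL"], 1800)
  # but a gap beyond max_gap_s splits the stay and closes at the last fix
  det2 <- detect_visits(f, park_fence(), max_gap_s = 600)
  expect_equal(nrow(det2$visits), 2)
  expect_equal(det2$visits$exit_t[1], 0)
  expect_false("DWELL" %in% det2$events$kind)
})

test_that("an outside fix arriving past max_gap_s closes the visit at the last inside fix", {
  f <- dplyr::bind_rows(in_fix(c(0, 120)), out_fix(120 + 20 * 3600))
  det <- detect_visits(f, park_fence(), max_gap_s = 12 * 3600)
  expect_equal(det$visits$exit_t, 120)
})

test_that("visit detection matches the interval-scan oracle on random streams", {
  set.seed(303)
  fences <- geofences(
    c("a", "b"),
    list(random_test_polygon("concave", cx = 0, cy = 0),
         random_test_polygon("holed", cx = 0.03, cy = 0.01)))
  for (rep in 1:20) {
    f <- random_stream(sample(30:120, 1), fences)
    det <- detect_visits(f, fences, max_gap_s = 3600)
    ora <- oracle_detect_visits(f, fences, max_gap_s = 3600)
    expect_equal(as.data.frame(det$visits[, names(ora$visits)]),
                 as.data.frame(ora$visits), ignore_attr = TRUE)
    expect_equal(as.data.frame(det$events[, names(ora$events)]),
                 as.data.frame(ora$events), ignore_attr = TRUE)
  }
})

test_that("visit invariants hold: non-overlap, fix conservation, event ordering", {
  set.seed(404)
  fences <- geofences(
    c("a", "b"),
    list(random_test_polygon("concave", cx = 0, cy = 0),
         random_test_polygon("multipart", cx = 0.04, cy = 0)))
  for (rep in 1:8) {
    f <- random_stream(150, fences, n_participants = 3)
    det <- detect_visits(f, fences, max_gap_s = 7200)
    # visits non-overlapping in time per (participant, fence)
    v <- dplyr::arrange(close_visits(det$visits, max(f$t)),
                        participant_id, geofence_id, entry_t)
    by_pf <- split(v, paste(v$participant_id, v$geofence_id))
    for (g in by_pf) {
      if (nrow(g) > 1) {
        expect_true(all(g$entry_t[-1] >= g$exit_t[-nrow(g)]))
      }
    }
    # inside-fix conservation: total fix_count equals inside-flag count
    inside <- fence_contains(fences, f$lat, f$lon)
    expect_equal(sum(det$visits$fix_count), sum(inside))
    # event ordering within each visit
    ev <- split(det$events, det$events$visit_id)
    rank <- c(ENTRY = 1, DWELL = 2, FOLLOWUP_DWELL = 3, EXIT = 4)
    for (e in ev) {
      e <- e[order(rank[e$kind]), ]
      expect_true(!is.unsorted(e$t))
      expect_equal(e$kind[1], "ENTRY")
    }
  }
})

test_that("time accounting sums closed visits and flags undefined shares", {
  fences <- geofences(
    c("p", "shop", "home"),
    list(list(list(square(0, 0))), list(list(square(2, 0))),
         list(list(square(4, 0)))),
    class = c("park", "commercial", "residential"))
  visits <- tibble::tibble(
    visit_id = as.character(1:4), participant_id = c("a", "a", "a", "b"),
    geofence_id = c("p", "shop", "home", "shop"),
    entry_t = c(0, 5000, 20000, 0),
    exit_t = c(3600, 8600, 100000, 7200), fix_count = 1L)
  tic <- time_in_class(visits, fences)
  expect_equal(tic$seconds[tic$participant_id == "a" & tic$class == "park"],
               3600)
  sh <- time_share(visits, fences)
  expect_equal(sh$share[sh$participant_id == "a"], 0.5)  # 60 of 120 min
  expect_true(is.na(sh$share[sh$participant_id == "b"]) ||
                sh$share[sh$participant_id == "b"] == 0)
  # 10 + 20 min in parks of 120 min total non-residential -> 25%
  visits2 <- tibble::tibble(
    visit_id = as.character(1:3), participant_id = "c",
    geofence_id = c("p", "p", "shop"),
    entry_t = c(0, 2000, 10000), exit_t = c(600, 3200, 10000 + 90 * 60),
    fix_count = 1L)
  expect_equal(time_share(visits2, fences)$share, 0.25)
  # open visits must be closed first
  visits$exit_t[2] <- NA
  expect_error(time_in_class(visits, fences), class = "gemaflow_state_error")
  expect_silent(time_in_class(close_visits(visits, 2e5), fences))
})
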