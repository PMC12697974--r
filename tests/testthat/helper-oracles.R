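# Independent oracles used across the suite.
#
# Containment oracle: shapely (Python, pre-installed) `covers`, which, like
# the engine's stated convention, counts boundary points as inside. Called
# through one subprocess per test block, vectorised over points.
#
# Visit oracle: a deliberately naive per-fix interval-scan state machine,
# written against the stated semantics independently of the engine's
# run-based implementation.

# inside[i, j]: does polygon j cover point i? (one python call)
# When `groups` is given (one polygon index per point), each point is only
# evaluated against its own polygon and a single logical vector returns.
oracle_contains <- function(fences, lat, lon, groups = NULL) {
  gj <- tempfile(fileext = ".geojson")
  write_geofences(fences, gj)
  pts <- tempfile(fileext = ".csv")
  grp <- if (is.null(groups)) rep(0L, length(lat)) else as.integer(groups)
  utils::write.table(data.frame(g = grp, x = lon, y = lat), pts,
                     row.names = FALSE, col.names = FALSE, sep = ",")
  out <- tempfile(fileext = ".txt")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import numpy as np",
    "import shapely",
    "from shapely.geometry import shape",
    "gj = json.load(open(sys.argv[1]))",
    "geoms = [shape(f['geometry']) for f in gj['features']]",
    "dat = np.loadtxt(sys.argv[2], delimiter=',', ndmin=2)",
    "grp = dat[:, 0].astype(int); pts = shapely.points(dat[:, 1], dat[:, 2])",
    "grouped = sys.argv[4] == '1'",
    "with open(sys.argv[3], 'w') as fh:",
    "    if grouped:",
    "        res = np.zeros(len(pts), dtype=int)",
    "        for j, g in enumerate(geoms):",
    "            m = grp == (j + 1)",
    "            if m.any():",
    "                res[m] = shapely.covers(g, pts[m]).astype(int)",
    "        fh.write('\\n'.join(map(str, res)) + '\\n')",
    "    else:",
    "        cols = [shapely.covers(g, pts).astype(int) for g in geoms]",
    "        for row in np.column_stack(cols):",
    "            fh.write(','.join(map(str, row)) + '\\n')"
  ), script)
  status <- system2("python", c(script, gj, pts, out,
                                if (is.null(groups)) "0" else "1"))
  stopifnot(status == 0)
  if (is.null(groups)) {
    m <- as.matrix(utils::read.csv(out, header = FALSE))
    matrix(m == 1, nrow = length(lat),
           dimnames = list(NULL, fences$geofence_id))
  } else {
    as.integer(readLines(out)) == 1L
  }
}

# minimum distance (in coordinate units) from a point to any ring edge
boundary_dist <- function(parts, px, py) {
  best <- Inf
  for (part in parts) for (ring in part) {
    m <- nrow(ring) - 1L
    x1 <- ring[1:m, 1]; y1 <- ring[1:m, 2]
    x2 <- ring[2:(m + 1), 1]; y2 <- ring[2:(m + 1), 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    s <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / pmax(len2, 1e-300)))
    d2 <- (x1 + s * dx - px)^2 + (y1 + s * dy - py)^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# random radial test polygons (concave / holed / multi-part), ~0.02 deg scale
random_test_polygon <- function(kind = c("concave", "holed", "multipart"),
                                cx = runif(1, -170, 170),
                                cy = runif(1, -60, 60)) {
  kind <- match.arg(kind)
  ring <- function(cx, cy, radii, rot) {
    k <- length(radii)
    ang <- rot + seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
    r <- cbind(cx + radii * cos(ang), cy + radii * sin(ang))
    rbind(r, r[1, , drop = FALSE])
  }
  rot <- runif(1, 0, 2 * pi)
  if (kind == "concave") {
    k <- sample(7:15, 1)
    radii <- rep(c(0.02, 0.007), k) * runif(2 * k, 0.8, 1.2)
    list(list(ring(cx, cy, radii, rot)))
  } else if (kind == "holed") {
    outer <- runif(14, 0.016, 0.022)
    list(list(ring(cx, cy, outer, rot),
              ring(cx, cy, rep(0.006, 10), rot)))
  } else {
    off <- 0.018
    list(list(ring(cx - off, cy, runif(9, 0.007, 0.011), rot)),
         list(ring(cx + off, cy, runif(9, 0.006, 0.010), rot)))
  }
}

# Naive interval-scan visit oracle: explicit per-fix state machine for one
# fence at a time, applying the same stated semantics (gap rule, exit at
# first outside fix unless it arrives past the gap, dwell at fix
# granularity).
oracle_detect_visits <- function(fixes, fences, max_gap_s = 43200,
                                 dwell_s = 600, followup_s = 2700) {
  inside <- fence_contains(fences, fixes$lat, fixes$lon)
  visits <- list(); events <- list()
  for (pid in unique(fixes$participant_id)) {
    rows <- which(fixes$participant_id == pid)
    t <- fixes$t[rows]
    for (j in seq_len(ncol(inside))) {
      gid <- colnames(inside)[j]
      v <- inside[rows, j]
      st <- NULL
      close_visit <- function(st, exit_t, open) {
        visits[[length(visits) + 1L]] <<- data.frame(
          participant_id = pid, geofence_id = gid, entry_t = st$entry,
          exit_t = if (open) NA_real_ else exit_t, fix_count = st$n)
        if (!open) {
          events[[length(events) + 1L]] <<- data.frame(
            kind = "EXIT", participant_id = pid, geofence_id = gid,
            t = exit_t)
        }
      }
      for (i in seq_along(t)) {
        if (v[i]) {
          if (!is.null(st) && t[i] - st$last > max_gap_s) {
            close_visit(st, st$last, open = FALSE)
            st <- NULL
          }
          if (is.null(st)) {
            st <- list(entry = t[i], last = t[i], n = 0L,
                       dwell = FALSE, fup = FALSE)
            events[[length(events) + 1L]] <- data.frame(
              kind = "ENTRY", participant_id = pid, geofence_id = gid,
              t = t[i])
          }
          st$n <- st$n + 1L
          st$last <- t[i]
          if (!st$dwell && t[i] - st$entry >= dwell_s) {
            st$dwell <- TRUE
            events[[length(events) + 1L]] <- data.frame(
              kind = "DWELL", participant_id = pid, geofence_id = gid,
              t = t[i])
          }
          if (st$dwell && !st$fup && t[i] - st$entry >= followup_s) {
            st$fup <- TRUE
            events[[length(events) + 1L]] <- data.frame(
              kind = "FOLLOWUP_DWELL", participant_id = pid,
              geofence_id = gid, t = t[i])
          }
        } else if (!is.null(st)) {
          exit_t <- if (t[i] - st$last <= max_gap_s) t[i] else st$last
          close_visit(st, exit_t, open = FALSE)
          st <- NULL
        }
      }
      if (!is.null(st)) close_visit(st, NA, open = TRUE)
    }
  }
  visits <- if (length(visits)) dplyr::bind_rows(visits) else
    data.frame(participant_id = character(), geofence_id = character(),
               entry_t = numeric(), exit_t = numeric(),
               fix_count = integer())
  events <- if (length(events)) dplyr::bind_rows(events) else
    data.frame(kind = character(), participant_id = character(),
               geofence_id = character(), t = numeric())
  kind_rank <- c(ENTRY = 1, DWELL = 2, FOLLOWUP_DWELL = 3, EXIT = 4)
  list(
    visits = dplyr::arrange(visits, participant_id, entry_t, geofence_id),
    events = dplyr::arrange(events, participant_id, t, kind_rank[kind],
                            geofence_id))
}

# random fix streams bouncing around a small fence set, for oracle
# equivalence tests
random_stream <- function(n_fix, fences, n_participants = 2) {
  bb <- do.call(rbind, fences$bbox)
  xr <- c(min(bb[, 1]), max(bb[, 3])); yr <- c(min(bb[, 2]), max(bb[, 4]))
  pad_x <- diff(xr) * 0.3; pad_y <- diff(yr) * 0.3
  pid <- sort(sample(sprintf("p%02d", seq_len(n_participants)), n_fix,
                     replace = TRUE))
  steps <- sample(c(60, 120, 600, 20000, 50000), n_fix, replace = TRUE,
                  prob = c(0.3, 0.4, 0.2, 0.07, 0.03))
  t <- unlist(lapply(split(steps, pid), cumsum), use.names = FALSE)
  gnss_fixes(pid,
             lat = runif(n_fix, yr[1] - pad_y, yr[2] + pad_y),
             lon = runif(n_fix, xr[1] - pad_x, xr[2] + pad_x),
             t = t, accuracy_m = runif(n_fix, 2, 25))
}
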