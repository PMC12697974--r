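# geofence_engine: complex-polygon containment (even-odd, boundary
# inclusive) and the state machine turning a sparse motion-gated fix stream
# into geofence entry / dwell / exit events.

# Internal geometry representation: a fence's `geometry` list-column element
# is a list of *parts* (one per polygon of a MultiPolygon); each part is a
# list of rings; each ring is an n x 2 matrix of [lon, lat] with first row
# == last row. Ring 1 of a part is the exterior, further rings are holes.

validate_ring <- function(ring, where) {
  if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 4) {
    rlang::abort(sprintf("geometry error in %s: ring must be a closed matrix with >= 4 vertices", where),
                 class = "gemaflow_geometry_error")
  }
  if (any(ring[1, ] != ring[nrow(ring), ])) {
    rlang::abort(sprintf("geometry error in %s: ring is not closed (first vertex != last)", where),
                 class = "gemaflow_geometry_error")
  }
  if (!all(is.finite(ring))) {
    rlang::abort(sprintf("geometry error in %s: non-finite vertex", where),
                 class = "gemaflow_geometry_error")
  }
  if (ring_self_intersects(ring)) {
    rlang::abort(sprintf("geometry error in %s: ring is self-intersecting", where),
                 class = "gemaflow_geometry_error")
  }
  invisible(TRUE)
}

# Proper-crossing test between all non-adjacent edge pairs (O(m^2); rings in
# practice have tens of vertices).
ring_self_intersects <- function(ring) {
  m <- nrow(ring) - 1L          # number of edges
  if (m < 3) return(TRUE)
  x1 <- ring[1:m, 1]; y1 <- ring[1:m, 2]
  x2 <- ring[2:(m + 1), 1]; y2 <- ring[2:(m + 1), 2]
  for (i in seq_len(m - 2L)) {
    # edges strictly after i, skipping the adjacent one (and edge m for i=1)
    j <- (i + 2L):m
    if (i == 1L) j <- j[j != m]
    if (!length(j)) next
    d1 <- (x2[i] - x1[i]) * (y1[j] - y1[i]) - (y2[i] - y1[i]) * (x1[j] - x1[i])
    d2 <- (x2[i] - x1[i]) * (y2[j] - y1[i]) - (y2[i] - y1[i]) * (x2[j] - x1[i])
    d3 <- (x2[j] - x1[j]) * (y1[i] - y1[j]) - (y2[j] - y1[j]) * (x1[i] - x1[j])
    d4 <- (x2[j] - x1[j]) * (y2[i] - y1[j]) - (y2[j] - y1[j]) * (x2[i] - x1[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Build a geofence table
#'
#' A geofence is an identified polygonal region, possibly multi-part and
#' possibly with interior rings (holes), carrying attribute properties such
#' as a land-use `class` ("park", "residential", ...). Geometry is validated
#' at load time: every ring must be closed, have at least four vertices, and
#' be non-self-intersecting.
#'
#' @param geofence_id Character vector of fence identifiers.
#' @param geometry List of geometries; each element a list of parts, each
#'   part a list of closed `[lon, lat]` ring matrices (exterior first).
#' @param class Character vector of land-use classes (default NA).
#' @param attributes Optional list of per-fence property lists.
#' @return A tibble of class `gemaflow_fences` with columns `geofence_id`,
#'   `class`, `geometry` (list), `bbox` (list of `c(xmin, ymin, xmax,
#'   ymax)`), `attributes` (list).
#' @export
geofences <- function(geofence_id, geometry, class = NA_character_,
                      attributes = NULL) {
  n <- length(geofence_id)
  stopifnot(length(geometry) == n)
  if (anyDuplicated(geofence_id)) {
    rlang::abort("geometry error: duplicate geofence_id",
                 class = "gemaflow_geometry_error")
  }
  for (i in seq_len(n)) {
    parts <- geometry[[i]]
    if (!length(parts)) {
      rlang::abort(sprintf("geometry error in %s: no exterior ring", geofence_id[i]),
                   class = "gemaflow_geometry_error")
    }
    for (p in seq_along(parts)) {
      for (r in seq_along(parts[[p]])) {
        validate_ring(parts[[p]][[r]],
                      sprintf("%s (part %d, ring %d)", geofence_id[i], p, r))
      }
    }
  }
  bbox <- lapply(geometry, function(parts) {
    xy <- do.call(rbind, unlist(parts, recursive = FALSE))
    c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
      xmax = max(xy[, 1]), ymax = max(xy[, 2]))
  })
  out <- tibble::tibble(
    geofence_id = as.character(geofence_id),
    class = rep_len(as.character(class), n),
    geometry = geometry,
    bbox = bbox,
    attributes = attributes %||% rep(list(list()), n)
  )
  class(out) <- c("gemaflow_fences", class(out))
  out
}

#' Read geofences from a GeoJSON FeatureCollection
#'
#' Accepts Polygon and MultiPolygon geometries with coordinates in
#' `[lon, lat]` order (RFC 7946, WGS84). Feature properties supply
#' `geofence_id` and `class`; a missing `geofence_id` falls back to the
#' feature's `id` member or a positional identifier.
#'
#' @param path Path to a GeoJSON file.
#' @return A `gemaflow_fences` tibble (see [geofences()]).
#' @export
read_geofences <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    rlang::abort("geometry error: expected a GeoJSON FeatureCollection",
                 class = "gemaflow_geometry_error")
  }
  feats <- gj$features
  ids <- character(length(feats)); classes <- character(length(feats))
  geoms <- vector("list", length(feats)); attrs <- vector("list", length(feats))
  ring_mat <- function(coords) {
    do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
  }
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    props <- f$properties %||% list()
    ids[i] <- as.character(props$geofence_id %||% f$id %||% sprintf("fence_%d", i))
    classes[i] <- as.character(props$class %||% NA_character_)
    g <- f$geometry
    if (identical(g$type, "Polygon")) {
      parts <- list(lapply(g$coordinates, ring_mat))
    } else if (identical(g$type, "MultiPolygon")) {
      parts <- lapply(g$coordinates, function(poly) lapply(poly, ring_mat))
    } else {
      rlang::abort(sprintf("geometry error in feature %d: unsupported geometry type '%s'",
                           i, g$type %||% "null"),
                   class = "gemaflow_geometry_error")
    }
    geoms[[i]] <- parts
    attrs[[i]] <- props[setdiff(names(props), c("geofence_id", "class"))]
  }
  geofences(ids, geoms, classes, attrs)
}

#' Write geofences as a GeoJSON FeatureCollection
#'
#' @param fences A `gemaflow_fences` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geofences <- function(fences, path) {
  stopifnot(inherits(fences, "gemaflow_fences"))
  features <- lapply(seq_len(nrow(fences)), function(i) {
    parts <- fences$geometry[[i]]
    coords <- lapply(parts, function(part) {
      lapply(part, function(ring) {
        lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1], ring[k, 2]))
      })
    })
    if (length(parts) == 1L) {
      geom <- list(type = "Polygon", coordinates = coords[[1]])
    } else {
      geom <- list(type = "MultiPolygon", coordinates = coords)
    }
    props <- c(list(geofence_id = fences$geofence_id[i],
                    class = fences$class[i]),
               fences$attributes[[i]])
    list(type = "Feature", properties = props, geometry = geom)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd containment of points (px, py) in one ring, plus boundary hits.
# Returns list(parity = logical, boundary = logical).
ring_hits <- function(ring, px, py) {
  m <- nrow(ring) - 1L
  parity <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  eps <- 1e-12
  for (i in seq_len(m)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    dx <- x2 - x1; dy <- y2 - y1
    # boundary: collinear within tolerance and inside the segment bbox
    cross <- dx * (py - y1) - dy * (px - x1)
    tol <- eps * (abs(dx) + abs(dy) + 1)
    onseg <- abs(cross) <= tol &
      px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
      py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
    boundary <- boundary | onseg
    if (dy != 0) {
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < x1 + (py - y1) / dy * dx)
      parity <- xor(parity, crosses)
    }
  }
  list(parity = parity, boundary = boundary)
}

# Containment of many points in one fence geometry (list of parts).
geometry_contains <- function(parts, px, py) {
  inside <- rep(FALSE, length(px))
  for (part in parts) {
    parity <- rep(FALSE, length(px))
    boundary <- rep(FALSE, length(px))
    for (ring in part) {
      h <- ring_hits(ring, px, py)
      parity <- xor(parity, h$parity)
      boundary <- boundary | h$boundary
    }
    inside <- inside | parity | boundary
  }
  inside
}

#' Point-in-geofence containment
#'
#' Even-odd (ray-casting) containment over all rings: interior rings are
#' holes (excluded), a MultiPolygon is the union of its parts, and points on
#' any boundary segment or vertex count as inside. Containment is evaluated
#' planar directly on lon/lat; at park scale the Earth's curvature is
#' negligible and the predicate stays projection-free and deterministic.
#'
#' @param fences A `gemaflow_fences` tibble.
#' @param lat,lon Numeric vectors of query coordinates (degrees WGS84).
#' @return A logical matrix with one row per query point and one named
#'   column per fence.
#' @examples
#' sq <- list(list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))))
#' f <- geofences("sq", list(sq), class = "park")
#' fence_contains(f, lat = 0.5, lon = 0.5)
#' @export
fence_contains <- function(fences, lat, lon) {
  stopifnot(inherits(fences, "gemaflow_fences"), length(lat) == length(lon))
  out <- matrix(FALSE, nrow = length(lat), ncol = nrow(fences),
                dimnames = list(NULL, fences$geofence_id))
  pad <- 1e-9
  for (j in seq_len(nrow(fences))) {
    bb <- fences$bbox[[j]]
    cand <- which(lon >= bb[1] - pad & lat >= bb[2] - pad &
                    lon <= bb[3] + pad & lat <= bb[4] + pad)
    if (length(cand)) {
      out[cand, j] <- geometry_contains(fences$geometry[[j]],
                                        lon[cand], lat[cand])
    }
  }
  out
}

#' Detect geofence visits and events from a fix stream
#'
#' A visit is a maximal run of consecutive fixes inside the same fence.
#' Because device sampling pauses while motionless, a silent gap bounded by
#' two inside-fixes of at most `max_gap_s` seconds counts as continuous
#' presence; a longer gap conservatively closes the visit at the last
#' observed inside fix. The first outside fix after an inside run closes the
#' visit with `exit_t` equal to that fix's timestamp (event-driven reading),
#' unless it arrives more than `max_gap_s` after the last inside fix, in
#' which case the visit closes at the last inside fix.
#'
#' Events are emitted at fix granularity: `ENTRY` at the first inside fix,
#' `DWELL` at the first fix whose elapsed time since entry reaches
#' `dwell_s`, `FOLLOWUP_DWELL` at the first fix reaching `followup_s` (only
#' in visits whose `DWELL` fired), and `EXIT` when the visit closes. A fix
#' inside k overlapping fences advances k concurrent visit states.
#'
#' @param fixes A time-sorted, accuracy-filtered fix tibble.
#' @param fences A `gemaflow_fences` tibble.
#' @param max_gap_s Largest silent gap treated as continuous presence
#'   (default 43200, i.e. 12 h).
#' @param dwell_s Dwell threshold in seconds (default 600, i.e. 10 min).
#' @param followup_s Follow-up dwell threshold in seconds (default 2700,
#'   i.e. 45 min).
#' @return A list of class `gemaflow_detection` with elements
#'   \describe{
#'     \item{visits}{tibble: `visit_id`, `participant_id`, `geofence_id`,
#'       `entry_t`, `exit_t` (NA while open), `fix_count`.}
#'     \item{events}{tibble: `kind` (ENTRY/DWELL/FOLLOWUP_DWELL/EXIT),
#'       `participant_id`, `geofence_id`, `t`, `visit_id`.}
#'   }
#' @export
detect_visits <- function(fixes, fences, max_gap_s = 43200,
                          dwell_s = 600, followup_s = 2700) {
  fixes <- validate_fixes(fixes)
  stopifnot(inherits(fences, "gemaflow_fences"))
  if (max_gap_s <= 0) {
    rlang::abort("configuration error: max_gap_s must be positive",
                 class = "gemaflow_config_error")
  }
  check_sorted(fixes$participant_id, fixes$t)

  visit_rows <- list()
  event_rows <- list()
  if (nrow(fixes)) {
    inside <- fence_contains(fences, fixes$lat, fixes$lon)
    split_idx <- split(seq_len(nrow(fixes)), fixes$participant_id)
    for (pid in names(split_idx)) {
      rows <- split_idx[[pid]]
      t <- fixes$t[rows]
      for (j in seq_len(ncol(inside))) {
        v <- inside[rows, j]
        if (!any(v)) next
        idx <- which(v)
        # split inside-fix runs: an intervening outside fix, or a time gap
        # beyond max_gap_s between consecutive inside fixes
        brk <- which(diff(idx) > 1L | diff(t[idx]) > max_gap_s)
        starts <- c(1L, brk + 1L)
        ends <- c(brk, length(idx))
        for (k in seq_along(starts)) {
          run <- idx[starts[k]:ends[k]]
          entry_t <- t[run[1]]
          last_in <- t[run[length(run)]]
          nxt <- run[length(run)] + 1L
          if (nxt <= length(t)) {
            # stream continues: outside fix or a gap-broken inside fix
            exit_t <- if (t[nxt] - last_in <= max_gap_s && !v[nxt]) t[nxt] else last_in
            open <- FALSE
          } else {
            exit_t <- NA_real_
            open <- TRUE
          }
          gid <- colnames(inside)[j]
          vid <- make_uuid("visit", pid, gid, entry_t)
          visit_rows[[length(visit_rows) + 1L]] <- tibble::tibble(
            visit_id = vid, participant_id = pid, geofence_id = gid,
            entry_t = entry_t, exit_t = exit_t,
            fix_count = length(run))
          ev <- tibble::tibble(kind = "ENTRY", participant_id = pid,
                               geofence_id = gid, t = entry_t, visit_id = vid)
          dw <- which(t[run] - entry_t >= dwell_s)
          if (length(dw)) {
            ev <- dplyr::bind_rows(ev, tibble::tibble(
              kind = "DWELL", participant_id = pid, geofence_id = gid,
              t = t[run[dw[1]]], visit_id = vid))
            fu <- which(t[run] - entry_t >= followup_s)
            if (length(fu)) {
              ev <- dplyr::bind_rows(ev, tibble::tibble(
                kind = "FOLLOWUP_DWELL", participant_id = pid,
                geofence_id = gid, t = t[run[fu[1]]], visit_id = vid))
            }
          }
          if (!open) {
            ev <- dplyr::bind_rows(ev, tibble::tibble(
              kind = "EXIT", participant_id = pid, geofence_id = gid,
              t = exit_t, visit_id = vid))
          }
          event_rows[[length(event_rows) + 1L]] <- ev
        }
      }
    }
  }
  empty_visits <- tibble::tibble(visit_id = character(),
                                 participant_id = character(),
                                 geofence_id = character(),
                                 entry_t = numeric(), exit_t = numeric(),
                                 fix_count = integer())
  empty_events <- tibble::tibble(kind = character(),
                                 participant_id = character(),
                                 geofence_id = character(),
                                 t = numeric(), visit_id = character())
  visits <- if (length(visit_rows)) dplyr::bind_rows(visit_rows) else empty_visits
  events <- if (length(event_rows)) dplyr::bind_rows(event_rows) else empty_events
  visits <- dplyr::arrange(visits, .data$participant_id, .data$entry_t,
                           .data$geofence_id)
  kind_rank <- c(ENTRY = 1, DWELL = 2, FOLLOWUP_DWELL = 3, EXIT = 4)
  events <- dplyr::arrange(events, .data$participant_id, .data$t,
                           kind_rank[.data$kind], .data$geofence_id)
  structure(list(visits = visits, events = events),
            class = "gemaflow_detection")
}

#' Close visits still open at end of study
#'
#' Visits whose participant's stream simply stopped (no outside fix, no
#' over-long gap observed) are open; end-of-study accounting closes them at
#' the supplied time, or at their last plausible moment (`entry_t`) when no
#' time is given.
#'
#' @param visits A visit tibble from [detect_visits()].
#' @param end_t Epoch seconds at which to close open visits. Must be at or
#'   after each open visit's `entry_t`.
#' @return The visit tibble with no open (`NA`) exit times.
#' @export
close_visits <- function(visits, end_t) {
  open <- is.na(visits$exit_t)
  if (any(open & visits$entry_t > end_t)) {
    rlang::abort("end_t precedes the entry of an open visit",
                 class = "gemaflow_config_error")
  }
  visits$exit_t[open] <- end_t
  visits
}

#' Time spent per land-use class
#'
#' Sums closed-visit durations per participant and fence class. Open visits
#' are an error: close them first with [close_visits()].
#'
#' @param visits A closed visit tibble.
#' @param fences The `gemaflow_fences` tibble the visits refer to.
#' @return A tibble: `participant_id`, `class`, `seconds`.
#' @export
time_in_class <- function(visits, fences) {
  stopifnot(inherits(fences, "gemaflow_fences"))
  if (anyNA(visits$exit_t)) {
    rlang::abort("open visit encountered: close visits before time accounting",
                 class = "gemaflow_state_error")
  }
  visits |>
    dplyr::inner_join(tibble::tibble(geofence_id = fences$geofence_id,
                                     class = fences$class),
                      by = "geofence_id") |>
    dplyr::group_by(.data$participant_id, .data$class) |>
    dplyr::summarise(seconds = sum(.data$exit_t - .data$entry_t),
                     .groups = "drop")
}

#' Share of time in a target class, excluding another
#'
#' The time-use summary reported for park exposure: per participant, the
#' share of time spent in `target` class fences relative to all time in
#' fences not of the `exclude` class (residential time is excluded because
#' it dominates everyone's day).
#'
#' @param visits A closed visit tibble.
#' @param fences A `gemaflow_fences` tibble.
#' @param target Class whose share is reported (default "park").
#' @param exclude Class excluded from the denominator (default
#'   "residential").
#' @return A tibble: `participant_id`, `target_s`, `total_s`, `share`
#'   (NA, flagged by `undefined = TRUE`, for participants with no
#'   non-excluded time).
#' @export
time_share <- function(visits, fences, target = "park",
                       exclude = "residential") {
  tic <- time_in_class(visits, fences)
  tic |>
    dplyr::filter(!.data$class %in% exclude) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      target_s = sum(.data$seconds[.data$class %in% target]),
      total_s = sum(.data$seconds), .groups = "drop") |>
    dplyr::mutate(
      share = ifelse(.data$total_s > 0, .data$target_s / .data$total_s,
                     NA_real_),
      undefined = .data$total_s <= 0)
}

#' Write geofence events as JSON-lines
#'
#' One object per line with keys `kind`, `participant_id`, `geofence_id`,
#' `t` (integer epoch seconds) and `visit_id`.
#'
#' @param events An event tibble from [detect_visits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write_jsonl(events, path)
}
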