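# Internal helpers: hashing, seeded RNG isolation, rounding, geodesy,
# local-time arithmetic. No exports except round_half_up and haversine_m.

`%||%` <- function(x, y) if (is.null(x)) y else x

# FNV-1a 32-bit over the UTF-8 bytes of a string, in pure double arithmetic
# (values never exceed 2^53, so products are exact).
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  p <- 16777619
  hi <- 33052   # 0x811C
  lo <- 40389   # 0x9DC5
  for (b in bytes) {
    lo <- bitwXor(lo, b %% 256L)
    prod_lo <- lo * p
    prod_hi <- (hi * p) %% 65536
    h <- (prod_lo + prod_hi * 65536) %% 4294967296
    hi <- h %/% 65536
    lo <- h %% 65536
  }
  hi * 65536 + lo
}

# Derive a 31-bit RNG seed from string parts; always in [1, 2^31 - 2].
derive_seed <- function(...) {
  h <- fnv1a32(paste(c(...), collapse = "\x1f"))
  as.integer(h %% 2147483645) + 1L
}

# Uniform in [0, 1) derived from a string key (not an RNG stream; one value).
keyed_unit <- function(...) {
  fnv1a32(paste(c(...), collapse = "\x1f")) / 4294967296
}

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# zero-padded lowercase hex of a 32-bit value held in a double
hex8 <- function(h) {
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministic UUID-format identifier from string parts (five salted FNV
# hashes laid out as 8-4-4-4-12 hex). Not cryptographic; used so reruns of
# identical input produce byte-identical prompt logs.
make_uuid <- function(...) {
  s <- paste(c(...), collapse = "\x1f")
  h <- vapply(1:5, function(i) fnv1a32(paste0(i, "#", s)), numeric(1))
  sprintf("%s-%04x-%04x-%04x-%04x%s",
          hex8(h[1]), as.integer(h[2] %% 65536), as.integer(h[3] %% 65536),
          as.integer(h[4] %% 65536), as.integer(h[5] %% 65536), hex8(h[5]))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages here follow
#' the usual presentation convention of rounding .5 away from zero.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(6.5, 7.5, -6.5))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5) / m
}

#' Great-circle distance in metres
#'
#' Haversine distance on a spherical Earth (radius 6,371,000 m). Vectorised
#' over all four arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees WGS84.
#' @return Distance(s) in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  r <- 6371000
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# metres per degree of latitude (spherical); longitude scales by cos(lat)
M_PER_DEG <- 6371000 * pi / 180

check_timezone <- function(tz) {
  if (!is.character(tz) || length(tz) != 1L || !tz %in% OlsonNames()) {
    rlang::abort(
      sprintf("configuration error: unknown IANA timezone '%s'", tz),
      class = "gemaflow_config_error"
    )
  }
  invisible(tz)
}

# Local calendar date (character "YYYY-MM-DD") of epoch seconds in tz.
local_date <- function(t, tz) {
  check_timezone(tz)
  format(as.POSIXct(t, origin = "1970-01-01", tz = tz), "%Y-%m-%d")
}

# Seconds since local midnight (wall clock) of epoch seconds in tz.
local_seconds_of_day <- function(t, tz) {
  check_timezone(tz)
  lt <- as.POSIXlt(as.POSIXct(t, origin = "1970-01-01", tz = tz))
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

# "HH:MM" -> seconds since midnight
parse_hhmm <- function(x) {
  ok <- grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", x)
  if (!all(ok)) {
    rlang::abort(
      sprintf("configuration error: bad clock time '%s' (expected HH:MM)",
              x[!ok][1]),
      class = "gemaflow_config_error"
    )
  }
  as.integer(substr(x, 1, 2)) * 3600 + as.integer(substr(x, 4, 5)) * 60
}

# epoch seconds of local date "YYYY-MM-DD" + seconds-of-day in tz
local_epoch <- function(date, sod, tz) {
  midnight <- as.numeric(as.POSIXct(paste0(date, " 00:00:00"), tz = tz))
  midnight + sod
}

# Error unless t is non-decreasing within each participant; names the first
# offending (1-based) row index of the input order.
check_sorted <- function(participant_id, t) {
  bad <- unlist(lapply(split(seq_along(t), participant_id), function(idx) {
    d <- diff(t[idx])
    if (any(d < 0)) idx[which(d < 0)[1] + 1L] else integer(0)
  }), use.names = FALSE)
  if (length(bad)) {
    rlang::abort(
      sprintf("ordering violation: fixes not sorted by time (first offending row: %d)",
              min(bad)),
      class = "gemaflow_order_error"
    )
  }
  invisible(TRUE)
}
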