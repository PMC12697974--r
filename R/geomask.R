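# geomask: reversible keyed coordinate disarrangement. Stored location data
# never reveals true positions; the same secret recovers them exactly.
#
# Scheme: project fixes into a local equirectangular plane about the data
# centroid, apply a keyed rigid rotation whose fixed point lies a keyed
# 1-2 thousand km away from the data (so every point is displaced at least
# the configured floor), permute record order with a keyed seed, and stash
# the projection origin in the file header offset by a keyed shift. A keyed
# checksum over the true coordinates detects wrong-key unmasking instead of
# returning plausible-but-wrong positions.

#' Create a masking key
#'
#' All masking parameters (rotation angle, fixed-point placement, record
#' permutation seed, origin shift, checksum salt) derive deterministically
#' from the secret, so the same secret always produces the same mask.
#'
#' @param secret High-entropy opaque string.
#' @param floor_m Minimum guaranteed displacement of every masked point from
#'   its true position, in metres (default 1000).
#' @return A list of class `gemaflow_mask_key`.
#' @export
mask_key <- function(secret, floor_m = 1000) {
  stopifnot(is.character(secret), length(secret) == 1L, nzchar(secret))
  if (floor_m <= 0) {
    rlang::abort("configuration error: floor_m must be positive",
                 class = "gemaflow_config_error")
  }
  # The transform is a rotation about a keyed fixed point ~2000 km away.
  # A point at planar distance d from the fixed point moves by
  # 2*sin(theta/2)*d, so with data confined to 1000 km of the projection
  # origin the displacement is bounded below by chord*(dist - 1e6) and
  # above by chord*(dist + 1e6). The angle is kept small enough that the
  # largest displacement stays ~150 km: far beyond any privacy floor, yet
  # small enough that equirectangular distortion leaves within-stream
  # distances intact (the analytic-utility goal of geomasking).
  chord_min <- max(5e-3, 2 * floor_m / 1e6)
  if (chord_min > 5e-2) {
    rlang::abort("configuration error: floor_m above 25000 m is not supported by the masking geometry",
                 class = "gemaflow_config_error")
  }
  chord <- chord_min + (5e-2 - chord_min) * keyed_unit(secret, "theta")
  theta <- 2 * asin(chord / 2)
  phi <- 2 * pi * keyed_unit(secret, "phi")
  dist <- 2e6 + 1e6 * keyed_unit(secret, "dist")
  structure(list(secret = secret, floor_m = floor_m, theta = theta,
                 phi = phi, dist = dist,
                 perm_seed = derive_seed(secret, "perm"),
                 origin_shift = c(
                   lat = -1e4 + 2e4 * keyed_unit(secret, "olat"),
                   lon = -1e4 + 2e4 * keyed_unit(secret, "olon"))),
            class = "gemaflow_mask_key")
}

mask_checksum <- function(secret, lat, lon, t) {
  payload <- paste(sprintf("%.9f,%.9f,%.3f", lat, lon, t), collapse = ";")
  paste0(hex8(fnv1a32(paste0(secret, "|chk1|", payload))),
         hex8(fnv1a32(paste0(secret, "|chk2|", payload))))
}

#' Mask a fix stream
#'
#' Applies the keyed rigid transform and record permutation. Timestamps and
#' accuracy values are unchanged; inter-point distances within the stream
#' are preserved (up to local projection error) while every absolute
#' position moves at least `floor_m` metres. Deterministic in
#' `(fixes, key)`.
#'
#' @param fixes A fix tibble.
#' @param key A [mask_key()].
#' @return A tibble of class `gemaflow_masked` with the fix schema plus a
#'   `header` attribute `list(masked = TRUE, checksum, origin_token)`.
#' @export
mask_fixes <- function(fixes, key) {
  fixes <- validate_fixes(fixes)
  stopifnot(inherits(key, "gemaflow_mask_key"))
  n <- nrow(fixes)
  if (n == 0) {
    origin <- c(lat = 0, lon = 0)
  } else {
    origin <- c(lat = mean(fixes$lat), lon = mean(fixes$lon))
  }
  sx <- M_PER_DEG * cos(origin[["lat"]] * pi / 180)
  sy <- M_PER_DEG
  px <- (fixes$lon - origin[["lon"]]) * sx
  py <- (fixes$lat - origin[["lat"]]) * sy
  far <- which(sqrt(px^2 + py^2) > 1e6)
  if (length(far)) {
    rlang::abort(paste0("points outside projectable range (>1000 km from stream centroid): rows ",
                        paste(utils::head(far, 10), collapse = ", "),
                        if (length(far) > 10) " ..."),
                 class = "gemaflow_projection_error")
  }
  ct <- cos(key$theta); st <- sin(key$theta)
  fx <- key$dist * cos(key$phi); fy <- key$dist * sin(key$phi)
  # rigid map q = R (p - f) + f with fixed point f
  qx <- ct * (px - fx) - st * (py - fy) + fx
  qy <- st * (px - fx) + ct * (py - fy) + fy
  out <- fixes
  out$lon <- qx / sx + origin[["lon"]]
  out$lat <- qy / sy + origin[["lat"]]
  perm <- with_seed(key$perm_seed, sample.int(n))
  out <- out[perm, , drop = FALSE]
  header <- list(
    masked = TRUE,
    checksum = mask_checksum(key$secret, fixes$lat, fixes$lon, fixes$t),
    origin_token = c(lat = origin[["lat"]] + key$origin_shift[["lat"]],
                     lon = origin[["lon"]] + key$origin_shift[["lon"]]))
  attr(out, "header") <- header
  class(out) <- c("gemaflow_masked", class(out))
  out
}

#' Unmask a masked fix stream
#'
#' Exact inverse of [mask_fixes()] under the same key: inverse permutation,
#' then the inverse rigid transform. A keyed checksum recomputed over the
#' recovered coordinates detects unmasking with the wrong key.
#'
#' @param masked A `gemaflow_masked` tibble (or a tibble plus `header`
#'   attribute as produced by [read_masked()]).
#' @param key The [mask_key()] used to mask.
#' @return The original fix tibble, in original record order.
#' @export
unmask_fixes <- function(masked, key) {
  stopifnot(inherits(key, "gemaflow_mask_key"))
  header <- attr(masked, "header")
  if (is.null(header) || !isTRUE(header$masked)) {
    rlang::abort("input is not a masked stream (missing header)",
                 class = "gemaflow_mask_error")
  }
  n <- nrow(masked)
  perm <- with_seed(key$perm_seed, sample.int(n))
  out <- masked
  out[perm, ] <- as.data.frame(masked)
  origin <- c(lat = header$origin_token[["lat"]] - key$origin_shift[["lat"]],
              lon = header$origin_token[["lon"]] - key$origin_shift[["lon"]])
  sx <- M_PER_DEG * cos(origin[["lat"]] * pi / 180)
  sy <- M_PER_DEG
  qx <- (out$lon - origin[["lon"]]) * sx
  qy <- (out$lat - origin[["lat"]]) * sy
  ct <- cos(key$theta); st <- sin(key$theta)
  fx <- key$dist * cos(key$phi); fy <- key$dist * sin(key$phi)
  px <- ct * (qx - fx) + st * (qy - fy) + fx
  py <- -st * (qx - fx) + ct * (qy - fy) + fy
  out$lon <- px / sx + origin[["lon"]]
  out$lat <- py / sy + origin[["lat"]]
  if (n > 0 &&
      !identical(mask_checksum(key$secret, out$lat, out$lon, out$t),
                 header$checksum)) {
    rlang::abort("key mismatch: checksum of recovered coordinates does not match the masked-file header",
                 class = "gemaflow_key_error")
  }
  out <- tibble::as_tibble(as.data.frame(out))
  attr(out, "header") <- NULL
  class(out) <- setdiff(class(out), "gemaflow_masked")
  validate_fixes(out)
}

#' Read and write masked fix files
#'
#' Masked files keep the fix CSV schema; the first line is a comment header
#' `#gemaflow-mask {json}` carrying `masked`, `checksum` and the keyed
#' origin token.
#'
#' @param masked A `gemaflow_masked` tibble.
#' @param path File path.
#' @return `write_masked()` returns `path` invisibly; `read_masked()`
#'   returns a `gemaflow_masked` tibble.
#' @export
write_masked <- function(masked, path) {
  header <- attr(masked, "header")
  if (is.null(header)) {
    rlang::abort("not a masked stream", class = "gemaflow_mask_error")
  }
  hdr <- jsonlite::toJSON(list(masked = TRUE, checksum = header$checksum,
                               origin_token = as.list(header$origin_token)),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#gemaflow-mask ", hdr), con)
  writeLines(paste(c("participant_id", "lat", "lon", "t", "accuracy_m"),
                   collapse = ","), con)
  if (nrow(masked)) {
    writeLines(sprintf("%s,%.12f,%.12f,%s,%s", masked$participant_id,
                       masked$lat, masked$lon,
                       format(masked$t, scientific = FALSE, trim = TRUE),
                       format(masked$accuracy_m, scientific = FALSE,
                              trim = TRUE)), con)
  }
  invisible(path)
}

#' @rdname write_masked
#' @export
read_masked <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#gemaflow-mask ")) {
    rlang::abort("not a masked file (missing #gemaflow-mask header)",
                 class = "gemaflow_mask_error")
  }
  header <- jsonlite::fromJSON(sub("^#gemaflow-mask ", "", first))
  header$origin_token <- unlist(header$origin_token)
  df <- utils::read.csv(path, skip = 1, colClasses = c(
    participant_id = "character", lat = "numeric", lon = "numeric",
    t = "numeric", accuracy_m = "numeric"))
  out <- tibble::as_tibble(df)
  attr(out, "header") <- header
  class(out) <- c("gemaflow_masked", class(out))
  out
}
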