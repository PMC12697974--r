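# autoplot / tidy / glance methods and print methods for the main result
# types, in the broom / ggplot2 idiom.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an adherence table
#'
#' @param x A `gemaflow_adherence` tibble.
#' @param ... Unused.
#' @return A plain tibble, one row per prompt kind.
#' @method tidy gemaflow_adherence
#' @export
tidy.gemaflow_adherence <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a pipeline run
#'
#' @param x A `gemaflow_run` object.
#' @param ... Unused.
#' @return The adherence table of the run, as a tibble.
#' @method tidy gemaflow_run
#' @export
tidy.gemaflow_run <- function(x, ...) {
  tidy(x$adherence)
}

#' One-row summary of a pipeline run
#'
#' @param x A `gemaflow_run` object.
#' @param ... Unused.
#' @return A one-row tibble: participants, fixes, prompts, responses,
#'   overall adherence percentage, detected visits.
#' @method glance gemaflow_run
#' @export
glance.gemaflow_run <- function(x, ...) {
  tibble::tibble(
    n_participants = x$cfg$n_participants,
    n_fixes = nrow(x$fixes),
    n_fixes_retained = nrow(x$filtered),
    n_visits = nrow(x$visits),
    n_prompts = nrow(x$prompts),
    n_responses = nrow(x$responses),
    adherence_pct = if (nrow(x$prompts))
      round_half_up(100 * nrow(x$responses) / nrow(x$prompts), 1)
    else NA_real_)
}

#' Plot an adherence table
#'
#' Bar chart of mean adherence per prompt kind with across-participant
#' standard deviation whiskers.
#'
#' @param object A `gemaflow_adherence` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gemaflow_adherence
#' @export
autoplot.gemaflow_adherence <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$prompt_kind <- factor(d$prompt_kind, levels = d$prompt_kind)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$prompt_kind,
                                  y = .data$adherence_pct_mean)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(0, .data$adherence_pct_mean - .data$adherence_pct_sd),
        ymax = pmin(100, .data$adherence_pct_mean + .data$adherence_pct_sd)),
      width = 0.2) +
    ggplot2::labs(x = NULL, y = "Adherence (%)",
                  title = "Prompt adherence by kind",
                  subtitle = "bars: participant mean; whiskers: ± participant SD") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot detected visits as a timeline
#'
#' One horizontal segment per closed visit, participants on the y axis,
#' coloured by geofence.
#'
#' @param object A `gemaflow_detection` result from [detect_visits()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gemaflow_detection
#' @export
autoplot.gemaflow_detection <- function(object, ...) {
  v <- object$visits[!is.na(object$visits$exit_t), ]
  ggplot2::ggplot(v, ggplot2::aes(y = .data$participant_id,
                                  colour = .data$geofence_id)) +
    ggplot2::geom_segment(ggplot2::aes(
      x = as.POSIXct(.data$entry_t, origin = "1970-01-01", tz = "UTC"),
      xend = as.POSIXct(.data$exit_t, origin = "1970-01-01", tz = "UTC"),
      yend = .data$participant_id), linewidth = 2) +
    ggplot2::labs(x = NULL, y = NULL, colour = "geofence",
                  title = "Detected geofence visits") +
    ggplot2::theme_minimal()
}

#' Plot fixes over the fence map
#'
#' Fence polygons (holes rendered) under the fix scatter; a quick visual
#' check of trajectories against geofences.
#'
#' @param fixes A fix tibble.
#' @param fences A `gemaflow_fences` tibble.
#' @param max_points Subsample cap for the fix layer (default 5000).
#' @return A ggplot.
#' @export
plot_trajectories <- function(fixes, fences, max_points = 5000) {
  rings <- purrr::imap_dfr(fences$geometry, function(parts, i) {
    purrr::imap_dfr(parts, function(part, p) {
      purrr::imap_dfr(part, function(ring, r) {
        tibble::tibble(lon = ring[, 1], lat = ring[, 2],
                       class = fences$class[i],
                       grp = sprintf("%s.%d.%d", fences$geofence_id[i], p, r),
                       poly = sprintf("%s.%d", fences$geofence_id[i], p))
      })
    })
  })
  if (nrow(fixes) > max_points) {
    fixes <- fixes[seq(1, nrow(fixes), length.out = max_points), ]
  }
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = rings,
      ggplot2::aes(.data$lon, .data$lat, group = .data$grp,
                   fill = .data$class),
      colour = "grey30", linewidth = 0.2, alpha = 0.5) +
    ggplot2::geom_point(
      data = fixes, ggplot2::aes(.data$lon, .data$lat),
      size = 0.3, alpha = 0.4) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}

#' @export
print.gemaflow_run <- function(x, ...) {
  g <- glance(x)
  cat("<gemaflow run>\n")
  cat(sprintf("  participants: %d   fixes: %d (retained %d)\n",
              g$n_participants, g$n_fixes, g$n_fixes_retained))
  cat(sprintf("  visits: %d   prompts: %d   responses: %d (%.1f%%)\n",
              g$n_visits, g$n_prompts, g$n_responses, g$adherence_pct))
  invisible(x)
}

#' @export
print.gemaflow_protocol <- function(x, ...) {
  cat(sprintf("<gemaflow protocol> %d rule(s), tz %s, filter %g m, gap %g s\n",
              nrow(x$rules), x$timezone, x$max_radial_m, x$max_gap_s))
  print(dplyr::select(x$rules, "rule_id", "kind", "window_start",
                      "window_end", "min_dwell_s", "geofence_class",
                      "expiry_s"))
  invisible(x)
}
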