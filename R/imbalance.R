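# Neighbour fate-imbalance statistic in the lookback window before divisions.

#' Configuration for the neighbour fate-imbalance statistic
#'
#' @param radius_um Neighbourhood radius around the focal division, um
#'   (default 10, roughly one cell distance); inclusive.
#' @param max_lookback_h Longest lookback before the focal division, hours.
#' @param frame_interval_h Lookback grid spacing, hours.
#' @param sign_convention `"figure"` scores neighbour gain through division as
#'   +1 and loss through delamination as -1; `"methods"` is the mirror
#'   convention (+1 differentiation, -1 division). The two describe the same
#'   curve reflected about zero.
#' @return Object of class `imbalance_config`.
#' @export
imbalance_config <- function(radius_um = 10, max_lookback_h = 120,
                             frame_interval_h = 12,
                             sign_convention = c("figure", "methods")) {
  stop_if_not_positive(radius_um, "radius_um")
  stop_if_not_positive(max_lookback_h, "max_lookback_h")
  stop_if_not_positive(frame_interval_h, "frame_interval_h")
  structure(list(radius_um = radius_um, max_lookback_h = max_lookback_h,
                 frame_interval_h = frame_interval_h,
                 sign_convention = match.arg(sign_convention)),
            class = "imbalance_config")
}

check_focal <- function(events, focal_id) {
  k <- match(focal_id, events$event_id)
  if (is.na(k)) stop(sprintf("focal event %s not found", focal_id))
  if (events$type[k] != "division") stop("focal event is not a division")
  k
}

#' Events in the neighbourhood and lookback window of a focal division
#'
#' Keeps events with Euclidean distance at most `radius_um` from the focal
#' position (inclusive) whose time is strictly before the focal time and
#' within `max_lookback_h`. The focal event itself is excluded, and so is
#' the focal cell's own birth division when the event table carries lineage
#' columns (`cell_id`, `daughter1`, `daughter2`): the statistic counts
#' neighbour gain and loss, and a cell's own appearance (parent replaced by
#' itself plus one sibling) is a net-zero change to its neighbourhood.
#'
#' @param events Event table (`event_id`, `type`, `time_h`, `x_um`, `y_um`).
#' @param focal_id Event id of the focal division.
#' @param config An [imbalance_config()].
#' @return Subset of `events`.
#' @export
neighbor_events <- function(events, focal_id, config = imbalance_config()) {
  k <- check_focal(events, focal_id)
  d2 <- (events$x_um - events$x_um[k])^2 + (events$y_um - events$y_um[k])^2
  sel <- d2 <= config$radius_um^2 &
    events$time_h < events$time_h[k] &
    events$time_h > events$time_h[k] - config$max_lookback_h &
    events$event_id != focal_id
  if (all(c("cell_id", "daughter1", "daughter2") %in% names(events))) {
    fc <- events$cell_id[k]
    own_birth <- !is.na(events$daughter1) & (events$daughter1 == fc) |
      !is.na(events$daughter2) & (events$daughter2 == fc)
    sel <- sel & !own_birth
  }
  events[sel, , drop = FALSE]
}

#' Cumulative neighbour fate-imbalance track before one division
#'
#' Taking the timepoint right after the focal division as zero and going back
#' in time, sums +1 for each neighbour division and -1 for each neighbour
#' delamination inside the window `(t_focal - tau, t_focal)`, for each
#' lookback `tau` on the grid (multiples of `frame_interval_h` up to
#' `max_lookback_h`).
#'
#' @inheritParams neighbor_events
#' @return Object of class `imbalance_track`: list with `focal_id`,
#'   `lookback_h` and integer `imbalance`.
#' @export
imbalance_track <- function(events, focal_id, config = imbalance_config()) {
  k <- check_focal(events, focal_id)
  nb <- neighbor_events(events, focal_id, config)
  taus <- seq(config$frame_interval_h, config$max_lookback_h,
              by = config$frame_interval_h)
  sgn <- ifelse(nb$type == "division", 1L, -1L)
  if (config$sign_convention == "methods") sgn <- -sgn
  dt <- events$time_h[k] - nb$time_h  # > 0 by construction
  imb <- vapply(taus, function(tau) sum(sgn[dt < tau]), integer(1))
  structure(list(focal_id = focal_id, lookback_h = taus, imbalance = imb),
            class = "imbalance_track")
}

#' Mean imbalance across focal divisions
#'
#' Pointwise mean and fluctuation (s.d. across focal events) of the
#' imbalance tracks on a shared lookback grid.
#'
#' @param tracks List of [imbalance_track()] results.
#' @return `data.frame(lookback_h, mean, sd, n_events)`.
#' @export
mean_imbalance <- function(tracks) {
  if (!length(tracks)) stop("no imbalance tracks supplied")
  grid <- tracks[[1]]$lookback_h
  for (tr in tracks)
    if (!identical(tr$lookback_h, grid)) stop("mismatched lookback grids")
  m <- do.call(rbind, lapply(tracks, `[[`, "imbalance"))
  data.frame(lookback_h = grid,
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             n_events = nrow(m))
}

#' All imbalance tracks for the divisions in an event table
#'
#' Convenience wrapper computing [imbalance_track()] for every division,
#' optionally restricted to focal divisions late enough that their full
#' lookback window is observed.
#'
#' @param events Event table.
#' @param config An [imbalance_config()].
#' @param full_window_only If `TRUE` (default), keep only divisions with
#'   `time_h >= max_lookback_h` so early-run truncation does not bias the
#'   average.
#' @return List of `imbalance_track` objects.
#' @export
imbalance_tracks_all <- function(events, config = imbalance_config(),
                                 full_window_only = TRUE) {
  div <- events[events$type == "division", , drop = FALSE]
  if (full_window_only)
    div <- div[div$time_h >= config$max_lookback_h, , drop = FALSE]
  lapply(div$event_id, function(id) imbalance_track(events, id, config))
}
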