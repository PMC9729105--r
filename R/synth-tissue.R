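# Basal-layer event simulator: delaminations can trigger nearby divisions.

#' Configuration for the basal-layer tissue simulator
#'
#' The simulator emulates homeostatic turnover of the epidermal basal layer:
#' cells delaminate (leave the layer) stochastically, and each delamination can
#' trigger a compensatory division of a neighbouring cell within
#' `trigger_radius`, after a day-scale delay. A differentiation-reporter onset
#' time is drawn for every delaminating cell several days before its exit.
#'
#' @param field_size Numeric length-2, field dimensions in um.
#' @param init_density Initial cell density, cells per 100 um^2.
#' @param frame_interval Imaging frame interval in hours.
#' @param n_frames Number of frames; total simulated time is
#'   `frame_interval * (n_frames - 1)` hours.
#' @param delam_rate Background delamination rate, events per cell per day.
#' @param div_rate Background (uncoupled) division rate, events per cell per
#'   day. Default 0: in the coupled model divisions arise only as responses
#'   to neighbour loss.
#' @param coupling_prob Probability in \[0, 1\] that a delamination triggers one
#'   division among neighbours within `trigger_radius`.
#' @param trigger_radius Neighbourhood radius for triggering, um (one cell
#'   distance, default 10).
#' @param trigger_delay Length-2 interval (hours) from which the delay between
#'   a delamination and its triggered division is drawn uniformly.
#' @param reporter_lead Length-2 `c(mean, sd)` in hours of the (truncated
#'   normal) lead time between reporter onset and delamination. Default mean
#'   84 h: reporter onset typically precedes basal exit by 3-4 days.
#' @param homeostatic Logical; if `TRUE` coupling is forced to 1 so every
#'   neighbour loss is compensated and the population stays balanced.
#' @param burn_in_h Stationary warm-up period, hours; the simulation starts
#'   `burn_in_h` before time zero so that the lagged compensation pipeline is
#'   already in flight at the start of the observation window. Default: twice
#'   the maximum trigger delay in homeostatic mode, else 0.
#' @param jitter_sd Per-frame positional jitter s.d. in um (cells are
#'   quasi-static; tracking relies on revisits, not migration).
#' @param cell_radius Nominal cell radius in um; daughters are placed at
#'   +/- half a radius along a random axis parallel to the basal plane.
#' @param seed Integer master seed.
#' @return An object of class `tissue_sim_config`.
#' @export
tissue_sim_config <- function(field_size = c(220, 220),
                              init_density = 2,
                              frame_interval = 12,
                              n_frames = 15,
                              delam_rate = 0.3,
                              div_rate = 0,
                              coupling_prob = 1,
                              trigger_radius = 10,
                              trigger_delay = c(12, 48),
                              reporter_lead = c(84, 12),
                              homeostatic = FALSE,
                              burn_in_h = NULL,
                              jitter_sd = 0.3,
                              cell_radius = 5,
                              seed = 1L) {
  stopifnot(length(field_size) == 2L)
  stop_if_not_positive(field_size, "field_size")
  stop_if_not_positive(init_density, "init_density")
  stop_if_not_positive(frame_interval, "frame_interval")
  stopifnot(n_frames >= 2)
  stop_if_not_positive(delam_rate, "delam_rate", strict = FALSE)
  stop_if_not_positive(div_rate, "div_rate", strict = FALSE)
  stop_if_not_scalar_prob(coupling_prob, "coupling_prob")
  stop_if_not_positive(trigger_radius, "trigger_radius")
  stopifnot(length(trigger_delay) == 2L, trigger_delay[1] >= 0,
            trigger_delay[2] >= trigger_delay[1])
  stopifnot(length(reporter_lead) == 2L, reporter_lead[1] > 0, reporter_lead[2] >= 0)
  if (is.null(burn_in_h))
    burn_in_h <- if (isTRUE(homeostatic)) 2 * trigger_delay[2] else 0
  stop_if_not_positive(burn_in_h, "burn_in_h", strict = FALSE)
  structure(list(field_size = as.numeric(field_size),
                 init_density = init_density,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 delam_rate = delam_rate,
                 div_rate = div_rate,
                 coupling_prob = if (isTRUE(homeostatic)) 1 else coupling_prob,
                 trigger_radius = trigger_radius,
                 trigger_delay = as.numeric(trigger_delay),
                 reporter_lead = as.numeric(reporter_lead),
                 homeostatic = isTRUE(homeostatic),
                 burn_in_h = burn_in_h,
                 jitter_sd = jitter_sd,
                 cell_radius = cell_radius,
                 seed = as.integer(seed)),
            class = "tissue_sim_config")
}

#' Simulate basal-layer division/delamination dynamics
#'
#' Event-driven continuous-time simulation. Background delaminations (and,
#' optionally, uncoupled background divisions) occur as Poisson processes over
#' the living cells. With probability `coupling_prob` a delamination picks one
#' uniform neighbour within `trigger_radius` and schedules its division after
#' a uniform `trigger_delay`; the causal link is recorded in the event table.
#' No compensatory delamination is scheduled when a triggered division fires:
#' density regulation emerges from the rate/coupling balance.
#'
#' @param config A [tissue_sim_config()].
#' @param seed_delamination Optional list `list(time =, cell_id =)` forcing one
#'   deterministic delamination (used to probe the coupling rule in isolation).
#' @return An object of class `basal_sim`: list with
#'   * `cells`: one row per cell (`cell_id`, `parent_id`, `birth_time`,
#'     `end_time`, `end_fate` in `{divide, delaminate, censored}`, `x0`, `y0`,
#'     `reporter_on_time`),
#'   * `events`: division/delamination table (`event_id`, `type`, `time_h`,
#'     `x_um`, `y_um`, `cell_id`, `daughter1`, `daughter2`, `cause_event_id`),
#'   * `positions`: per-frame jittered cell positions,
#'   * `config`.
#' @export
simulate_basal_dynamics <- function(config, seed_delamination = NULL) {
  stopifnot(inherits(config, "tissue_sim_config"))
  if (!all(is.finite(c(config$delam_rate, config$div_rate))))
    stop("rates must be finite")
  seeds <- derive_seeds(config$seed)
  with_seed(seeds[["tissue"]], simulate_basal_dynamics_impl(config, seed_delamination))
}

simulate_basal_dynamics_impl <- function(config, seed_delamination) {
  fs <- config$field_size
  t_obs <- config$frame_interval * (config$n_frames - 1L)
  t_end <- t_obs + config$burn_in_h  # simulate the warm-up before time zero
  n0 <- round(config$init_density * prod(fs) / 100)
  if (n0 < 1) stop("zero initial cells: increase field_size or init_density")

  r_d <- config$delam_rate / 24   # per cell per hour
  r_b <- config$div_rate / 24

  n_max <- as.integer(n0 * (2 + 3 * (config$delam_rate + config$div_rate) *
                              t_end / 24) + 64L)
  x <- y <- birth <- end_t <- rep(NA_real_, n_max)
  parent <- rep(NA_integer_, n_max)
  fate <- rep(NA_character_, n_max)
  alive <- rep(FALSE, n_max)
  committed <- rep(FALSE, n_max)  # scheduled for a triggered division
  # hard-core (sequential-inhibition) seeding: epithelial cells exclude each
  # other at about one cell radius, unlike a clumpy uniform Poisson draw
  init <- place_hardcore(n0, fs, min_sep = config$cell_radius)
  x[1:n0] <- init[, 1]; y[1:n0] <- init[, 2]
  birth[1:n0] <- 0; alive[1:n0] <- TRUE
  n_cells <- n0

  ev_id <- ev_type <- ev_cell <- ev_cause <- ev_d1 <- ev_d2 <- integer(0)
  ev_time <- ev_x <- ev_y <- numeric(0)
  ev_type <- character(0)
  n_ev <- 0L
  reporter_on <- rep(NA_real_, n_max)

  # queue of scheduled (triggered) divisions
  q_cell <- integer(0); q_time <- numeric(0); q_cause <- integer(0)

  forced <- seed_delamination
  record_event <- function(type, time, cx, cy, cell, d1, d2, cause) {
    n_ev <<- n_ev + 1L
    ev_id[n_ev] <<- n_ev; ev_type[n_ev] <<- type; ev_time[n_ev] <<- time
    ev_x[n_ev] <<- cx; ev_y[n_ev] <<- cy; ev_cell[n_ev] <<- cell
    ev_d1[n_ev] <<- d1; ev_d2[n_ev] <<- d2; ev_cause[n_ev] <<- cause
    n_ev
  }

  do_delaminate <- function(c_id, time) {
    record_event("delamination", time, x[c_id], y[c_id], c_id,
                 NA_integer_, NA_integer_, NA_integer_)
  }

  # pick one uncommitted neighbour of event eid within trigger_radius and
  # schedule its division; committed cells are protected from other fates so
  # that the compensation reliably fires
  schedule_trigger <- function(eid, time) {
    idx <- which(alive[seq_len(n_cells)] & !committed[seq_len(n_cells)])
    if (!length(idx)) return(invisible(NULL))
    d2c <- (x[idx] - ev_x[eid])^2 + (y[idx] - ev_y[eid])^2
    nb <- idx[d2c <= config$trigger_radius^2]
    if (!length(nb)) return(invisible(NULL))
    tgt <- if (length(nb) == 1L) nb else sample(nb, 1L)
    committed[tgt] <<- TRUE
    q_cell <<- c(q_cell, tgt)
    q_time <<- c(q_time, time + runif(1, config$trigger_delay[1],
                                      config$trigger_delay[2]))
    q_cause <<- c(q_cause, eid)
    invisible(NULL)
  }

  t <- 0
  repeat {
    elig <- alive[seq_len(n_cells)] & !committed[seq_len(n_cells)]
    n_elig <- sum(elig)
    if (n_elig == 0L && !length(q_time) && is.null(forced)) break
    t_delam <- if (r_d > 0 && n_elig > 0) t + rexp(1, n_elig * r_d) else Inf
    t_bgdiv <- if (r_b > 0 && n_elig > 0) t + rexp(1, n_elig * r_b) else Inf
    t_sched <- if (length(q_time)) min(q_time) else Inf
    t_forced <- if (!is.null(forced)) forced$time + config$burn_in_h else Inf
    t_next <- min(t_delam, t_bgdiv, t_sched, t_forced)
    if (t_next > t_end) break
    t <- t_next

    if (t_next == t_forced) {
      c_id <- forced$cell_id
      forced <- NULL
      if (!alive[c_id]) next
      eid <- do_delaminate(c_id, t)
      fate[c_id] <- "delaminate"; end_t[c_id] <- t; alive[c_id] <- FALSE
      lead <- max(1, rnorm(1, config$reporter_lead[1], config$reporter_lead[2]))
      reporter_on[c_id] <- max(birth[c_id], t - lead)
      if (runif(1) < config$coupling_prob) schedule_trigger(eid, t)
    } else if (t_next == t_sched || t_next == t_bgdiv) {
      if (t_next == t_sched) {
        k <- which.min(q_time)
        c_id <- q_cell[k]; cause <- q_cause[k]
        q_cell <- q_cell[-k]; q_time <- q_time[-k]; q_cause <- q_cause[-k]
        if (!alive[c_id]) next   # safety: should not happen (committed)
      } else {
        idx <- which(elig)
        if (!length(idx)) next
        c_id <- if (length(idx) == 1L) idx else sample(idx, 1L)
        cause <- NA_integer_
      }
      # divide: two daughters at +/- half a cell radius along a random
      # in-plane axis (mitosis parallel to the basement membrane)
      theta <- runif(1, 0, 2 * pi)
      off <- config$cell_radius / 2
      dx <- cos(theta) * off; dy <- sin(theta) * off
      d1 <- n_cells + 1L; d2 <- n_cells + 2L
      if (d2 > n_max) stop("internal: cell buffer exhausted")
      x[d1] <- min(max(x[c_id] + dx, 0), fs[1]); y[d1] <- min(max(y[c_id] + dy, 0), fs[2])
      x[d2] <- min(max(x[c_id] - dx, 0), fs[1]); y[d2] <- min(max(y[c_id] - dy, 0), fs[2])
      birth[c(d1, d2)] <- t; parent[c(d1, d2)] <- c_id; alive[c(d1, d2)] <- TRUE
      n_cells <- n_cells + 2L
      record_event("division", t, x[c_id], y[c_id], c_id, d1, d2, cause)
      fate[c_id] <- "divide"; end_t[c_id] <- t
      alive[c_id] <- FALSE; committed[c_id] <- FALSE
    } else {
      # background delamination (uncommitted cells only)
      idx <- which(elig)
      if (!length(idx)) next
      c_id <- if (length(idx) == 1L) idx else sample(idx, 1L)
      eid <- do_delaminate(c_id, t)
      fate[c_id] <- "delaminate"; end_t[c_id] <- t; alive[c_id] <- FALSE
      lead <- max(1, rnorm(1, config$reporter_lead[1], config$reporter_lead[2]))
      reporter_on[c_id] <- max(birth[c_id], t - lead)
      if (runif(1) < config$coupling_prob) schedule_trigger(eid, t)
    }
  }

  live <- alive[seq_len(n_cells)]
  fate[seq_len(n_cells)][live] <- "censored"
  end_t[seq_len(n_cells)][live] <- t_end

  # shift times so the observation window starts at 0 (warm-up is negative)
  if (config$burn_in_h > 0) {
    birth <- birth - config$burn_in_h
    end_t <- end_t - config$burn_in_h
    reporter_on <- reporter_on - config$burn_in_h
    ev_time <- ev_time - config$burn_in_h
  }

  ii <- seq_len(n_cells)
  cells <- data.frame(cell_id = ii, parent_id = parent[ii],
                      birth_time = birth[ii], end_time = end_t[ii],
                      end_fate = fate[ii], x0 = x[ii], y0 = y[ii],
                      reporter_on_time = reporter_on[ii])
  events <- data.frame(event_id = ev_id[seq_len(n_ev)],
                       type = ev_type[seq_len(n_ev)],
                       time_h = ev_time[seq_len(n_ev)],
                       x_um = ev_x[seq_len(n_ev)], y_um = ev_y[seq_len(n_ev)],
                       cell_id = ev_cell[seq_len(n_ev)],
                       daughter1 = ev_d1[seq_len(n_ev)],
                       daughter2 = ev_d2[seq_len(n_ev)],
                       cause_event_id = ev_cause[seq_len(n_ev)])

  positions <- make_frame_positions(cells, config)
  structure(list(cells = cells, events = events, positions = positions,
                 config = config), class = "basal_sim")
}

# random sequential adsorption: n points with pairwise separation >= min_sep
# (falls back to unconstrained draws if the field saturates)
place_hardcore <- function(n, fs, min_sep) {
  px <- numeric(n); py <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 200L * n
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cx <- runif(1, 0, fs[1]); cy <- runif(1, 0, fs[2])
    if (placed == 0L ||
        min((px[seq_len(placed)] - cx)^2 + (py[seq_len(placed)] - cy)^2) >=
        min_sep^2) {
      placed <- placed + 1L
      px[placed] <- cx; py[placed] <- cy
    }
  }
  while (placed < n) {  # saturated: fill the remainder unconstrained
    placed <- placed + 1L
    px[placed] <- runif(1, 0, fs[1]); py[placed] <- runif(1, 0, fs[2])
  }
  cbind(px, py)
}

# per-frame jittered positions for cells alive at each frame time
make_frame_positions <- function(cells, config) {
  times <- seq(0, by = config$frame_interval, length.out = config$n_frames)
  out <- vector("list", length(times))
  for (f in seq_along(times)) {
    tt <- times[f]
    sel <- cells$birth_time <= tt & cells$end_time >= tt
    n <- sum(sel)
    if (!n) next
    out[[f]] <- data.frame(cell_id = cells$cell_id[sel], frame = f, time_h = tt,
                           x = pmin(pmax(cells$x0[sel] + rnorm(n, 0, config$jitter_sd), 0),
                                    config$field_size[1]),
                           y = pmin(pmax(cells$y0[sel] + rnorm(n, 0, config$jitter_sd), 0),
                                    config$field_size[2]))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Cell count over time
#'
#' Exact bookkeeping series: `count(t) = count(0) + divisions(<= t) -
#' delaminations(<= t)`.
#'
#' @param sim A `basal_sim`.
#' @param times Numeric vector of times (hours).
#' @return Integer vector of live-cell counts at `times`.
#' @export
cell_count_series <- function(sim, times) {
  stopifnot(inherits(sim, "basal_sim"))
  vapply(times, function(tt)
    sum(sim$cells$birth_time <= tt & sim$cells$end_time > tt |
          (sim$cells$birth_time <= tt & sim$cells$end_fate == "censored")),
    integer(1))
}

#' Resolved daughter-fate statistics
#'
#' Among daughter cells whose next fate (division or delamination) resolved
#' within `window_h` hours of birth, tallies the percentage delaminating
#' versus dividing. Under homeostasis (balanced gain and loss) the branching
#' process forces mean offspring one, hence approximately 50/50.
#'
#' Only daughters born in the observation window with a full `window_h` of
#' follow-up (`0 <= birth` and `birth + window_h` within the simulated span)
#' enter the tally, so late births do not bias it toward fast-resolving
#' fates.
#'
#' @param sim A `basal_sim`.
#' @param window_h Resolution window after birth, hours (default 120 = 5 days).
#' @return List with `n_daughters`, `n_resolved`, `pct_delaminated`,
#'   `pct_divided`.
#' @export
daughter_fate_stats <- function(sim, window_h = 120) {
  stopifnot(inherits(sim, "basal_sim"))
  t_obs <- sim$config$frame_interval * (sim$config$n_frames - 1L)
  d <- sim$cells[!is.na(sim$cells$parent_id) &
                   sim$cells$birth_time >= 0 &
                   sim$cells$birth_time + window_h <= t_obs, , drop = FALSE]
  res <- d[d$end_fate %in% c("divide", "delaminate") &
             (d$end_time - d$birth_time) <= window_h, , drop = FALSE]
  n_res <- nrow(res)
  pct_del <- if (n_res) 100 * mean(res$end_fate == "delaminate") else NA_real_
  list(n_daughters = nrow(d), n_resolved = n_res,
       pct_delaminated = pct_del,
       pct_divided = if (n_res) 100 - pct_del else NA_real_)
}
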