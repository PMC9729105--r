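# Synthetic 3D multichannel timelapse rendering of a curved basal layer.

#' Configuration for the synthetic timelapse renderer
#'
#' Describes the imaging world: a curved epidermis-dermis interface
#' `h*(x, y)`, nuclei as 3D Gaussian blobs resting just above the interface,
#' a membrane channel with ridges between neighbouring cells, an ECM slab
#' below the interface, inter-frame drift, and a nuclear reporter channel
#' whose intensity depends on each cell's reporter state.
#'
#' @param pixel_size_um Pixel size in xy, um.
#' @param z_step_um Slice spacing, um. z index 1 is the tissue surface and
#'   increases with depth.
#' @param n_z Number of z slices.
#' @param surface_base_um Mean interface depth, um.
#' @param surface_amp_um Amplitude of the sinusoidal curvature, um (0 = flat).
#' @param surface_period_um Spatial period of the curvature, um.
#' @param nucleus_sigma_um Length-2 `c(xy, z)` Gaussian blob s.d., um.
#' @param nucleus_depth_um How far nuclear centres sit above the interface, um.
#' @param ecm_thickness_um Thickness of the ECM slab below the interface, um.
#' @param drift Either `NULL` (random-walk drift, s.d. `drift_sd_um` per
#'   frame, frame 1 fixed at (0, 0)) or an `n_frames x 2` matrix of
#'   per-frame shifts in um.
#' @param drift_sd_um Random-walk drift step s.d., um.
#' @param noise_sd Additive Gaussian noise s.d. (intensities are in \[0, 1\]
#'   units before noise).
#' @param reporter_high,reporter_low Nuclear reporter intensities for cells
#'   with the reporter on versus off.
#' @param seed Integer seed for the imaging substream.
#' @return Object of class `image_sim_config`.
#' @export
image_sim_config <- function(pixel_size_um = 1, z_step_um = 1, n_z = 16,
                             surface_base_um = 5, surface_amp_um = 1.5,
                             surface_period_um = 80,
                             nucleus_sigma_um = c(1.8, 1.2),
                             nucleus_depth_um = 0, ecm_thickness_um = 3,
                             drift = NULL, drift_sd_um = 1.5,
                             noise_sd = 0.02,
                             reporter_high = 1, reporter_low = 0.15,
                             seed = 1L) {
  stop_if_not_positive(c(pixel_size_um, z_step_um, n_z), "image geometry")
  structure(as.list(environment()), class = "image_sim_config")
}

#' Create an image stack container
#'
#' @param channels Named list of 3D arrays indexed `[y, x, z]` (z increases
#'   with tissue depth).
#' @param voxel_size_um Length-3 `c(x, y, z)` voxel size in um.
#' @param frame_time_h Acquisition time of the frame, hours.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size_um, frame_time_h = 0) {
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, length, integer(1)) == 3L))
    stop("each channel must be a 3D array [y, x, z]")
  if (length(unique(lapply(dims, identity))) != 1L) stop("channel shapes differ")
  if (any(vapply(channels, function(a) any(a < 0), logical(1))))
    stop("intensities must be non-negative")
  structure(list(channels = channels, voxel_size_um = as.numeric(voxel_size_um),
                 frame_time_h = frame_time_h, dim = dims[[1]]),
            class = "image_stack")
}

#' Render a synthetic multichannel timelapse from simulated tracks
#'
#' @param sim A `basal_sim` from [simulate_basal_dynamics()].
#' @param cfg An [image_sim_config()].
#' @param frames Integer vector of frames to render (default all).
#' @return List with `stacks` (list of [image_stack()]) and `truth`, a list
#'   holding per frame the rendered nuclei centres (image coordinates, um),
#'   the interface height map in z-index units, the applied drift, and the
#'   per-cell reporter class.
#' @export
synthesize_timelapse <- function(sim, cfg = image_sim_config(), frames = NULL) {
  stopifnot(inherits(sim, "basal_sim"), inherits(cfg, "image_sim_config"))
  if (is.null(sim$positions) || !nrow(sim$positions)) stop("tracks are empty")
  seeds <- derive_seeds(cfg$seed)
  with_seed(seeds[["imaging"]], synthesize_timelapse_impl(sim, cfg, frames))
}

synthesize_timelapse_impl <- function(sim, cfg, frames) {
  fs <- sim$config$field_size
  nx <- ceiling(fs[1] / cfg$pixel_size_um)
  ny <- ceiling(fs[2] / cfg$pixel_size_um)
  if (min(nx, ny) * cfg$pixel_size_um < 6 * cfg$nucleus_sigma_um[1])
    stop("field too small for the nucleus blob size")
  if (is.null(frames)) frames <- sort(unique(sim$positions$frame))
  nf <- length(frames)

  drift <- cfg$drift
  if (is.null(drift)) {
    step <- matrix(rnorm(2 * nf, 0, cfg$drift_sd_um), ncol = 2)
    step[1, ] <- 0
    drift <- apply(step, 2, cumsum)
    if (nf == 1L) drift <- matrix(drift, ncol = 2)
  } else {
    drift <- as.matrix(drift)[seq_len(nf), , drop = FALSE]
  }

  # pixel-centre coordinate grids (um); origin at pixel (1,1) = (0,0) um
  xs <- (seq_len(nx) - 1) * cfg$pixel_size_um
  ys <- (seq_len(ny) - 1) * cfg$pixel_size_um
  surf <- function(px, py)  # interface depth in um
    cfg$surface_base_um + cfg$surface_amp_um *
      sin(2 * pi * px / cfg$surface_period_um) *
      sin(2 * pi * py / cfg$surface_period_um)

  stacks <- vector("list", nf)
  truth_frames <- vector("list", nf)

  for (fi in seq_len(nf)) {
    f <- frames[fi]
    pos <- sim$positions[sim$positions$frame == f, , drop = FALSE]
    tt <- pos$time_h[1]
    cx <- pos$x + drift[fi, 1]
    cy <- pos$y + drift[fi, 2]
    # cells ride on the tissue surface at their tissue coordinates
    hz_um <- surf(pos$x, pos$y)
    cz_um <- pmax(0, hz_um - cfg$nucleus_depth_um)

    on_now <- !is.na(sim$cells$reporter_on_time[pos$cell_id]) &
      sim$cells$reporter_on_time[pos$cell_id] <= tt
    rep_class <- ifelse(on_now, "high", "low")

    # drift shifts tissue content relative to the fixed camera frame: the
    # imaged surface at pixel (x, y) is the tissue surface at (x - dx, y - dy)
    hmap_um <- outer(ys, xs, function(py, px)
      surf(px - drift[fi, 1], py - drift[fi, 2]))
    hmap_z <- hmap_um / cfg$z_step_um + 1  # 1-based z index of the interface

    nz <- cfg$n_z
    nuc <- array(0, dim = c(ny, nx, nz))
    rep_ch <- array(0, dim = c(ny, nx, nz))
    sxy <- cfg$nucleus_sigma_um[1]; sz <- cfg$nucleus_sigma_um[2]
    rwin <- ceiling(3 * sxy / cfg$pixel_size_um)
    for (i in seq_along(cx)) {
      icx <- round(cx[i] / cfg$pixel_size_um) + 1
      icy <- round(cy[i] / cfg$pixel_size_um) + 1
      xr <- max(1, icx - rwin):min(nx, icx + rwin)
      yr <- max(1, icy - rwin):min(ny, icy + rwin)
      if (!length(xr) || !length(yr)) next
      gx <- exp(-((xs[xr] - cx[i])^2) / (2 * sxy^2))
      gy <- exp(-((ys[yr] - cy[i])^2) / (2 * sxy^2))
      zc <- (seq_len(nz) - 1) * cfg$z_step_um
      gz <- exp(-((zc - cz_um[i])^2) / (2 * sz^2))
      blob <- outer(gy, gx)
      for (z in which(gz > 1e-3)) {
        nuc[yr, xr, z] <- nuc[yr, xr, z] + blob * gz[z]
        amp <- if (rep_class[i] == "high") cfg$reporter_high else cfg$reporter_low
        rep_ch[yr, xr, z] <- rep_ch[yr, xr, z] + amp * blob * gz[z]
      }
    }

    # membrane: ridges along boundaries between neighbouring cells, painted
    # in the z band occupied by the basal cell bodies
    mem <- array(0, dim = c(ny, nx, nz))
    if (length(cx) >= 2) {
      grid <- cbind(rep(xs, each = ny), rep(ys, nx))
      kn <- FNN::get.knnx(cbind(cx, cy), grid, k = 2)
      ridge <- exp(-((kn$nn.dist[, 2] - kn$nn.dist[, 1])^2) / (2 * 1.0^2))
      ridge <- matrix(ridge, nrow = ny)
      zc <- (seq_len(nz) - 1) * cfg$z_step_um
      for (z in seq_len(nz)) {
        band <- exp(-((zc[z] - (mean(hmap_um) - cfg$nucleus_depth_um))^2) /
                      (2 * (2 * sz)^2))
        if (band > 1e-3) mem[, , z] <- ridge * band
      }
    }

    # ECM: slab just below the interface, partial-volume rendered so the
    # interface has a sub-slice position
    ecm <- array(0, dim = c(ny, nx, nz))
    zc <- (seq_len(nz) - 1) * cfg$z_step_um
    half <- cfg$z_step_um / 2
    for (z in seq_len(nz)) {
      cover <- pmin(zc[z] + half, hmap_um + cfg$ecm_thickness_um) -
        pmax(zc[z] - half, hmap_um)
      ecm[, , z] <- pmin(pmax(cover / cfg$z_step_um, 0), 1)
    }

    chans <- list(nuclei = nuc, reporter = rep_ch, membrane = mem, ecm = ecm)
    if (cfg$noise_sd > 0)
      chans <- lapply(chans, function(a)
        pmax(a + array(rnorm(length(a), 0, cfg$noise_sd), dim = dim(a)), 0))

    stacks[[fi]] <- image_stack(chans,
                                voxel_size_um = c(cfg$pixel_size_um,
                                                  cfg$pixel_size_um,
                                                  cfg$z_step_um),
                                frame_time_h = tt)
    truth_frames[[fi]] <- list(
      centres = data.frame(cell_id = pos$cell_id, x_um = cx, y_um = cy,
                           z_um = cz_um, reporter_class = rep_class),
      hmap_z = hmap_z,
      drift_um = drift[fi, ])
  }

  list(stacks = stacks,
       truth = list(frames = truth_frames, drift_um = drift,
                    frame_ids = frames))
}
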