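# Basal-layer extraction from 3D stacks: height correction, projection,
# cell detection, drift registration and reporter quantification.

# separable 2D Gaussian blur with edge renormalization
gaussian_blur_2d <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  blur_1d <- function(m, along_rows) {
    if (along_rows) m <- t(m)
    n <- nrow(m)
    acc <- matrix(0, nrow(m), ncol(m))
    wsum <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      acc[ok, ] <- acc[ok, ] + k[j] * m[src[ok], ]
      wsum[ok, ] <- wsum[ok, ] + k[j]
    }
    out <- acc / wsum
    if (along_rows) t(out) else out
  }
  blur_1d(blur_1d(mat, FALSE), TRUE)
}

# Otsu threshold on a 256-bin histogram
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(255L, as.integer((x - rng[1]) / diff(rng) * 256)) + 1L, 256L)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(256) - 0.5) / 256 * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

#' Height map of the epidermis-dermis interface
#'
#' Gaussian-blurs the named channel slice-wise in the xy plane (default width
#' 6 um, interpreted as the Gaussian sigma), builds a 3D mask by Otsu
#' thresholding the blurred signal, and records per xy column the first
#' (shallowest) masked z index as the interface height. Columns with no masked
#' voxel are filled by nearest-neighbour interpolation.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name carrying the interface signal (ECM or nuclei).
#' @param blur_sigma_um Gaussian sigma of the xy blur, um.
#' @return Object of class `height_map`: list with `h` (matrix \[y, x\] of
#'   1-based z indices, float) and `voxel_size_um`.
#' @export
compute_height_map <- function(stack, channel, blur_sigma_um = 6) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels))
    stop(sprintf("channel '%s' not found", channel))
  a <- stack$channels[[channel]]
  if (all(a == 0)) stop("no interface signal: channel is empty")
  sigma_px <- blur_sigma_um / stack$voxel_size_um[1]
  nz <- dim(a)[3]
  bl <- array(0, dim = dim(a))
  for (z in seq_len(nz)) bl[, , z] <- gaussian_blur_2d(a[, , z], sigma_px)
  thr <- otsu_threshold(as.vector(bl))
  mask <- bl > thr
  if (!any(mask)) stop("no interface signal: empty mask after thresholding")

  # first masked z per column, refined to the half-rise of the local edge
  # (the mask threshold fixes the slice; the half-maximum fixes the
  # sub-slice position of the interface)
  d12 <- dim(a)[1:2]
  first_z <- matrix(NA_real_, d12[1], d12[2])
  for (yy in seq_len(d12[1])) for (xx in seq_len(d12[2])) {
    v <- bl[yy, xx, ]
    w <- which(v > thr)
    if (!length(w)) next
    z <- w[1]
    if (z == 1L) { first_z[yy, xx] <- 1; next }
    v_lo <- min(v[max(z - 3, 1):(z - 1)])
    v_hi <- max(v[z:min(z + 3, nz)])
    mid <- (v_lo + v_hi) / 2
    h_est <- z  # fallback: the first masked slice
    for (zz in max(z - 3, 1):min(z + 2, nz - 1)) {
      if (v[zz] <= mid && v[zz + 1] > mid) {
        h_est <- zz + (mid - v[zz]) / (v[zz + 1] - v[zz])
        break
      }
    }
    first_z[yy, xx] <- h_est
  }
  if (anyNA(first_z)) {
    idx_na <- which(is.na(first_z), arr.ind = TRUE)
    idx_ok <- which(!is.na(first_z), arr.ind = TRUE)
    nn <- FNN::get.knnx(idx_ok, idx_na, k = 1)$nn.index
    first_z[idx_na] <- first_z[idx_ok[nn, , drop = FALSE]]
  }
  structure(list(h = first_z, voxel_size_um = stack$voxel_size_um),
            class = "height_map")
}

#' Flatten a stack so the interface is level
#'
#' Subtracts the interface height per xy column (linear interpolation in z):
#' after correction the interface lies at the first z slice everywhere,
#' levelling the basal layer.
#'
#' @param stack An [image_stack()].
#' @param hmap A `height_map` with matching xy shape.
#' @return A height-corrected [image_stack()].
#' @export
flatten_stack <- function(stack, hmap) {
  stopifnot(inherits(stack, "image_stack"), inherits(hmap, "height_map"))
  d <- stack$dim
  if (!all(dim(hmap$h) == d[1:2])) stop("shape mismatch between stack and height map")
  nz <- d[3]
  shift <- hmap$h - 1  # interface z index -> 0 shift keeps data in place
  lo <- floor(shift); frac <- shift - lo
  npix <- d[1] * d[2]
  rows <- rep(seq_len(d[1]), d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  out_ch <- lapply(stack$channels, function(a) {
    out <- array(0, dim = d)
    for (z in seq_len(nz)) {
      z0 <- z + as.vector(lo)
      z1 <- z0 + 1L
      v0 <- ifelse(z0 >= 1 & z0 <= nz, a[cbind(rows, cols, pmin(pmax(z0, 1), nz))], 0)
      v1 <- ifelse(z1 >= 1 & z1 <= nz, a[cbind(rows, cols, pmin(pmax(z1, 1), nz))], 0)
      out[, , z] <- matrix(v0 * (1 - as.vector(frac)) + v1 * as.vector(frac), d[1], d[2])
    }
    out
  })
  image_stack(out_ch, stack$voxel_size_um, stack$frame_time_h)
}

#' Average a few consecutive z slices into a 2D basal-plane image
#'
#' @param stack An [image_stack()] (typically height-corrected).
#' @param z_start First slice (1-based).
#' @param n_slices Number of consecutive slices to average (default 3).
#' @return Object of class `plane_image`: named list of 2D matrices plus
#'   `pixel_size_um`.
#' @export
project_basal <- function(stack, z_start, n_slices = 3) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- stack$dim[3]
  if (z_start < 1 || z_start + n_slices - 1 > nz)
    stop(sprintf("z range [%d, %d] out of stack range [1, %d]",
                 z_start, z_start + n_slices - 1, nz))
  zr <- z_start:(z_start + n_slices - 1)
  chans <- lapply(stack$channels, function(a) {
    m <- a[, , zr[1]]
    for (z in zr[-1]) m <- m + a[, , z]
    m / length(zr)
  })
  structure(list(channels = chans, pixel_size_um = stack$voxel_size_um[1]),
            class = "plane_image")
}

#' Detect cell positions as local extrema of a plane image
#'
#' Lightly smooths the image, finds strict local maxima (nuclei) or minima
#' (membrane vertices) over the 8-neighbourhood, and greedily prunes
#' detections closer than `min_separation_um`, keeping the higher-prominence
#' extremum.
#'
#' @param plane A `plane_image` or a 2D matrix.
#' @param channel Channel name when `plane` is a `plane_image`.
#' @param mode `"maxima"` or `"minima"`.
#' @param min_separation_um Minimum pairwise separation, um.
#' @param smooth_sigma_um Pre-smoothing Gaussian sigma, um.
#' @param min_intensity_frac Peaks weaker than this fraction of the dynamic
#'   range of the smoothed image (above its minimum) are discarded as noise.
#' @param pixel_size_um Pixel size when `plane` is a bare matrix.
#' @return `data.frame(x_um, y_um, value)`; zero rows on featureless input.
#' @export
detect_cells <- function(plane, channel = NULL, mode = c("maxima", "minima"),
                         min_separation_um = 4, smooth_sigma_um = 1,
                         min_intensity_frac = 0.3, pixel_size_um = 1) {
  mode <- match.arg(mode)
  if (inherits(plane, "plane_image")) {
    pixel_size_um <- plane$pixel_size_um
    m <- plane$channels[[channel %||% names(plane$channels)[1]]]
  } else m <- plane
  if (!length(m)) stop("empty plane")
  if (mode == "minima") m <- -m
  ms <- gaussian_blur_2d(m, smooth_sigma_um / pixel_size_um)
  ny <- nrow(ms); nx <- ncol(ms)
  if (ny < 3 || nx < 3) return(data.frame(x_um = numeric(0), y_um = numeric(0),
                                          value = numeric(0)))
  core <- ms[2:(ny - 1), 2:(nx - 1)]
  is_peak <- core > ms[1:(ny - 2), 2:(nx - 1)] & core > ms[3:ny, 2:(nx - 1)] &
    core > ms[2:(ny - 1), 1:(nx - 2)] & core > ms[2:(ny - 1), 3:nx] &
    core > ms[1:(ny - 2), 1:(nx - 2)] & core > ms[1:(ny - 2), 3:nx] &
    core > ms[3:ny, 1:(nx - 2)] & core > ms[3:ny, 3:nx]
  idx <- which(is_peak, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(x_um = numeric(0), y_um = numeric(0),
                                    value = numeric(0)))
  py <- idx[, 1] + 1L; px <- idx[, 2] + 1L
  val <- ms[cbind(py, px)]
  floor_v <- min(ms) + min_intensity_frac * (max(ms) - min(ms))
  keep0 <- val >= floor_v
  px <- px[keep0]; py <- py[keep0]; val <- val[keep0]
  if (!length(val)) return(data.frame(x_um = numeric(0), y_um = numeric(0),
                                      value = numeric(0)))
  ord <- order(val, decreasing = TRUE)
  px <- px[ord]; py <- py[ord]; val <- val[ord]
  keep <- logical(length(val))
  min_sep_px2 <- (min_separation_um / pixel_size_um)^2
  for (i in seq_along(val)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kk <- which(keep)
    if (all((px[kk] - px[i])^2 + (py[kk] - py[i])^2 >= min_sep_px2)) keep[i] <- TRUE
  }
  px <- px[keep]; py <- py[keep]; val <- val[keep]
  # subpixel refinement: 1D parabolic fit through the peak and its neighbours
  sub_off <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (den >= 0) return(0)
    min(max(0.5 * (vm - vp) / den, -0.5), 0.5)
  }
  ox <- oy <- numeric(length(val))
  for (i in seq_along(val)) {
    if (px[i] > 1 && px[i] < nx)
      ox[i] <- sub_off(ms[py[i], px[i] - 1], ms[py[i], px[i]], ms[py[i], px[i] + 1])
    if (py[i] > 1 && py[i] < ny)
      oy[i] <- sub_off(ms[py[i] - 1, px[i]], ms[py[i], px[i]], ms[py[i] + 1, px[i]])
  }
  data.frame(x_um = (px + ox - 1) * pixel_size_um,
             y_um = (py + oy - 1) * pixel_size_um,
             value = if (mode == "minima") -val else val)
}

#' Register two frames by translation
#'
#' Finds the 2D shift `s` minimizing the mean squared distance between each
#' moving-frame cell position (shifted back by `s`) and its nearest
#' reference-frame position: a coarse 1-um grid search over the search radius
#' followed by Nelder-Mead refinement. When `mov` equals `ref` shifted by
#' `s_true`, the estimate recovers `s_true`. Ties on the coarse grid break
#' toward the smaller shift norm.
#'
#' @param ref,mov Two-column matrices or data frames of positions (um); data
#'   frames may use columns `x_um`/`y_um`.
#' @param search_radius_um Half-width of the coarse search grid, um.
#' @return Numeric length-2 shift `c(dx, dy)` in um.
#' @export
register_frames <- function(ref, mov, search_radius_um = 10) {
  as_xy <- function(p) {
    if (is.data.frame(p)) {
      if (all(c("x_um", "y_um") %in% names(p))) return(cbind(p$x_um, p$y_um))
      return(as.matrix(p[, 1:2]))
    }
    as.matrix(p)[, 1:2, drop = FALSE]
  }
  ref <- as_xy(ref); mov <- as_xy(mov)
  if (!nrow(ref) || !nrow(mov)) stop("empty position set")
  cost <- function(s) {
    d <- FNN::get.knnx(ref, cbind(mov[, 1] - s[1], mov[, 2] - s[2]), k = 1)$nn.dist
    mean(d^2)
  }
  g <- seq(-search_radius_um, search_radius_um, by = 1)
  grid <- expand.grid(dx = g, dy = g)
  cc <- apply(grid, 1, cost)
  best <- which(cc <= min(cc) + 1e-12)
  if (length(best) > 1L)
    best <- best[which.min(grid$dx[best]^2 + grid$dy[best]^2)]
  s <- as.numeric(grid[best, ])
  # local refinement: trimmed iterative closest point. Cells present in only
  # one frame otherwise drag the nearest-neighbour cost off the optimum.
  for (it in 1:8) {
    nn <- FNN::get.knnx(ref, cbind(mov[, 1] - s[1], mov[, 2] - s[2]), k = 1)
    d <- nn$nn.dist[, 1]
    keep <- d <= max(2, 2 * stats::median(d))
    if (sum(keep) < 3) break
    delta <- c(mean(mov[keep, 1] - ref[nn$nn.index[keep, 1], 1]),
               mean(mov[keep, 2] - ref[nn$nn.index[keep, 1], 2]))
    if (max(abs(delta - s)) < 1e-6) { s <- delta; break }
    s <- delta
  }
  s
}

#' Quantify nuclear reporter intensity per cell
#'
#' `disc_mean`: mean intensity within a disc of `radius_um` around each
#' position, averaging in-bounds pixels only. `segment_sum`: sum of intensity
#' over the segmented region (from `labels`) containing each position.
#'
#' @param plane A `plane_image` or 2D matrix.
#' @param positions `data.frame(x_um, y_um)`, optionally with `cell_id`.
#' @param channel Channel name for `plane_image` input.
#' @param radius_um Disc radius, um (default 3).
#' @param method `"disc_mean"` or `"segment_sum"`.
#' @param labels Integer label matrix (same shape as the plane) for
#'   `segment_sum`.
#' @param pixel_size_um Pixel size for bare-matrix input.
#' @return `data.frame(cell_id, raw)`.
#' @export
quantify_reporter <- function(plane, positions, channel = NULL, radius_um = 3,
                              method = c("disc_mean", "segment_sum"),
                              labels = NULL, pixel_size_um = 1) {
  method <- match.arg(method)
  if (radius_um <= 0) stop("radius_um must be > 0")
  if (inherits(plane, "plane_image")) {
    pixel_size_um <- plane$pixel_size_um
    m <- plane$channels[[channel %||% names(plane$channels)[1]]]
  } else m <- plane
  ny <- nrow(m); nx <- ncol(m)
  ids <- positions$cell_id %||% seq_len(nrow(positions))
  raw <- numeric(nrow(positions))
  if (method == "disc_mean") {
    r_px <- radius_um / pixel_size_um
    for (i in seq_len(nrow(positions))) {
      cxp <- positions$x_um[i] / pixel_size_um + 1
      cyp <- positions$y_um[i] / pixel_size_um + 1
      xr <- max(1, floor(cxp - r_px)):min(nx, ceiling(cxp + r_px))
      yr <- max(1, floor(cyp - r_px)):min(ny, ceiling(cyp + r_px))
      dx2 <- (xr - cxp)^2; dy2 <- (yr - cyp)^2
      disc <- outer(dy2, dx2, `+`) <= r_px^2
      raw[i] <- mean(m[yr, xr, drop = FALSE][disc])
    }
  } else {
    if (is.null(labels)) stop("segment_sum requires a label matrix")
    for (i in seq_len(nrow(positions))) {
      cxp <- min(max(round(positions$x_um[i] / pixel_size_um) + 1, 1), nx)
      cyp <- min(max(round(positions$y_um[i] / pixel_size_um) + 1, 1), ny)
      lab <- labels[cyp, cxp]
      raw[i] <- if (lab == 0) 0 else sum(m[labels == lab])
    }
  }
  data.frame(cell_id = ids, raw = raw)
}

#' Normalize reporter levels by the dividing-cell mean
#'
#' @param levels `data.frame(cell_id, raw)` from [quantify_reporter()].
#' @param dividing_ids Cell ids of dividing cells in the same region.
#' @return Input with a `normalized` column; the normalized mean over the
#'   dividing cells is 1 by construction.
#' @export
normalize_by_dividing <- function(levels, dividing_ids) {
  if (!length(dividing_ids)) stop("no dividing cells supplied")
  sel <- levels$cell_id %in% dividing_ids
  if (!any(sel)) stop("no dividing cells present in `levels`")
  m <- mean(levels$raw[sel])
  if (!is.finite(m) || m == 0) stop("dividing-cell mean is degenerate")
  levels$normalized <- levels$raw / m
  levels
}

#' Flag high-reporter cells
#'
#' @param levels Output of [normalize_by_dividing()].
#' @param threshold Normalized-intensity threshold (strict `>`). The paper's
#'   equivalent threshold was set manually per experiment, so no default.
#' @return Input with logical `is_high` column.
#' @export
classify_high <- function(levels, threshold) {
  stopifnot(is.finite(threshold))
  levels$is_high <- levels$normalized > threshold
  levels
}
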