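# Motion-energy feature space: a fixed bank of quadrature spatiotemporal
# Gabor filters tuned to orientation, spatial frequency, temporal frequency
# and motion direction. Per channel, energy is the sum of squares of the
# two phase-offset outputs, log-transformed and averaged over frames.

#' Convert frames to CIE L* luminance
#'
#' sRGB values are linearized, converted to relative luminance Y (D65
#' primaries) and mapped to CIE L*. Grayscale input is treated as equal
#' RGB. Inputs in [0, 255] are auto-scaled to [0, 1].
#'
#' @param frames T x H x W (grayscale) or T x H x W x 3 (RGB) array.
#' @param normalize If TRUE (default) return L*/100 in [0, 1]; otherwise
#'   L* in [0, 100].
#' @return T x H x W luminance array.
#' @export
to_luminance <- function(frames, normalize = TRUE) {
  nd <- length(dim(frames))
  if (!nd %in% c(3, 4)) stop("frames must be T x H x W (x 3)")
  x <- frames
  if (max(x) > 1 + 1e-9) x <- x / 255
  if (any(x < -1e-9) || any(x > 1 + 1e-9)) stop("pixel values out of range")
  srgb_lin <- function(c) ifelse(c <= 0.04045, c / 12.92,
                                 ((c + 0.055) / 1.055)^2.4)
  Y <- if (nd == 3) {
    srgb_lin(x)
  } else {
    0.2126 * srgb_lin(x[, , , 1]) + 0.7152 * srgb_lin(x[, , , 2]) +
      0.0722 * srgb_lin(x[, , , 3])
  }
  fy <- ifelse(Y > (6 / 29)^3, Y^(1 / 3), Y / (3 * (6 / 29)^2) + 4 / 29)
  L <- 116 * fy - 16
  L <- pmax(L, 0)
  if (normalize) L / 100 else L
}

#' Build a spatiotemporal Gabor filter bank
#'
#' Channels are the cross product of spatial grid positions, orientations,
#' spatial frequencies, temporal frequencies and two opposite motion
#' directions. Each channel has a quadrature (90 degree phase offset) pair
#' of spatial filters and of temporal kernels. Spatial envelopes scale
#' inversely with spatial frequency and the position grid spacing is
#' proportional to the envelope, so low frequencies tile coarsely and high
#' frequencies finely. Spatial filters are DC-corrected (zero mean) and
#' L2-normalized.
#'
#' @param image_h,image_w Frame size in pixels.
#' @param pixels_per_degree Calibration scalar (pixels per degree of
#'   visual angle).
#' @param fps Frames per second of the video.
#' @param orientations Degrees; default c(0, 45, 90, 135).
#' @param spatial_freqs Cycles/degree, log-spaced in [0.5, 8] by default.
#' @param temporal_freqs Hz, in [1, 16] by default.
#' @param sf_env Spatial envelope sigma in degrees = `sf_env` / sf.
#' @param spacing Grid spacing in units of the spatial envelope sigma.
#' @param tf_env Temporal envelope sigma in seconds = `tf_env` / tf.
#' @param allow_out_of_range If FALSE (default), frequencies outside the
#'   stated ranges are rejected.
#' @return Object of class `gabor_bank`; `$channels` is a data.frame with
#'   one row per channel.
#' @export
build_filter_bank <- function(image_h, image_w, pixels_per_degree,
                              fps = 30,
                              orientations = c(0, 45, 90, 135),
                              spatial_freqs = c(0.5, 1, 2, 4, 8),
                              temporal_freqs = c(1, 2, 4, 8, 16),
                              sf_env = 0.56, spacing = 3.5, tf_env = 0.5,
                              allow_out_of_range = FALSE) {
  if (image_h <= 0 || image_w <= 0 || pixels_per_degree <= 0) {
    stop("image size and pixels_per_degree must be positive")
  }
  if (!allow_out_of_range) {
    if (any(spatial_freqs < 0.5 | spatial_freqs > 8)) {
      stop("spatial frequencies outside [0.5, 8] cycles/degree")
    }
    if (any(temporal_freqs < 1 | temporal_freqs > 16)) {
      stop("temporal frequencies outside [1, 16] Hz")
    }
  }
  grid_1d <- function(extent, step, sigma_px) {
    # a single centered position when one envelope covers the frame
    n <- if (2 * sigma_px >= extent) 1L else max(1L, floor(extent / step))
    (seq_len(n) - 0.5) * extent / n
  }
  spatial_units <- list()
  for (sf in spatial_freqs) {
    sigma_px <- sf_env / sf * pixels_per_degree
    step <- max(1, spacing * sigma_px)
    cx <- grid_1d(image_w, step, sigma_px)
    cy <- grid_1d(image_h, step, sigma_px)
    for (ori in orientations) {
      for (x0 in cx) for (y0 in cy) {
        spatial_units[[length(spatial_units) + 1]] <-
          list(x0 = x0, y0 = y0, ori = ori, sf = sf, sigma_px = sigma_px)
      }
    }
  }
  # precompute spatial quadrature pairs on clipped patches
  half_support <- 3
  spatial <- lapply(spatial_units, function(u) {
    r <- ceiling(half_support * u$sigma_px)
    ix <- max(1, round(u$x0) - r):min(image_w, round(u$x0) + r)
    iy <- max(1, round(u$y0) - r):min(image_h, round(u$y0) + r)
    gx <- matrix(rep(ix - 0.5 - u$x0, each = length(iy)), length(iy))
    gy <- matrix(rep(iy - 0.5 - u$y0, times = length(ix)), length(iy))
    th <- u$ori * pi / 180
    uu <- gx * cos(th) + gy * sin(th)
    env <- exp(-(gx^2 + gy^2) / (2 * u$sigma_px^2))
    f_px <- u$sf / pixels_per_degree   # cycles per pixel
    even <- env * cos(2 * pi * f_px * uu)
    odd <- env * sin(2 * pi * f_px * uu)
    # envelope-weighted DC removal keeps the quadrature relation intact
    even <- even - env * (sum(even) / sum(env))
    odd <- odd - env * (sum(odd) / sum(env))
    # common normalization preserves the even/odd amplitude balance
    n <- sqrt((sum(even^2) + sum(odd^2)) / 2)
    list(ix = ix, iy = iy, even = even / n, odd = odd / n, unit = u)
  })
  temporal <- lapply(temporal_freqs, function(tf) {
    sigma_s <- tf_env / tf
    half <- max(2L, ceiling(3 * sigma_s * fps))
    tau <- (-half:half) / fps
    env <- exp(-tau^2 / (2 * sigma_s^2))
    te <- env * cos(2 * pi * tf * tau)
    to <- env * sin(2 * pi * tf * tau)
    te <- te - env * (sum(te) / sum(env))
    to <- to - env * (sum(to) / sum(env))
    n <- sqrt((sum(te^2) + sum(to^2)) / 2)
    list(tf = tf, te = te / n, to = to / n, half = half)
  })
  channels <- do.call(rbind, lapply(seq_along(spatial), function(si) {
    u <- spatial[[si]]$unit
    do.call(rbind, lapply(temporal_freqs, function(tf) {
      data.frame(spatial_idx = si, x0 = u$x0, y0 = u$y0, ori = u$ori,
                 sf = u$sf, tf = tf, direction = c(1, -1))
    }))
  }))
  structure(list(channels = channels, spatial = spatial,
                 temporal = temporal,
                 image_h = image_h, image_w = image_w,
                 pixels_per_degree = pixels_per_degree, fps = fps),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("<gabor_bank> %d channels (%d spatial units x %d TFs x 2 dir), %dx%d px\n",
              nrow(x$channels), length(x$spatial), length(x$temporal),
              x$image_h, x$image_w))
  invisible(x)
}

# temporal "same" convolution with edge replication
.conv_same_replicate <- function(x, k) {
  half <- (length(k) - 1) / 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  stats::filter(xp, rev(k), sides = 2)[(half + 1):(half + length(x))]
}

#' Motion energy of a video under a filter bank
#'
#' Per channel: the frame sequence is projected on the channel's quadrature
#' spatial pair, the two time courses are convolved with the quadrature
#' temporal pair, and opponent combinations give energies for the two
#' motion directions as sums of squared phase-offset outputs. Raw energies
#' are log-transformed (log(x + eps)) and averaged over frames.
#'
#' @param frames T x H x W luminance array in [0, 1].
#' @param bank A `gabor_bank` matching the frame geometry.
#' @param eps_rel eps as a fraction of the video's maximum raw energy,
#'   default 1e-5 (with an absolute floor of 1e-12).
#' @param log_transform If FALSE return frame-averaged raw energies.
#' @return Named numeric vector, one value per bank channel.
#' @export
motion_energy <- function(frames, bank, eps_rel = 1e-5,
                          log_transform = TRUE) {
  d <- dim(frames)
  if (length(d) != 3 || d[2] != bank$image_h || d[3] != bank$image_w) {
    stop("frame geometry does not match the bank")
  }
  if (d[1] < 2) stop("need at least 2 frames")
  nt <- d[1]
  n_sp <- length(bank$spatial)
  n_tf <- length(bank$temporal)
  # raw energy per frame, indexed [frame, spatial, tf, dir]
  E <- array(0, dim = c(nt, n_sp, n_tf, 2))
  for (si in seq_len(n_sp)) {
    sp <- bank$spatial[[si]]
    patch <- frames[, sp$iy, sp$ix, drop = FALSE]
    dim(patch) <- c(nt, length(sp$iy) * length(sp$ix))
    se <- patch %*% as.numeric(sp$even)
    so <- patch %*% as.numeric(sp$odd)
    for (ti in seq_len(n_tf)) {
      te <- bank$temporal[[ti]]$te
      to <- bank$temporal[[ti]]$to
      a_ee <- .conv_same_replicate(se, te)
      a_eo <- .conv_same_replicate(se, to)
      a_oe <- .conv_same_replicate(so, te)
      a_oo <- .conv_same_replicate(so, to)
      # opponent quadrature combinations: dir +1 prefers drift toward the
      # positive spatial-phase axis, dir -1 the opposite
      E[, si, ti, 1] <- (a_ee + a_oo)^2 + (a_eo - a_oe)^2
      E[, si, ti, 2] <- (a_ee - a_oo)^2 + (a_eo + a_oe)^2
    }
  }
  ch <- bank$channels
  raw <- matrix(0, nt, nrow(ch))
  dir_idx <- ifelse(ch$direction == 1, 1, 2)
  tf_idx <- match(ch$tf, vapply(bank$temporal, `[[`, numeric(1), "tf"))
  for (k in seq_len(nrow(ch))) {
    raw[, k] <- E[, ch$spatial_idx[k], tf_idx[k], dir_idx[k]]
  }
  # average over frames whose temporal kernel support lies fully inside the
  # clip; replicated-edge transients would otherwise leak into the mean
  frame_mean <- function(v, half) {
    keep <- if (nt > 2 * half + 2) (half + 1):(nt - half) else seq_len(nt)
    mean(v[keep])
  }
  halves <- vapply(bank$temporal, `[[`, numeric(1), "half")[tf_idx]
  out <- if (log_transform) {
    eps <- max(max(raw) * eps_rel, 1e-12)
    vapply(seq_len(nrow(ch)),
           function(k) frame_mean(log(raw[, k] + eps), halves[k]), numeric(1))
  } else {
    vapply(seq_len(nrow(ch)),
           function(k) frame_mean(raw[, k], halves[k]), numeric(1))
  }
  names(out) <- sprintf("me_p%02d_o%g_sf%g_tf%g_d%+d",
                        ch$spatial_idx, ch$ori, ch$sf, ch$tf, ch$direction)
  out
}

#' Motion-energy feature space for a set of videos
#'
#' @param videos Named list of T x H x W luminance arrays.
#' @param bank A `gabor_bank`.
#' @param ... Passed to [motion_energy()].
#' @return A `feature_space` named "moten".
#' @export
moten_features <- function(videos, bank, ...) {
  X <- t(vapply(videos, motion_energy, bank = bank, ...,
                FUN.VALUE = numeric(nrow(bank$channels))))
  rownames(X) <- names(videos)
  feature_space("moten", X, feature_names = colnames(X),
                stimulus_ids = names(videos))
}
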