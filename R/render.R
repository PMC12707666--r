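# Stick-figure video rendering: orthographic projection of keypoints and
# anti-aliased line segments on a black background. The luminance output is
# the only thing the motion-energy model consumes, so no mesh or shading
# pipeline is needed.

#' Render a stick-figure video from keypoint positions
#'
#' Orthographic projection of the skeleton's bones. The world origin (plus
#' `center_world`) maps to the image center so the figure stays centered
#' relative to a fixation point, and translations of the keypoints move the
#' figure proportionally in pixels.
#'
#' @param keypoints frames x joints x 3 array of world positions (meters).
#' @param bones Two-column matrix of joint index pairs to connect (e.g.
#'   `skeleton_bones(skel)`).
#' @param image_h,image_w Image size in pixels; default 128 x 64 emulating
#'   a tall stimulus aspect.
#' @param view "front" (x right, y up) or "side" (z right, y up).
#' @param pixels_per_meter Projection scale; default fits a ~2.2 m figure
#'   into the image height.
#' @param center_world Length-3 world point mapped to the image center.
#' @param line_width Stroke half-width in pixels; anti-aliasing ramps
#'   luminance linearly over one pixel beyond it.
#' @return frames x image_h x image_w array of luminance in [0, 1].
#' @export
render_stick_video <- function(keypoints, bones, image_h = 128, image_w = 64,
                               view = c("front", "side"),
                               pixels_per_meter = image_h / 2.2,
                               center_world = c(0, 0, 0),
                               line_width = 0.8) {
  view <- match.arg(view)
  if (image_h < 2 || image_w < 2) stop("degenerate image size")
  stopifnot_finite(keypoints, "keypoints")
  nf <- dim(keypoints)[1]
  ax <- if (view == "front") c(1, 2) else c(3, 2)
  frames <- array(0, dim = c(nf, image_h, image_w))
  for (f in seq_len(nf)) {
    P <- keypoints[f, , , drop = TRUE]
    px <- (P[, ax[1]] - center_world[ax[1]]) * pixels_per_meter + image_w / 2
    py <- image_h / 2 - (P[, ax[2]] - center_world[ax[2]]) * pixels_per_meter
    img <- matrix(0, image_h, image_w)
    for (b in seq_len(nrow(bones))) {
      a <- bones[b, 1]; c2 <- bones[b, 2]
      x1 <- px[a]; y1 <- py[a]; x2 <- px[c2]; y2 <- py[c2]
      pad <- line_width + 1
      r0 <- max(1, floor(min(y1, y2) - pad)); r1 <- min(image_h, ceiling(max(y1, y2) + pad))
      c0 <- max(1, floor(min(x1, x2) - pad)); c1 <- min(image_w, ceiling(max(x1, x2) + pad))
      if (r1 < r0 || c1 < c0) next  # segment entirely off-screen
      ir <- r0:r1; ic <- c0:c1
      gx <- matrix(rep(ic - 0.5, each = length(ir)), length(ir))
      gy <- matrix(rep(ir - 0.5, times = length(ic)), length(ir))
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      t <- if (len2 > 0) clip(((gx - x1) * dx + (gy - y1) * dy) / len2, 0, 1) else 0
      d <- sqrt((gx - (x1 + t * dx))^2 + (gy - (y1 + t * dy))^2)
      lum <- clip(line_width + 1 - d, 0, 1)
      img[ir, ic] <- pmax(img[ir, ic], lum)
    }
    frames[f, , ] <- img
  }
  frames
}
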