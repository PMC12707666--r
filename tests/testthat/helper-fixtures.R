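# Shared fixtures and independent oracles used across test files.

# Independent forward-kinematics oracle: for each joint, walk the path
# from the root and compose rotation matrices explicitly, without reusing
# the package's traversal.
fk_oracle <- function(skel, euler_frame, root_position = c(0, 0, 0)) {
  nj <- length(skel$joint_names)
  path_to_root <- function(j) {
    p <- integer(0)
    while (!is.na(j)) { p <- c(j, p); j <- skel$parent_index[j] }
    p
  }
  pos <- matrix(0, nj, 3)
  for (j in seq_len(nj)) {
    chain <- path_to_root(j)
    R <- diag(3); x <- root_position
    for (k in seq_along(chain)) {
      jj <- chain[k]
      if (k > 1) x <- x + R %*% skel$offset[jj, ]
      R <- R %*% euler_to_matrix(euler_frame[jj, ], skel$rotation_order)
    }
    pos[j, ] <- x
  }
  pos
}

# world rotation of one joint, composed independently along the root path
world_rotation_oracle <- function(skel, euler_frame, joint) {
  j <- match(joint, skel$joint_names)
  chain <- integer(0)
  while (!is.na(j)) { chain <- c(j, chain); j <- skel$parent_index[j] }
  R <- diag(3)
  for (jj in chain) {
    R <- R %*% euler_to_matrix(euler_frame[jj, ], skel$rotation_order)
  }
  R
}

# tiny two-joint chain used by several kinematics tests
tiny_chain <- function(offset = c(1, 0, 0)) {
  skeleton(data.frame(
    name = c("base", "tip"), parent = c(NA, "base"),
    dx = c(0, offset[1]), dy = c(0, offset[2]), dz = c(0, offset[3]),
    rotating = c(TRUE, TRUE), flexion_axis = NA, group = "chain",
    stringsAsFactors = FALSE))
}

# small reduced pipeline config reused by io/pipeline tests
tiny_config <- function(...) {
  pipeline_config(
    n_possible = 15, n_impossible = 15, n_actors = 3,
    n_runs = 6, sessions = 2, stimuli_per_run = 10, reps = 3,
    n_voxels = 12, n_subjects = 3, n_random = 6, n_outer = 3, n_inner = 2,
    min_frames = 60, max_frames = 62,
    image_h = 32, image_w = 16, pixels_per_degree = 32 / 4.32,
    moten_spatial_freqs = c(1, 4), moten_temporal_freqs = c(2, 8),
    manifold_max_samples = 150, snr = 1, ...)
}

# drifting sinusoidal grating: dir = +1 drifts toward the +orientation axis
make_grating <- function(T, H, W, sf, tf, ori_deg, ppd, fps = 30,
                         dir = 1, phase = 0, contrast = 0.5) {
  th <- ori_deg * pi / 180
  gx <- matrix(rep((1:W) - 0.5, each = H), H)
  gy <- matrix(rep((1:H) - 0.5, times = W), H)
  u <- gx * cos(th) + gy * sin(th)
  fr <- array(0, c(T, H, W))
  for (t in 1:T) {
    fr[t, , ] <- 0.5 + contrast * 0.5 *
      sin(2 * pi * (sf / ppd) * u - dir * 2 * pi * tf * (t - 1) / fps + phase)
  }
  fr
}

# random band designs for encoding/partition tests
random_band_designs <- function(n, p_per_band, bands = c("a", "b"),
                                seed = 1) {
  set.seed(seed)
  out <- lapply(bands, function(b) matrix(rnorm(n * p_per_band), n))
  names(out) <- bands
  out
}
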