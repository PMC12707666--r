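# SimDist feature space: per-joint Gaussian-kernel similarity distance of a
# movement to a manifold of normal (possible) movements in axis-angle
# rotation space. Impossible movements sit farther from the manifold, so
# the feature scales with the magnitude of biomechanical deviation rather
# than a binary label.

#' Select joints that carry rotation data
#'
#' Joints whose rotation channels are identically zero across every
#' supplied trajectory (or are flagged rotationless in the skeleton) are
#' excluded.
#'
#' @param trajectories List of `joint_trajectory` sharing one skeleton.
#' @return Character vector of retained joint names.
#' @export
select_rotating_joints <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  sk <- trajectories[[1]]$skeleton
  any_rot <- rep(FALSE, n_joints(sk))
  for (tr in trajectories) {
    any_rot <- any_rot | apply(tr$euler != 0, 2, any)
  }
  sk$joint_names[any_rot]
}

# pooled axis-angle samples, one n x 3 matrix per joint
.axis_angle_samples <- function(traj, joints) {
  sk <- traj$skeleton
  idx <- match(joints, sk$joint_names)
  out <- lapply(idx, function(j) {
    euler_to_axis_angle(traj$euler[, j, , drop = TRUE], sk$rotation_order)
  })
  names(out) <- joints
  out
}

#' Build the manifold of normal movements
#'
#' For each retained joint, the per-frame axis-angle vectors of all
#' exemplar possible movements are pooled into a sample set; the kernel
#' bandwidth sigma is set per joint by the median pairwise-distance
#' heuristic (with a configurable floor). Optionally the pooled set is
#' thinned to `max_samples` points (deterministic, seeded) to bound the
#' cost of kernel evaluation.
#'
#' @param possible_trajectories List of >= 2 `joint_trajectory` objects
#'   labeled possible.
#' @param joints Joint names to model; default [select_rotating_joints()].
#' @param bandwidth_rule "median" (default) or a fixed numeric sigma.
#' @param sigma_floor Lower bound on sigma in radians, default 1e-3.
#' @param max_samples Cap on pooled samples per joint, default 500.
#' @param seed Seed for the thinning subsample.
#' @return Object of class `manifold_model` with `samples` (list of n x 3
#'   matrices), `sigma` (named vector, radians), `retained_joints`.
#' @export
build_manifold <- function(possible_trajectories, joints = NULL,
                           bandwidth_rule = "median", sigma_floor = 1e-3,
                           max_samples = 500, seed = 1) {
  if (length(possible_trajectories) < 2) {
    stop("need at least 2 possible movements to build a manifold")
  }
  if (any(vapply(possible_trajectories, function(tr) tr$plausibility, "") !=
          "possible")) {
    stop("manifold must be built only from possible movements")
  }
  joints <- joints %||% select_rotating_joints(possible_trajectories)
  pooled <- lapply(joints, function(j) {
    do.call(rbind, lapply(possible_trajectories, function(tr) {
      .axis_angle_samples(tr, j)[[1]]
    }))
  })
  names(pooled) <- joints
  with_seed(seed, {
    pooled <- lapply(pooled, function(S) {
      if (nrow(S) > max_samples) S[sort(sample(nrow(S), max_samples)), , drop = FALSE]
      else S
    })
    sigma <- vapply(pooled, function(S) {
      if (is.numeric(bandwidth_rule)) return(max(bandwidth_rule, sigma_floor))
      d <- stats::dist(S)
      max(stats::median(d), sigma_floor)
    }, numeric(1))
    structure(list(samples = pooled, sigma = sigma, retained_joints = joints),
              class = "manifold_model")
  })
}

#' @export
print.manifold_model <- function(x, ...) {
  cat(sprintf("<manifold_model> %d joints, %d-%d samples/joint\n",
              length(x$samples), min(vapply(x$samples, nrow, 1L)),
              max(vapply(x$samples, nrow, 1L))))
  invisible(x)
}

#' Similarity distance of a test movement to the manifold
#'
#' For joint j and frame t with axis-angle vector x_jt, the kernel
#' similarity is s = mean_i exp(-||x_jt - m_ji||^2 / (2 sigma_j^2)) over
#' the manifold samples m_ji; the per-joint distance is the mean over
#' frames of (1 - s), bounded in [0, 1].
#'
#' @param test_trajectory A `joint_trajectory`.
#' @param manifold A `manifold_model`.
#' @param mode "one_minus_mean" (default), "neglog" (-log s, unbounded) or
#'   "one_minus_max" (nearest-sample similarity).
#' @return Named numeric vector of per-joint distances.
#' @export
similarity_distance <- function(test_trajectory, manifold,
                                mode = c("one_minus_mean", "neglog",
                                         "one_minus_max")) {
  mode <- match.arg(mode)
  joints <- manifold$retained_joints
  missing <- setdiff(joints, test_trajectory$skeleton$joint_names)
  if (length(missing)) stop("test trajectory lacks joints: ", missing[1])
  aa <- .axis_angle_samples(test_trajectory, joints)
  out <- vapply(joints, function(j) {
    X <- aa[[j]]                       # frames x 3
    M <- manifold$samples[[j]]         # n x 3
    if (!nrow(M)) stop("empty manifold for joint ", j)
    s2 <- manifold$sigma[[j]]^2
    d2 <- outer(rowSums(X^2), rowSums(M^2), `+`) - 2 * X %*% t(M)
    K <- exp(-pmax(d2, 0) / (2 * s2))
    s <- switch(mode,
                one_minus_mean = rowMeans(K),
                one_minus_max  = apply(K, 1, max),
                neglog         = rowMeans(K))
    if (mode == "neglog") mean(-log(pmax(s, 1e-300))) else mean(1 - s)
  }, numeric(1))
  names(out) <- joints
  out
}

#' Filter non-finite joints and concatenate SimDist features
#'
#' Any joint with a non-finite distance for any stimulus is dropped; the
#' remaining per-joint distances are concatenated into the feature matrix.
#'
#' @param distances stimuli x joints matrix (rows named by stimulus).
#' @return A `feature_space` named "simdist" with attribute
#'   `retained_joints`.
#' @export
filter_finite_and_concat <- function(distances) {
  distances <- as.matrix(distances)
  keep <- which(apply(is.finite(distances), 2, all))
  if (!length(keep)) stop("all joints dropped by the finiteness filter")
  fs <- feature_space("simdist", distances[, keep, drop = FALSE],
                      feature_names = colnames(distances)[keep],
                      stimulus_ids = rownames(distances))
  attr(fs, "retained_joints") <- colnames(distances)[keep]
  fs
}

#' SimDist feature space for a stimulus set
#'
#' Convenience wrapper: build the manifold from training possible
#' trajectories, compute per-joint distances for every stimulus, filter
#' non-finite joints and concatenate.
#'
#' @param trajectories Named list of `joint_trajectory` (the stimuli).
#' @param manifold A `manifold_model`.
#' @param mode Distance mode, see [similarity_distance()].
#' @return A `feature_space` named "simdist".
#' @export
simdist_features <- function(trajectories, manifold,
                             mode = "one_minus_mean") {
  D <- t(vapply(trajectories, similarity_distance, manifold = manifold,
                mode = mode,
                FUN.VALUE = numeric(length(manifold$retained_joints))))
  rownames(D) <- names(trajectories)
  filter_finite_and_concat(D)
}
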