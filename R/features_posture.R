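# Posture feature spaces: 3D keypoint positions (kp3d) summarized per
# stimulus, and the two-column categorical possibility indicator.

#' Construct a feature space
#'
#' @param name Feature-space label.
#' @param X stimuli x features numeric matrix.
#' @param feature_names Column labels.
#' @param stimulus_ids Row labels.
#' @return Object of class `feature_space`.
#' @export
feature_space <- function(name, X, feature_names = colnames(X),
                          stimulus_ids = rownames(X)) {
  X <- as.matrix(X)
  if (ncol(X) == 0) stop("feature space must have at least one feature")
  stopifnot_finite(X, paste0(name, " features"))
  dimnames(X) <- list(stimulus_ids, feature_names)
  structure(list(name = name, X = X, feature_names = feature_names,
                 stimulus_ids = stimulus_ids),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %s: %d stimuli x %d features\n",
              x$name, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' kp3d feature space: frame-averaged root-centered keypoint positions
#'
#' Each stimulus is summarized by the mean over frames of its root-centered
#' 3D keypoint coordinates (or, with `summary = "frames"`, by a fixed
#' number of subsampled frames concatenated). Keypoints whose summarized
#' position is (almost) constant across the full stimulus set - total
#' coordinate variance below `variance_threshold` - are excluded, and the
#' retained-keypoint list is recorded.
#'
#' @param keypoint_trajectories Named list of frames x joints x 3 position
#'   arrays (all sharing the joint set), e.g. from [forward_kinematics()].
#' @param skeleton The common `skeleton` (used for joint names and root).
#' @param variance_threshold Positional variance floor in m^2, default 1e-8.
#' @param summary "mean" (default) or "frames".
#' @param n_frames Frames kept when `summary = "frames"`.
#' @return A `feature_space` named "kp3d" with attribute
#'   `retained_keypoints`.
#' @export
extract_kp3d <- function(keypoint_trajectories, skeleton,
                         variance_threshold = 1e-8,
                         summary = c("mean", "frames"), n_frames = 5) {
  summary <- match.arg(summary)
  if (!length(keypoint_trajectories)) stop("empty stimulus set")
  if (variance_threshold < 0) stop("variance_threshold must be >= 0")
  nj <- n_joints(skeleton)
  summarize <- function(kp) {
    # root-center so global translation does not dominate
    kp <- kp - kp[, rep(skeleton$root, nj), , drop = FALSE]
    if (summary == "mean") {
      apply(kp, c(2, 3), mean)                       # joints x 3
    } else {
      idx <- unique(round(seq(1, dim(kp)[1], length.out = n_frames)))
      aperm(kp[idx, , , drop = FALSE], c(2, 3, 1))   # joints x 3 x frames
    }
  }
  summ <- lapply(keypoint_trajectories, summarize)
  n_stim <- length(summ)
  per_joint <- vapply(seq_len(nj), function(j) {
    v <- vapply(summ, function(s) {
      if (summary == "mean") s[j, ] else as.numeric(s[j, , ])
    }, numeric(if (summary == "mean") 3 else 3 * n_frames))
    sum(apply(matrix(v, ncol = n_stim), 1, stats::var))
  }, numeric(1))
  keep <- which(per_joint > variance_threshold)
  if (!length(keep)) stop("all keypoints dropped by the variance threshold")
  X <- t(vapply(summ, function(s) {
    if (summary == "mean") as.numeric(t(s[keep, , drop = FALSE]))
    else as.numeric(aperm(s[keep, , , drop = FALSE], c(3, 2, 1)))
  }, numeric(length(keep) * 3 * if (summary == "mean") 1 else n_frames)))
  coords <- c("x", "y", "z")
  fn <- if (summary == "mean") {
    as.character(t(outer(skeleton$joint_names[keep], coords, paste, sep = "_")))
  } else paste0("kp", seq_len(ncol(X)))
  fs <- feature_space("kp3d", X, feature_names = fn,
                      stimulus_ids = names(keypoint_trajectories))
  attr(fs, "retained_keypoints") <- skeleton$joint_names[keep]
  fs
}

#' Categorical possibility feature space
#'
#' Two indicator columns (possible, impossible); exactly one is active per
#' stimulus.
#'
#' @param labels Character vector in {"possible", "impossible"}.
#' @param stimulus_ids Optional row labels.
#' @return A `feature_space` named "categorical".
#' @export
categorical_features <- function(labels, stimulus_ids = names(labels)) {
  bad <- setdiff(unique(labels), c("possible", "impossible"))
  if (length(bad)) stop("unknown plausibility label: ", bad[1])
  X <- cbind(possible = as.numeric(labels == "possible"),
             impossible = as.numeric(labels == "impossible"))
  feature_space("categorical", X, feature_names = colnames(X),
                stimulus_ids = stimulus_ids)
}
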