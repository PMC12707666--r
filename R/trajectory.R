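# Joint trajectories: smooth synthetic movements built from low-frequency
# sinusoids, the possible -> impossible mirroring operation on elbows and
# knees, and forward kinematics.

#' Construct a joint trajectory
#'
#' @param euler frames x joints x 3 array of Euler angles in degrees,
#'   channels ordered as the skeleton's rotation order.
#' @param skeleton A `skeleton`.
#' @param fps Frames per second, default 30.
#' @param plausibility "possible" or "impossible".
#' @return Object of class `joint_trajectory`.
#' @export
joint_trajectory <- function(euler, skeleton, fps = 30,
                             plausibility = "possible") {
  stopifnot(length(dim(euler)) == 3, dim(euler)[2] == n_joints(skeleton),
            dim(euler)[3] == 3)
  stopifnot_finite(euler, "euler angles")
  if (any(abs(euler[, !skeleton$rotating, ]) > 0)) {
    stop("joints without rotation data must have all-zero angles")
  }
  structure(list(euler = euler, skeleton = skeleton, fps = fps,
                 plausibility = match.arg(plausibility,
                                          c("possible", "impossible"))),
            class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat(sprintf("<joint_trajectory> %d frames @ %g fps, %d joints, %s\n",
              dim(x$euler)[1], x$fps, dim(x$euler)[2], x$plausibility))
  invisible(x)
}

# Per-group sinusoid amplitude (degrees) for the four actions. Every
# rotating joint also gets a small baseline wiggle so that all 56 joints
# carry nonzero rotation in every clip.
.action_amplitudes <- function(action) {
  base <- c(torso = 4, arm_l = 6, arm_r = 6, hand_l = 4, hand_r = 4,
            leg_l = 5, leg_r = 5)
  boost <- switch(action,
    kick  = c(leg_r = 45, leg_l = 12, torso = 8),
    jump  = c(leg_l = 35, leg_r = 35, arm_l = 20, arm_r = 20, torso = 10),
    point = c(arm_r = 40, hand_r = 15, torso = 6),
    wave  = c(arm_r = 35, hand_r = 20),
    stop("unknown action label: ", action)
  )
  base[names(boost)] <- boost
  base
}

#' Actions available to the trajectory generator
#' @export
dynbody_actions <- function() c("kick", "jump", "point", "wave")

#' Simulate a biomechanically possible joint trajectory
#'
#' Each rotation channel of each rotating joint is a sum of up to three
#' low-frequency sinusoids (0.5-2 cycles per clip). Channels flagged as a
#' flexion axis with anatomical limits (elbows and knees) are mapped
#' affinely into the limit interval so that e.g. elbow/knee flexion never
#' goes below zero degrees. Deterministic given `seed`.
#'
#' @param skeleton A `skeleton`.
#' @param action One of `dynbody_actions()`.
#' @param duration_frames Clip length in frames, between 60 and 90.
#' @param seed Integer seed.
#' @param amplitude_scale Global multiplier on all sinusoid amplitudes;
#'   0 yields a static pose.
#' @param flexion_limits Length-2 numeric, degrees: the interval for
#'   elbow/knee flexion channels. Default c(0, 150).
#' @param fps Frames per second.
#' @return A `joint_trajectory` labeled "possible".
#' @export
simulate_possible_trajectory <- function(skeleton, action, duration_frames,
                                         seed = 1, amplitude_scale = 1,
                                         flexion_limits = c(0, 150),
                                         fps = 30) {
  if (!action %in% dynbody_actions()) stop("unknown action label: ", action)
  if (duration_frames < 60 || duration_frames > 90) {
    stop("duration_frames must be in [60, 90]")
  }
  amps <- .action_amplitudes(action)
  nj <- n_joints(skeleton)
  tt <- seq(0, 1, length.out = duration_frames)
  order_axes <- .check_order(skeleton$rotation_order)
  with_seed(seed, {
    euler <- array(0, dim = c(duration_frames, nj, 3))
    for (j in seq_len(nj)) {
      if (!skeleton$rotating[j]) next
      amp <- amps[[skeleton$group[j]]] %||% 3
      flex_ch <- if (!is.na(skeleton$flexion_axis[j])) {
        match(skeleton$flexion_axis[j], order_axes)
      } else NA_integer_
      for (ch in 1:3) {
        k <- sample(1:3, 1)
        a <- stats::runif(k, 0.2, 1) * amp
        f <- stats::runif(k, 0.5, 2)
        ph <- stats::runif(k, 0, 2 * pi)
        s <- rowSums(vapply(seq_len(k), function(i) {
          a[i] * sin(2 * pi * f[i] * tt + ph[i])
        }, numeric(duration_frames)))
        if (!is.na(flex_ch) && ch == flex_ch) {
          # map into the anatomical flexion interval: s / sum|a| in [-1, 1]
          u <- if (sum(a) > 0) s / sum(a) else rep(0, duration_frames)
          lo <- flexion_limits[1]; hi <- flexion_limits[2]
          mid <- (lo + hi) / 2
          half <- (hi - lo) / 2 * amplitude_scale
          half <- min(half, (hi - lo) / 2)
          euler[, j, ch] <- mid + half * u
          if (amplitude_scale == 0) euler[, j, ch] <- 0
        } else {
          euler[, j, ch] <- amplitude_scale * s
        }
      }
    }
    joint_trajectory(euler, skeleton, fps = fps, plausibility = "possible")
  })
}

# world rotation matrices for every joint at one frame
.world_rotations <- function(skeleton, euler_frame) {
  nj <- n_joints(skeleton)
  Rw <- vector("list", nj)
  for (j in skeleton$topo_order) {
    Rl <- euler_to_matrix(euler_frame[j, ], skeleton$rotation_order)
    p <- skeleton$parent_index[j]
    Rw[[j]] <- if (is.na(p)) Rl else Rw[[p]] %*% Rl
  }
  Rw
}

#' Forward kinematics
#'
#' World position of every joint at every frame. A child's position is its
#' parent's position plus the parent's world rotation applied to the
#' child's offset; a joint's world rotation composes its parent's world
#' rotation with its own local rotation.
#'
#' @param skeleton A `skeleton`.
#' @param traj A `joint_trajectory` (or frames x joints x 3 Euler array).
#' @param root_position Length-3 world position of the root, meters.
#' @return frames x joints x 3 array of positions in meters.
#' @export
forward_kinematics <- function(skeleton, traj,
                               root_position = c(0, 0, 0)) {
  euler <- if (inherits(traj, "joint_trajectory")) traj$euler else traj
  nf <- dim(euler)[1]; nj <- n_joints(skeleton)
  pos <- array(0, dim = c(nf, nj, 3),
               dimnames = list(NULL, skeleton$joint_names, c("x", "y", "z")))
  for (f in seq_len(nf)) {
    Rw <- vector("list", nj)
    P <- matrix(0, nj, 3)
    for (j in skeleton$topo_order) {
      Rl <- euler_to_matrix(euler[f, j, ], skeleton$rotation_order)
      p <- skeleton$parent_index[j]
      if (is.na(p)) {
        Rw[[j]] <- Rl
        P[j, ] <- root_position
      } else {
        Rw[[j]] <- Rw[[p]] %*% Rl
        P[j, ] <- P[p, ] + Rw[[p]] %*% skeleton$offset[j, ]
      }
    }
    pos[f, , ] <- P
  }
  pos
}

#' Mirror elbow and knee rotations to create an impossible movement
#'
#' The rotation about the flexion axis of each elbow and knee is negated at
#' every frame, reversing the bending direction against its anatomical
#' limit. The wrist (resp. ankle) local rotation is then re-solved so that
#' the end-effector's (hand/foot) world orientation matches the original
#' trajectory at every frame.
#'
#' @param traj A `joint_trajectory` labeled "possible".
#' @return A `joint_trajectory` labeled "impossible".
#' @export
make_impossible <- function(traj) {
  stopifnot(inherits(traj, "joint_trajectory"))
  if (traj$plausibility != "possible") {
    stop("make_impossible expects a trajectory labeled possible")
  }
  sk <- traj$skeleton
  if (sk$rotation_order != "ZXY") {
    stop("mirroring is implemented for the ZXY rotation order")
  }
  mirrored <- which(!is.na(sk$flexion_axis) & sk$rotating)
  if (!length(mirrored)) stop("skeleton has no elbow/knee flexion joints")
  order_axes <- .check_order(sk$rotation_order)
  euler <- traj$euler
  # child-of-mirrored joints whose local rotation is re-solved (wrist/ankle)
  fix <- which(sk$parent_index %in% mirrored)
  nf <- dim(euler)[1]
  for (f in seq_len(nf)) {
    Rw_old <- .world_rotations(sk, traj$euler[f, , ])
    for (j in mirrored) {
      ch <- match(sk$flexion_axis[j], order_axes)
      euler[f, j, ch] <- -euler[f, j, ch]
    }
    Rw_new <- .world_rotations(sk, euler[f, , ])
    for (j in fix) {
      p <- sk$parent_index[j]
      # keep the subtree rooted at j world-aligned with the original
      L <- t(Rw_new[[p]]) %*% Rw_old[[j]]
      euler[f, j, ] <- matrix_to_euler_zxy(L)
    }
  }
  joint_trajectory(euler, sk, fps = traj$fps, plausibility = "impossible")
}
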