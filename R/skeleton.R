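# Skeleton model: a rooted joint tree with per-joint offsets (meters), an
# Euler rotation order, and bookkeeping of which joints carry rotation data.
# The default skeleton mimics a marker-based mocap skeleton with 71 named
# joints, of which 56 carry rotation channels (torso, limbs, hands, fingers)
# and 15 are rigid (root anchor, neck, head and facial keypoints).

#' Construct a skeleton
#'
#' @param joints A data.frame with columns `name`, `parent` (name or NA for
#'   the root), `dx`, `dy`, `dz` (offset from parent, meters), `rotating`
#'   (logical: does this joint carry rotation channels), `flexion_axis`
#'   (one of "X","Y","Z" or NA; the axis whose rotation bends the joint),
#'   and `group` (label used by the trajectory generator).
#' @param rotation_order Euler convention label, default `"ZXY"`.
#' @return An object of class `skeleton`.
#' @export
skeleton <- function(joints, rotation_order = "ZXY") {
  .check_order(rotation_order)
  stopifnot(is.data.frame(joints),
            all(c("name", "parent", "dx", "dy", "dz",
                  "rotating", "flexion_axis", "group") %in% names(joints)))
  name <- as.character(joints$name)
  if (anyDuplicated(name)) stop("duplicate joint names")
  parent_index <- match(joints$parent, name)
  root <- which(is.na(joints$parent))
  if (length(root) != 1L) stop("skeleton must have exactly one root")
  if (any(is.na(parent_index[-root]))) stop("unknown parent joint")
  # cycle check / topological order
  order <- integer(0); placed <- rep(FALSE, nrow(joints))
  frontier <- root
  while (length(frontier)) {
    order <- c(order, frontier); placed[frontier] <- TRUE
    frontier <- which(!placed & parent_index %in% frontier)
  }
  if (!all(placed)) stop("cyclic parent graph")
  off <- as.matrix(joints[, c("dx", "dy", "dz")])
  if (any(rowSums(off[-root, , drop = FALSE]^2) == 0)) {
    stop("non-root joints must have nonzero offsets")
  }
  structure(list(
    joint_names = name,
    parent_index = parent_index,
    offset = off,
    rotation_order = rotation_order,
    rotating = as.logical(joints$rotating),
    flexion_axis = as.character(joints$flexion_axis),
    group = as.character(joints$group),
    topo_order = order,
    root = root
  ), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d joints (%d with rotation data), order %s\n",
              length(x$joint_names), sum(x$rotating), x$rotation_order))
  invisible(x)
}

#' Number of joints
#' @param skel A `skeleton`.
#' @export
n_joints <- function(skel) length(skel$joint_names)

.side <- function(df, side) {
  s <- if (side == "l") 1 else -1
  df$name <- paste0(side, "_", df$name)
  df$parent <- ifelse(df$parent %in% c("chest", "root"),
                      df$parent, paste0(side, "_", df$parent))
  df$dx <- s * df$dx
  df$group <- paste0(df$group, "_", side)
  df
}

.j <- function(name, parent, dx, dy, dz, rotating, flexion, group) {
  data.frame(name = name, parent = parent, dx = dx, dy = dy, dz = dz,
             rotating = rotating, flexion_axis = flexion, group = group,
             stringsAsFactors = FALSE)
}

#' Default 71-joint mocap-style skeleton
#'
#' A stick-figure skeleton in a T-pose: arms along +/-x, legs along -y,
#' y up. 56 joints carry rotation channels; the root anchor, neck, head and
#' 12 facial keypoints are rigid. Limb and torso offsets scale with
#' `actor_scale` (emulating actors of different stature) while facial
#' offsets are fixed.
#'
#' @param actor_scale Multiplier applied to the offsets of rotating joints.
#' @return A `skeleton` with 71 joints.
#' @export
movi_skeleton <- function(actor_scale = 1) {
  arm <- rbind(
    .j("clavicle", "chest",    0.08, 0.05, 0, TRUE, NA,  "arm"),
    .j("shoulder", "clavicle", 0.12, 0.00, 0, TRUE, NA,  "arm"),
    .j("elbow",    "shoulder", 0.28, 0.00, 0, TRUE, "Z", "arm"),
    .j("wrist",    "elbow",    0.26, 0.00, 0, TRUE, NA,  "arm"),
    .j("hand",     "wrist",    0.08, 0.00, 0, TRUE, NA,  "hand"),
    .j("thumb1",   "hand",   0.030, 0, 0.030, TRUE, NA, "hand"),
    .j("thumb2",   "thumb1", 0.030, 0, 0.010, TRUE, NA, "hand"),
    .j("thumb3",   "thumb2", 0.020, 0, 0.005, TRUE, NA, "hand"),
    .j("index1",   "hand",   0.090, 0, 0.020, TRUE, NA, "hand"),
    .j("index2",   "index1", 0.030, 0, 0.000, TRUE, NA, "hand"),
    .j("index3",   "index2", 0.020, 0, 0.000, TRUE, NA, "hand"),
    .j("middle1",  "hand",   0.090, 0, 0.000, TRUE, NA, "hand"),
    .j("middle2",  "middle1",0.032, 0, 0.000, TRUE, NA, "hand"),
    .j("middle3",  "middle2",0.022, 0, 0.000, TRUE, NA, "hand"),
    .j("ring1",    "hand",   0.088, 0, -0.020, TRUE, NA, "hand"),
    .j("ring2",    "ring1",  0.030, 0,  0.000, TRUE, NA, "hand"),
    .j("ring3",    "ring2",  0.020, 0,  0.000, TRUE, NA, "hand"),
    .j("pinky1",   "hand",   0.080, 0, -0.035, TRUE, NA, "hand"),
    .j("pinky2",   "pinky1", 0.025, 0,  0.000, TRUE, NA, "hand"),
    .j("pinky3",   "pinky2", 0.018, 0,  0.000, TRUE, NA, "hand")
  )
  leg <- rbind(
    .j("hip",   "root", 0.09, -0.05, 0.00, TRUE, NA,  "leg"),
    .j("knee",  "hip",  0.00, -0.42, 0.00, TRUE, "X", "leg"),
    .j("ankle", "knee", 0.00, -0.40, 0.00, TRUE, NA,  "leg"),
    .j("foot",  "ankle",0.00, -0.05, 0.12, TRUE, NA,  "leg"),
    .j("toe",   "foot", 0.00,  0.00, 0.08, TRUE, NA,  "leg"),
    .j("toe2",  "toe",  0.00,  0.00, 0.04, TRUE, NA,  "leg")
  )
  face <- rbind(
    .j("neck",      "root", 0.00, 0.58, 0.00, FALSE, NA, "face"),
    .j("head",      "neck", 0.00, 0.10, 0.00, FALSE, NA, "face"),
    .j("jaw",       "head", 0.00, -0.02, 0.06, FALSE, NA, "face"),
    .j("chin",      "jaw",  0.00, -0.02, 0.02, FALSE, NA, "face"),
    .j("nose",      "head", 0.00, 0.02, 0.09, FALSE, NA, "face"),
    .j("forehead",  "head", 0.00, 0.07, 0.07, FALSE, NA, "face"),
    .j("l_eye",     "head", 0.03, 0.03, 0.08, FALSE, NA, "face"),
    .j("r_eye",     "head",-0.03, 0.03, 0.08, FALSE, NA, "face"),
    .j("l_eyeball", "l_eye", 0.005, 0, 0.01, FALSE, NA, "face"),
    .j("r_eyeball", "r_eye",-0.005, 0, 0.01, FALSE, NA, "face"),
    .j("l_ear",     "head", 0.07, 0.01, 0.00, FALSE, NA, "face"),
    .j("r_ear",     "head",-0.07, 0.01, 0.00, FALSE, NA, "face"),
    .j("l_cheek",   "head", 0.04, -0.01, 0.06, FALSE, NA, "face"),
    .j("r_cheek",   "head",-0.04, -0.01, 0.06, FALSE, NA, "face")
  )
  torso <- rbind(
    .j("spine1", "root",   0.00, 0.12, 0.00, TRUE, NA, "torso"),
    .j("spine2", "spine1", 0.00, 0.12, 0.00, TRUE, NA, "torso"),
    .j("spine3", "spine2", 0.00, 0.12, 0.00, TRUE, NA, "torso"),
    .j("chest",  "spine3", 0.00, 0.12, 0.00, TRUE, NA, "torso")
  )
  joints <- rbind(
    .j("root", NA, 0, 0, 0, FALSE, NA, "core"),
    torso, face,
    .side(arm, "l"), .side(arm, "r"),
    .side(leg, "l"), .side(leg, "r")
  )
  body <- joints$rotating
  joints$dx[body] <- joints$dx[body] * actor_scale
  joints$dy[body] <- joints$dy[body] * actor_scale
  joints$dz[body] <- joints$dz[body] * actor_scale
  skeleton(joints)
}

#' Bone list (parent-child index pairs) for rendering
#' @param skel A `skeleton`.
#' @return Two-column integer matrix of joint index pairs.
#' @export
skeleton_bones <- function(skel) {
  child <- seq_along(skel$joint_names)[-skel$root]
  cbind(skel$parent_index[child], child)
}
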