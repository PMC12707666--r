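# Scoring and variance partitioning: Fisher-z averaged prediction
# accuracies, decomposition of the joint model's explained variance into
# per-band contributions, and the composite HSV visualization.

#' Fisher-z averaged prediction accuracy per voxel
#'
#' Pearson r per fold per voxel; r is clipped to +/-(1 - 1e-7), Fisher
#' z-transformed (atanh), averaged over folds, and back-transformed with
#' tanh. Zero-variance predictions score r = 0.
#'
#' @param Y_true,Y_pred n x v matrices.
#' @param fold_ids Integer fold label per row.
#' @return Named list: `r` (per-voxel aggregate), `r_fold` (fold x voxel).
#' @export
accuracy <- function(Y_true, Y_pred, fold_ids) {
  folds <- sort(unique(fold_ids))
  rf <- vapply(folds, function(k) {
    rows <- which(fold_ids == k)
    if (length(rows) < 3) stop("need at least 3 time points per fold")
    Yc <- sweep(Y_true[rows, , drop = FALSE], 2,
                colMeans(Y_true[rows, , drop = FALSE]))
    Pc <- sweep(Y_pred[rows, , drop = FALSE], 2,
                colMeans(Y_pred[rows, , drop = FALSE]))
    den <- sqrt(colSums(Yc^2) * colSums(Pc^2))
    ifelse(den > 0, colSums(Yc * Pc) / den, 0)
  }, numeric(ncol(Y_true)))
  if (is.null(dim(rf))) rf <- matrix(rf, nrow = 1)  # single-voxel input
  r_fold <- t(rf)
  z <- atanh(clip(r_fold, -(1 - 1e-7), 1 - 1e-7))
  list(r = tanh(colMeans(z)), r_fold = r_fold)
}

#' Per-band contributions to the jointly explained variance
#'
#' With joint prediction yhat = sum_b yhat_b, the identity
#' R2 = sum_b (2 cov(y, yhat_b) - cov(yhat_b, yhat)) / var(y)
#' attributes a signed contribution to each band that sums exactly to the
#' joint R2. Negative contributions (suppression) are clipped to zero
#' before normalizing into fractions. Partial correlations between y and
#' each band's partial prediction, controlling for the other bands'
#' predictions, are returned alongside.
#'
#' @param Y_true n x v matrix.
#' @param band_predictions Named list of n x v per-band partial
#'   predictions (summing to the joint prediction).
#' @return List with `R2_joint` (per voxel), `contrib` (band x voxel,
#'   signed), `fraction` (band x voxel, clipped and normalized; NA where
#'   R2_joint <= 0), `partial_r` (band x voxel), `n_clipped`.
#' @export
partial_contribution <- function(Y_true, band_predictions) {
  nb <- length(band_predictions)
  bands <- names(band_predictions) %||% paste0("band", seq_len(nb))
  n <- nrow(Y_true); v <- ncol(Y_true)
  Yc <- sweep(Y_true, 2, colMeans(Y_true))
  Pc <- lapply(band_predictions, function(P) sweep(P, 2, colMeans(P)))
  joint <- Reduce(`+`, Pc)
  vy <- colSums(Yc^2)
  R2 <- 1 - colSums((Yc - joint)^2) / vy
  contrib <- matrix(0, nb, v, dimnames = list(bands, colnames(Y_true)))
  for (b in seq_len(nb)) {
    contrib[b, ] <- (2 * colSums(Yc * Pc[[b]]) -
                       colSums(Pc[[b]] * joint)) / vy
  }
  clipped <- pmax(contrib, 0)
  n_clipped <- sum(contrib < 0)
  tot <- colSums(clipped)
  fraction <- sweep(clipped, 2, ifelse(tot > 0, tot, NA), `/`)
  fraction[, R2 <= 0] <- NA
  # partial correlation: residualize y and yhat_b on the other bands
  partial_r <- matrix(0, nb, v, dimnames = dimnames(contrib))
  for (b in seq_len(nb)) {
    for (vv in seq_len(v)) {
      Z <- cbind(1, vapply(Pc[-b], function(P) P[, vv], numeric(n)))
      qz <- qr(Z)
      ry <- qr.resid(qz, Yc[, vv])
      rp <- qr.resid(qz, Pc[[b]][, vv])
      den <- sqrt(sum(ry^2) * sum(rp^2))
      partial_r[b, vv] <- if (den > 0) sum(ry * rp) / den else 0
    }
  }
  list(R2_joint = R2, contrib = contrib, fraction = fraction,
       partial_r = partial_r, n_clipped = n_clipped)
}

#' Composite HSV map of residual variance partitioning
#'
#' Motion energy is factored out: the residual fractions of the kp3d,
#' categorical and SimDist bands are mixed as RGB weights whose hue
#' encodes their relative proportions (pure red = kp3d, pure green =
#' categorical, pure blue = SimDist). Saturation encodes the residual
#' strength 1 - motion-energy fraction, rescaled between `s_min` and
#' `s_max`; value encodes the joint prediction accuracy, min-max scaled
#' over the map.
#'
#' @param fraction band x voxel fraction matrix with rownames including
#'   "kp3d", "categorical", "simdist", "moten".
#' @param r_joint Per-voxel joint accuracy.
#' @param s_min,s_max Saturation rescale anchors, defaults 0.23 and 0.93.
#' @param tie_tol Residual-fraction spread below which a voxel is treated
#'   as achromatic (S = 0).
#' @return List with vectors `H`, `S`, `V` in [0, 1].
#' @export
hsv_composite <- function(fraction, r_joint, s_min = 0.23, s_max = 0.93,
                          tie_tol = 1e-9) {
  stopifnot(all(c("kp3d", "categorical", "simdist", "moten") %in%
                  rownames(fraction)))
  stopifnot_finite(r_joint, "r_joint")
  v <- ncol(fraction)
  residual <- 1 - fraction["moten", ]
  rgb <- fraction[c("kp3d", "categorical", "simdist"), , drop = FALSE]
  H <- S <- numeric(v)
  for (i in seq_len(v)) {
    w <- rgb[, i]
    if (any(!is.finite(w)) || sum(w) <= 0 ||
        max(w) - min(w) < tie_tol) {
      H[i] <- 0; S[i] <- 0
    } else {
      w <- w / max(w)
      hsv <- grDevices::rgb2hsv(w[1], w[2], w[3], maxColorValue = 1)
      H[i] <- hsv[1, 1]
      S[i] <- clip((residual[i] - s_min) / (s_max - s_min), 0, 1)
    }
  }
  rng <- range(r_joint)
  V <- if (diff(rng) > 0) (r_joint - rng[1]) / diff(rng) else rep(1, v)
  list(H = H, S = S, V = V)
}
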