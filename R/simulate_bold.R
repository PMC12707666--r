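# Generative twin of the encoding model: voxel time series follow the
# delayed linear model Y = sum_b X_b W_b + Gaussian noise, with per-band
# generating variance fractions recorded as ground truth.

#' Construct ground-truth band weights for BOLD simulation
#'
#' Weights are drawn i.i.d. standard normal per band and then rescaled per
#' voxel so the variance of each band's signal `X_b W_b` over the supplied
#' design equals `band_fractions[b] * total_signal_var`. The noise standard
#' deviation follows from `snr` (signal variance / noise variance) unless
#' `noise_sd` is given directly.
#'
#' @param design_by_band Named list of n_TR x p_b design matrices.
#' @param n_voxels Number of voxels.
#' @param band_fractions Named or positional nonnegative fractions, one per
#'   band, summing to at most 1 (the remainder is unmodeled signal left
#'   out). Fractions are of the total generated signal variance.
#' @param total_signal_var Total signal variance per voxel, default 1.
#' @param snr Signal-to-noise variance ratio; ignored if `noise_sd` given.
#' @param noise_sd Per-voxel noise SD (scalar or length n_voxels).
#' @param seed Integer seed.
#' @return List of class `ground_truth` with `band_weights`, `noise_sd`,
#'   `band_fractions`, `seed`.
#' @export
make_ground_truth <- function(design_by_band, n_voxels, band_fractions,
                              total_signal_var = 1, snr = NULL,
                              noise_sd = NULL, seed = 1) {
  stopifnot(length(band_fractions) == length(design_by_band))
  if (any(band_fractions < 0) || sum(band_fractions) > 1 + 1e-12) {
    stop("band_fractions must be nonnegative and sum to at most 1")
  }
  if (is.null(noise_sd)) {
    if (is.null(snr)) stop("supply either snr or noise_sd")
    noise_sd <- sqrt(total_signal_var / snr)
  }
  bands <- names(design_by_band) %||% paste0("band", seq_along(design_by_band))
  with_seed(seed, {
    W <- lapply(seq_along(design_by_band), function(b) {
      X <- design_by_band[[b]]
      Wb <- matrix(stats::rnorm(ncol(X) * n_voxels), ncol(X), n_voxels)
      target <- band_fractions[b] * total_signal_var
      if (target == 0) return(Wb * 0)
      S <- X %*% Wb
      v <- apply(S, 2, stats::var)
      v[v == 0] <- 1
      Wb * rep(sqrt(target / v), each = ncol(X))
    })
    names(W) <- bands
    structure(list(band_weights = W,
                   noise_sd = rep(noise_sd, length.out = n_voxels),
                   band_fractions = stats::setNames(band_fractions, bands),
                   seed = seed),
              class = "ground_truth")
  })
}

#' Simulate BOLD time series from band designs and ground truth
#'
#' @param design_by_band Named list of n_TR x p_b matrices on a shared TR
#'   grid.
#' @param ground_truth A `ground_truth` object.
#' @param runs Optional integer vector (length n_TR) of run labels; stored
#'   as an attribute for run-wise cross-validation.
#' @param seed Seed for the noise draw; defaults to `ground_truth$seed + 1`.
#' @return n_TR x n_voxels matrix `Y` with attributes `runs` and `signal`
#'   (the noiseless sum) and `band_signals` (list of per-band signals).
#' @export
simulate_bold <- function(design_by_band, ground_truth, runs = NULL,
                          seed = NULL) {
  W <- ground_truth$band_weights
  stopifnot(length(W) == length(design_by_band))
  n_tr <- nrow(design_by_band[[1]])
  if (!all(vapply(design_by_band, nrow, 1L) == n_tr)) {
    stop("band design matrices must share the TR grid")
  }
  for (b in seq_along(W)) {
    if (ncol(design_by_band[[b]]) != nrow(W[[b]])) {
      stop("design/weight dimension mismatch in band ", b)
    }
  }
  nv <- ncol(W[[1]])
  band_signals <- lapply(seq_along(W), function(b) design_by_band[[b]] %*% W[[b]])
  names(band_signals) <- names(design_by_band)
  signal <- Reduce(`+`, band_signals)
  eps <- with_seed(seed %||% (ground_truth$seed + 1), {
    matrix(stats::rnorm(n_tr * nv), n_tr, nv) *
      rep(ground_truth$noise_sd, each = n_tr)
  })
  Y <- signal + eps
  attr(Y, "runs") <- runs
  attr(Y, "signal") <- signal
  attr(Y, "band_signals") <- band_signals
  Y
}
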