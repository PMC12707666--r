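# Encoding stage: delayed TR-level design matrices from events and feature
# spaces, training-statistics standardization, nuisance denoising, banded
# ridge regression with a closed-form solution, and nested run-wise
# cross-validation with random-search hyperparameter optimization.

#' Canonical double-gamma hemodynamic response function
#'
#' Peak at 6 s, undershoot at 16 s, undershoot ratio 1/6; unit peak.
#'
#' @param t Time in seconds.
#' @return HRF values.
#' @export
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h[t < 0] <- 0
  h / max(h)
}

#' Build delayed band design matrices from events and feature spaces
#'
#' Each stimulus trial contributes its feature row at its onset TR; the
#' design is then expanded with `n_delays` copies shifted forward in time
#' by 1..n_delays TRs (within run), so 5 delays at TR 2.3 s span 11.5 s of
#' hemodynamic lag. Blank and target trials contribute no feature content.
#'
#' @param events An `event_table` (or data.frame with `run`, `onset_s`,
#'   `stimulus_id`, `trial_type`).
#' @param feature_spaces Named list of `feature_space` objects.
#' @param n_tr TRs per run.
#' @param tr_s TR in seconds, default 2.3.
#' @param n_delays Number of TR delays, default 5.
#' @param delay_offset First delay in TRs, default 1 (set 0 to include an
#'   undelayed copy).
#' @param add_onset If TRUE, append a unit "onset" feature to every band
#'   (a delayed stimulus indicator capturing the mean evoked response, so
#'   that training-statistics standardization of the features is an exact
#'   reparametrization of the unstandardized model).
#' @return Named list of n_total_TR x (features * n_delays) matrices, with
#'   attributes `runs` (run label per row) and `n_delays`.
#' @export
build_design <- function(events, feature_spaces, n_tr,
                         tr_s = attr(events, "tr_s") %||% 2.3,
                         n_delays = 5, delay_offset = 1,
                         add_onset = FALSE) {
  runs <- sort(unique(events$run))
  run_row <- rep(runs, each = n_tr)
  stim <- events[events$trial_type == "stimulus", , drop = FALSE]
  onset_tr <- round(stim$onset_s / tr_s)
  if (any(onset_tr >= n_tr)) stop("stimulus onset beyond run length")
  out <- lapply(feature_spaces, function(fs) {
    miss <- setdiff(unique(stim$stimulus_id), fs$stimulus_ids)
    if (length(miss)) {
      stop("missing stimulus feature in band ", fs$name, ": ", miss[1])
    }
    Xf <- fs$X
    if (add_onset) Xf <- cbind(Xf, onset = 1)
    p <- ncol(Xf)
    base <- matrix(0, n_tr * length(runs), p)
    row0 <- (match(stim$run, runs) - 1) * n_tr + onset_tr + 1
    feat <- Xf[match(stim$stimulus_id, fs$stimulus_ids), , drop = FALSE]
    for (i in seq_along(row0)) {
      base[row0[i], ] <- base[row0[i], ] + feat[i, ]
    }
    delays <- delay_offset + seq_len(n_delays) - 1
    X <- matrix(0, nrow(base), p * n_delays)
    for (di in seq_along(delays)) {
      d <- delays[di]
      cols <- (di - 1) * p + seq_len(p)
      for (r in seq_along(runs)) {
        rr <- (r - 1) * n_tr
        src <- seq_len(n_tr - d)
        X[rr + src + d, cols] <- base[rr + src, ]
      }
    }
    colnames(X) <- paste0(rep(colnames(Xf), times = n_delays), "_d",
                          rep(delays, each = p))
    X
  })
  names(out) <- names(feature_spaces)
  for (b in seq_along(out)) {
    attr(out[[b]], "runs") <- run_row
    attr(out[[b]], "n_delays") <- n_delays
  }
  out
}

#' Standardize columns by training statistics
#'
#' Training columns are scaled to mean 0, sd 1; test columns are shifted
#' and scaled with the training statistics only, so no information leaks
#' from the test split. Zero-variance training columns are dropped with a
#' warning.
#'
#' @param train,test Numeric matrices with identical columns (`test` may
#'   be NULL).
#' @return List with `train`, `test`, `mean`, `sd`, `dropped`.
#' @export
standardize <- function(train, test = NULL) {
  m <- colMeans(train)
  s <- apply(train, 2, stats::sd)
  dropped <- which(s == 0 | !is.finite(s))
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance training column(s)",
                    length(dropped)))
    keep <- setdiff(seq_len(ncol(train)), dropped)
  } else keep <- seq_len(ncol(train))
  scale2 <- function(X) {
    X <- X[, keep, drop = FALSE]
    sweep(sweep(X, 2, m[keep]), 2, s[keep], `/`)
  }
  list(train = scale2(train),
       test = if (!is.null(test)) scale2(test),
       mean = m[keep], sd = s[keep], dropped = dropped)
}

#' Regress nuisance signals out of voxel time series
#'
#' Projects `Y` on the orthogonal complement of the regressor span
#' (intercept included). Rank-deficient regressor sets are handled by the
#' pseudo-inverse implicit in the QR with pivoting.
#'
#' @param Y n_TR x voxels matrix.
#' @param nuisance n_TR x k matrix of nuisance regressors (e.g. stimulus
#'   onsets convolved with [hrf_double_gamma()] and motion parameters).
#' @return Residual matrix of the same shape as `Y`.
#' @export
denoise_timeseries <- function(Y, nuisance) {
  X <- cbind(1, as.matrix(nuisance))
  if (ncol(X) >= nrow(X)) stop("regressors must span fewer dimensions than TRs")
  qrX <- qr(X)
  Y - qr.fitted(qrX, Y)
}

#' Build an onset regressor convolved with the canonical HRF
#'
#' @param onsets_s Onset times in seconds (within one run).
#' @param n_tr TRs in the run.
#' @param tr_s TR in seconds.
#' @return Length-`n_tr` regressor.
#' @export
onset_hrf_regressor <- function(onsets_s, n_tr, tr_s = 2.3) {
  stick <- numeric(n_tr)
  idx <- round(onsets_s / tr_s) + 1
  stick[idx[idx >= 1 & idx <= n_tr]] <- 1
  h <- hrf_double_gamma(seq(0, 30, by = tr_s))
  as.numeric(stats::convolve(stick, rev(h), type = "open"))[seq_len(n_tr)]
}

#' Banded ridge regression (closed form)
#'
#' Minimizes ||Y - sum_b X_b W_b||^2 + sum_b lambda_b ||W_b||^2 via the
#' scaled-feature concatenation trick: columns of band b are divided by
#' sqrt(lambda_b), an ordinary ridge with unit penalty is solved in the
#' primal (p <= n) or dual (p > n) form, and the weights are scaled back.
#'
#' @param X_bands Named list of n x p_b matrices.
#' @param Y n x v response matrix.
#' @param lambdas Positive penalties, one per band.
#' @return Object of class `banded_ridge_fit` with per-band weights `W`
#'   (list of p_b x v), `lambdas`, and band column counts.
#' @export
fit_banded_ridge <- function(X_bands, Y, lambdas) {
  stopifnot(length(lambdas) == length(X_bands))
  if (any(lambdas <= 0)) stop("lambdas must be positive")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (!all(vapply(X_bands, nrow, 1L) == n)) stop("TR count mismatch")
  p_b <- vapply(X_bands, ncol, 1L)
  Xs <- do.call(cbind, lapply(seq_along(X_bands), function(b) {
    X_bands[[b]] / sqrt(lambdas[b])
  }))
  p <- ncol(Xs)
  if (p <= n) {
    A <- crossprod(Xs) + diag(p)
    Wt <- solve(A, crossprod(Xs, Y))
  } else {
    K <- tcrossprod(Xs) + diag(n)
    Wt <- crossprod(Xs, solve(K, Y))
  }
  # undo the column scaling per band
  splits <- rep(seq_along(X_bands), p_b)
  W <- lapply(seq_along(X_bands), function(b) {
    Wt[splits == b, , drop = FALSE] / sqrt(lambdas[b])
  })
  names(W) <- names(X_bands)
  structure(list(W = W, lambdas = lambdas, p_b = p_b,
                 bands = names(X_bands)),
            class = "banded_ridge_fit")
}

#' Predict from a banded ridge fit
#'
#' @param object A `banded_ridge_fit`.
#' @param X_bands Named list of design matrices.
#' @param per_band If TRUE also return each band's partial prediction.
#' @param ... Unused.
#' @return Prediction matrix, or list(joint, bands) if `per_band`.
#' @export
predict.banded_ridge_fit <- function(object, X_bands, per_band = FALSE,
                                     ...) {
  preds <- lapply(seq_along(object$W), function(b) {
    X_bands[[b]] %*% object$W[[b]]
  })
  names(preds) <- object$bands
  joint <- Reduce(`+`, preds)
  if (per_band) list(joint = joint, bands = preds) else joint
}

# mean over voxels of the Pearson correlation between columns
.mean_voxel_cor <- function(Y, Yhat) {
  Yc <- sweep(Y, 2, colMeans(Y))
  Pc <- sweep(Yhat, 2, colMeans(Yhat))
  num <- colSums(Yc * Pc)
  den <- sqrt(colSums(Yc^2) * colSums(Pc^2))
  r <- ifelse(den > 0, num / den, 0)
  mean(r)
}

# mean over voxels of out-of-sample R^2
.mean_voxel_r2 <- function(Y, Yhat) {
  Yc <- sweep(Y, 2, colMeans(Y))
  mean(1 - colSums((Y - Yhat)^2) / colSums(Yc^2))
}

#' Random-search (plus optional coordinate refinement) of band penalties
#'
#' Candidates are drawn log-uniformly per band from `lambda_range` and
#' scored on held-out validation runs, averaged over inner folds; the
#' best candidate over the validation folds is selected. The default
#' score is the mean voxel-wise out-of-sample R^2 (the criterion the
#' standard banded-ridge solvers optimize); `score = "correlation"` uses
#' the mean voxel-wise Pearson correlation instead. Optional refinement
#' performs coordinate descent on log-lambdas around the winner.
#'
#' @param X_bands Named list of training design matrices.
#' @param Y Training responses.
#' @param inner_folds List of integer row-index vectors, one per
#'   validation fold (rows held out; the rest train).
#' @param n_random Number of random candidates, default 100.
#' @param refine Number of coordinate-refinement sweeps, default 0.
#' @param lambda_range Log-uniform search interval, default c(1e-3, 1e5).
#' @param score "r2" (default) or "correlation".
#' @param tie_tol Score tolerance within which stronger regularization is
#'   preferred (a one-standard-error-style tie-break; non-predictive bands
#'   are pushed toward the top of the grid instead of an arbitrary point
#'   of the flat score plateau).
#' @param seed Integer seed.
#' @return List with `lambdas` (selected), `score`, and `search_log`.
#' @export
optimize_hyperparams <- function(X_bands, Y, inner_folds, n_random = 100,
                                 refine = 0, lambda_range = c(1e-3, 1e5),
                                 score = c("r2", "correlation"),
                                 tie_tol = 1e-6, seed = 1) {
  if (length(inner_folds) < 2) stop("need at least 2 inner folds")
  if (n_random < 1) stop("empty search budget")
  score <- match.arg(score)
  scorer <- if (score == "r2") .mean_voxel_r2 else .mean_voxel_cor
  nb <- length(X_bands)
  score_cand <- function(lam) {
    mean(vapply(inner_folds, function(val_rows) {
      tr <- setdiff(seq_len(nrow(Y)), val_rows)
      fit <- fit_banded_ridge(lapply(X_bands, function(X) X[tr, , drop = FALSE]),
                              Y[tr, , drop = FALSE], lam)
      pred <- predict(fit, lapply(X_bands, function(X) X[val_rows, , drop = FALSE]))
      scorer(Y[val_rows, , drop = FALSE], pred)
    }, numeric(1)))
  }
  with_seed(seed, {
    cands <- matrix(10^stats::runif(n_random * nb,
                                    log10(lambda_range[1]),
                                    log10(lambda_range[2])),
                    n_random, nb)
    scores <- apply(cands, 1, score_cand)
    # among near-ties, prefer the most regularized candidate
    near <- which(scores >= max(scores) - tie_tol)
    best <- near[which.max(rowSums(log10(cands[near, , drop = FALSE])))]
    lam <- cands[best, ]
    sc <- scores[best]
    log_rows <- cbind(cands, score = scores)
    if (refine > 0) {
      step <- 0.5  # decades
      for (sweep_i in seq_len(refine)) {
        improved <- FALSE
        for (b in seq_len(nb)) {
          for (dir in c(-1, 1)) {
            cand <- lam
            cand[b] <- 10^(log10(lam[b]) + dir * step)
            cand[b] <- clip(cand[b], lambda_range[1], lambda_range[2])
            if (cand[b] == lam[b]) next
            s <- score_cand(cand)
            log_rows <- rbind(log_rows, c(cand, s))
            if (s > sc + tie_tol) {
              lam <- cand; sc <- s; improved <- TRUE
            } else if (dir > 0 && s > sc - tie_tol) {
              # flat plateau: accept the more regularized point
              lam <- cand; sc <- max(sc, s)
            }
          }
        }
        if (!improved) step <- step / 2
      }
    }
    list(lambdas = stats::setNames(lam, names(X_bands)), score = sc,
         search_log = log_rows)
  })
}

#' Run-wise fold assignment
#'
#' @param runs Vector of unique run labels.
#' @param n_folds Number of folds.
#' @param shuffle_seed If non-NULL, runs are shuffled (seeded) before the
#'   contiguous split.
#' @return List of run-label vectors, one per fold (the test runs).
#' @export
make_run_folds <- function(runs, n_folds, shuffle_seed = NULL) {
  runs <- unique(runs)
  if (length(runs) %% n_folds != 0) stop("runs not divisible into folds")
  if (!is.null(shuffle_seed)) runs <- with_seed(shuffle_seed, sample(runs))
  split(runs, rep(seq_len(n_folds), each = length(runs) / n_folds))
}

#' Nested run-wise cross-validation of the banded ridge model
#'
#' Outer folds hold out whole runs for testing (default 3 folds: train 8,
#' test 4 of 12 runs). Within each outer training set, feature matrices
#' are standardized with training statistics, band designs are built and
#' delayed, penalties are selected by inner run-wise cross-validation
#' (default 4 folds: train 6, validate 2), the model is refit on all
#' training runs, and held-out predictions (joint and per band) are
#' recorded.
#'
#' @param events An `event_table`.
#' @param feature_spaces Named list of `feature_space` objects (raw,
#'   unstandardized).
#' @param Y n_total_TR x voxels response matrix (rows ordered run-major as
#'   in [build_design()]).
#' @param n_tr TRs per run.
#' @param tr_s TR seconds.
#' @param n_delays Delays, default 5.
#' @param n_outer,n_inner Outer/inner fold counts, default 3 and 4.
#' @param n_random,refine,lambda_range Hyperparameter search settings,
#'   see [optimize_hyperparams()].
#' @param shuffle_seed Optional seed to shuffle run-to-fold assignment.
#' @param seed Master seed for the search.
#' @return Object of class `cv_result`: `pred` (joint prediction matrix,
#'   rows of held-out TRs), `band_pred` (list per band), `Y_test`,
#'   `fold_of_row` (outer fold per held-out row), `fits`, `lambdas`.
#' @export
cross_validate <- function(events, feature_spaces, Y, n_tr,
                           tr_s = attr(events, "tr_s") %||% 2.3,
                           n_delays = 5, n_outer = 3, n_inner = 4,
                           n_random = 100, refine = 0,
                           lambda_range = c(1e-3, 1e5),
                           score = "r2",
                           shuffle_seed = NULL, seed = 1) {
  runs <- sort(unique(events$run))
  if (length(runs) < n_outer) stop("cross-validation infeasible: fewer runs than outer folds")
  outer <- make_run_folds(runs, n_outer, shuffle_seed)
  run_of_row <- rep(runs, each = n_tr)
  nv <- ncol(Y)
  pred <- matrix(NA_real_, nrow(Y), nv)
  band_pred <- lapply(feature_spaces, function(.) matrix(NA_real_, nrow(Y), nv))
  fold_of_row <- rep(NA_integer_, nrow(Y))
  fits <- list(); lambdas <- list()
  for (k in seq_along(outer)) {
    test_runs <- outer[[k]]
    train_runs <- setdiff(runs, test_runs)
    stim <- events[events$trial_type == "stimulus", ]
    train_ids <- unique(stim$stimulus_id[stim$run %in% train_runs])
    # standardize each feature space on training stimuli only
    fs_std <- lapply(feature_spaces, function(fs) {
      tr_rows <- fs$stimulus_ids %in% train_ids
      st <- standardize(fs$X[tr_rows, , drop = FALSE],
                        fs$X[!tr_rows, , drop = FALSE])
      Xall <- matrix(0, nrow(fs$X), ncol(st$train))
      Xall[tr_rows, ] <- st$train
      Xall[!tr_rows, ] <- st$test
      feature_space(fs$name, Xall, feature_names = colnames(st$train),
                    stimulus_ids = fs$stimulus_ids)
    })
    designs <- build_design(events, fs_std, n_tr, tr_s, n_delays,
                            add_onset = TRUE)
    tr_rows <- which(run_of_row %in% train_runs)
    te_rows <- which(run_of_row %in% test_runs)
    X_tr <- lapply(designs, function(X) X[tr_rows, , drop = FALSE])
    X_te <- lapply(designs, function(X) X[te_rows, , drop = FALSE])
    inner <- make_run_folds(train_runs, n_inner)
    inner_rows <- lapply(inner, function(rs) which(run_of_row[tr_rows] %in% rs))
    opt <- optimize_hyperparams(X_tr, Y[tr_rows, , drop = FALSE], inner_rows,
                                n_random = n_random, refine = refine,
                                lambda_range = lambda_range, score = score,
                                seed = derive_seed(seed, paste0("fold", k)))
    fit <- fit_banded_ridge(X_tr, Y[tr_rows, , drop = FALSE], opt$lambdas)
    pb <- predict(fit, X_te, per_band = TRUE)
    pred[te_rows, ] <- pb$joint
    for (b in names(band_pred)) band_pred[[b]][te_rows, ] <- pb$bands[[b]]
    fold_of_row[te_rows] <- k
    fits[[k]] <- fit
    lambdas[[k]] <- opt$lambdas
  }
  structure(list(pred = pred, band_pred = band_pred, Y = Y,
                 fold_of_row = fold_of_row, fits = fits,
                 lambdas = lambdas, outer_folds = outer),
            class = "cv_result")
}
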