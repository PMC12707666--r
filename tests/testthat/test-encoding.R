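# Encoding stage: design construction, standardization, denoising, banded
# ridge, hyperparameter search and nested cross-validation.

simple_events <- function(onsets_tr, ids, run = 1, tr_s = 2.3) {
  ev <- data.frame(run = run, session = 1, onset_s = onsets_tr * tr_s,
                   duration_s = tr_s, stimulus_id = ids,
                   trial_type = "stimulus")
  attr(ev, "tr_s") <- tr_s
  class(ev) <- c("event_table", "data.frame")
  ev
}

unit_fs <- function(ids, p = 1) {
  feature_space("unit", matrix(seq_along(ids), length(ids), p),
                feature_names = paste0("f", seq_len(p)), stimulus_ids = ids)
}

test_that("design places delayed impulses where the oracle says", {
  # one stimulus at TR 0, one unit feature, 5 delays -> rows 2..6 carry it
  fs <- feature_space("u", matrix(1, 1, 1), "f", "s1")
  X <- build_design(simple_events(0, "s1"), list(u = fs), n_tr = 12)[[1]]
  expect_equal(dim(X), c(12, 5))
  for (d in 1:5) {
    expect_equal(which(X[, d] != 0), 1 + d)
  }
  # linearity: two disjoint stimuli superpose
  fs2 <- feature_space("u", matrix(c(1, 2), 2, 1), "f", c("s1", "s2"))
  X12 <- build_design(simple_events(c(0, 6), c("s1", "s2")),
                      list(u = fs2), n_tr = 16)[[1]]
  X1 <- build_design(simple_events(0, "s1"), list(u = fs2), n_tr = 16)[[1]]
  X2 <- build_design(simple_events(6, "s2"), list(u = fs2), n_tr = 16)[[1]]
  expect_equal(X12, X1 + X2)
  # random schedule vs an impulse-train convolution oracle
  set.seed(12)
  on <- sort(sample(0:40, 8))
  ids <- sprintf("s%d", seq_along(on))
  fsr <- feature_space("u", matrix(rnorm(8), 8, 1), "f", ids)
  Xr <- build_design(simple_events(on, ids), list(u = fsr), n_tr = 50)[[1]]
  stick <- numeric(50); stick[on + 1] <- fsr$X[, 1]
  for (d in 1:5) {
    oracle <- c(rep(0, d), stick)[1:50]
    expect_equal(Xr[, d], oracle)
  }
  # blank/target trials contribute nothing
  evb <- simple_events(c(0, 6), c("s1", NA))
  evb$trial_type <- c("stimulus", "blank")
  Xb <- build_design(evb, list(u = fs), n_tr = 16)[[1]]
  expect_equal(sum(Xb != 0), 5)
  expect_error(build_design(simple_events(30, "s1"), list(u = fs), n_tr = 10),
               "beyond run length")
  expect_error(build_design(simple_events(0, "sX"), list(u = fs), n_tr = 10),
               "missing stimulus")
})

test_that("standardization uses training statistics only", {
  set.seed(5)
  tr <- matrix(rnorm(60), 20, 3); te <- matrix(rnorm(30), 10, 3)
  st <- standardize(tr, tr)
  expect_equal(unname(colMeans(st$test)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(st$test, 2, sd)), rep(1, 3), tolerance = 1e-12)
  # test = train + c -> test mean = c / train_sd
  st2 <- standardize(tr, tr + 2)
  expect_equal(unname(colMeans(st2$test)), unname(2 / apply(tr, 2, sd)),
               tolerance = 1e-12)
  # leakage probe: pooled statistics differ from train-only statistics
  st3 <- standardize(tr, te)
  pooled <- standardize(rbind(tr, te))$train
  expect_false(isTRUE(all.equal(st3$test, pooled[21:30, ])))
  expect_warning(standardize(cbind(tr, 0)), "zero-variance")
})

test_that("denoising is an exact projection", {
  set.seed(8)
  n <- 60
  nuis <- cbind(onset_hrf_regressor(c(10, 50, 90) , n), rnorm(n))
  # Y in the regressor span -> residual ~ 0
  Y_in <- nuis %*% matrix(rnorm(2 * 4), 2, 4) + 0.5
  expect_lt(max(abs(denoise_timeseries(Y_in, nuis))), 1e-8 * max(abs(Y_in)))
  # Y orthogonal to the span -> unchanged
  Q <- qr.Q(qr(cbind(1, nuis)), complete = TRUE)[, 4:10]
  Y_orth <- Q %*% matrix(rnorm(7 * 3), 7, 3)
  expect_equal(denoise_timeseries(Y_orth, nuis), Y_orth, tolerance = 1e-9)
  # random Y vs an lm()-based least-squares oracle
  Y <- matrix(rnorm(n * 3), n, 3)
  res <- denoise_timeseries(Y, nuis)
  res_lm <- residuals(lm(Y ~ nuis))
  expect_equal(res, res_lm, tolerance = 1e-9, ignore_attr = TRUE)
  # rank-deficient regressors are tolerated
  expect_silent(denoise_timeseries(Y, cbind(nuis, nuis[, 1])))
})

test_that("banded ridge matches closed-form oracles", {
  set.seed(21)
  X <- random_band_designs(80, c(6), c("a", "b"), seed = 21)
  Y <- matrix(rnorm(80 * 4), 80, 4)
  # equal lambdas == ordinary ridge on the concatenation
  fit <- fit_banded_ridge(X, Y, c(3, 3))
  Xc <- cbind(X$a, X$b)
  W_or <- solve(crossprod(Xc) + 3 * diag(12), crossprod(Xc, Y))
  expect_lt(max(abs(rbind(fit$W$a, fit$W$b) - W_or)), 1e-8)
  # huge lambda kills one band
  fit2 <- fit_banded_ridge(X, Y, c(1, 1e12))
  ref <- sqrt(sum(fit_banded_ridge(X, Y, c(1, 1e-9))$W$b^2))
  expect_lt(sqrt(sum(fit2$W$b^2)), 1e-6 * ref)
  # noiseless recovery in the lambda -> 0 limit
  W_true <- list(a = matrix(rnorm(6 * 4), 6, 4), b = matrix(rnorm(6 * 4), 6, 4))
  Y0 <- X$a %*% W_true$a + X$b %*% W_true$b
  fit0 <- fit_banded_ridge(X, Y0, c(1e-12, 1e-12))
  expect_lt(max(abs(fit0$W$a - W_true$a)) / max(abs(W_true$a)), 1e-6)
  # adding an all-zero band leaves joint predictions unchanged
  X3 <- c(X, list(z = matrix(0, 80, 5)))
  fit3 <- fit_banded_ridge(X3, Y, c(3, 3, 1))
  expect_equal(predict(fit3, X3), predict(fit, X), tolerance = 1e-8)
  expect_error(fit_banded_ridge(X, Y, c(1, -1)), "positive")
  expect_error(fit_banded_ridge(X, Y[1:10, ], c(1, 1)), "mismatch")
})

test_that("hyperparameter search is deterministic and penalizes noise bands", {
  set.seed(31)
  n <- 120
  X <- random_band_designs(n, 5, c("sig", "noise"), seed = 31)
  W <- matrix(rnorm(5 * 6), 5, 6)
  Y <- X$sig %*% W + 0.5 * matrix(rnorm(n * 6), n, 6)
  folds <- split(seq_len(n), rep(1:3, each = n / 3))
  o1 <- optimize_hyperparams(X, Y, folds, n_random = 10, seed = 7)
  o2 <- optimize_hyperparams(X, Y, folds, n_random = 10, seed = 7)
  expect_identical(o1$lambdas, o2$lambdas)
  # a single candidate is returned unchanged
  o3 <- optimize_hyperparams(X, Y, folds, n_random = 1, seed = 3)
  expect_equal(unname(o3$lambdas), unname(o3$search_log[1, 1:2]))
  expect_error(optimize_hyperparams(X, Y, folds, n_random = 0), "budget")
  expect_error(optimize_hyperparams(X, Y, folds[1], n_random = 2), "2 inner")
  # the pure-noise band lands in the top decade in >= 90 percent of replicates
  hits <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    nn <- 200
    Xs <- list(sig = matrix(rnorm(nn * 5), nn),
               noise = matrix(rnorm(nn * 40), nn))
    Ws <- matrix(rnorm(5 * 3), 5, 3)
    Ys <- Xs$sig %*% Ws + 0.3 * matrix(rnorm(nn * 3), nn, 3)
    fl <- split(seq_len(nn), rep(1:4, each = nn / 4))
    opt <- optimize_hyperparams(Xs, Ys, fl, n_random = 16, refine = 6,
                                lambda_range = c(1e-2, 1e4),
                                tie_tol = 1e-4, seed = s)
    log10(opt$lambdas["noise"]) >= 3
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # refinement never decreases the selected score
  o_ref <- optimize_hyperparams(X, Y, folds, n_random = 5, refine = 2, seed = 7)
  o_base <- optimize_hyperparams(X, Y, folds, n_random = 5, refine = 0, seed = 7)
  expect_gte(o_ref$score, o_base$score)
})

test_that("nested cross-validation is leak-free and exact on noiseless data", {
  tr_s <- 2.3
  n_runs <- 6; n_tr <- 40
  set.seed(41)
  ids <- sprintf("s%02d", 1:12)
  pool_runs <- rep(1:3, each = 4)  # 3 run-sets of 4 stimuli, 2 sessions
  ev <- do.call(rbind, lapply(1:n_runs, function(r) {
    set_ids <- ids[pool_runs == ((r - 1) %% 3) + 1]
    ons <- seq(2, by = 3, length.out = 2 * length(set_ids))
    simple_events(ons, rep(set_ids, 2), run = r)
  }))
  attr(ev, "tr_s") <- tr_s
  class(ev) <- c("event_table", "data.frame")
  fs <- list(
    a = feature_space("a", matrix(rnorm(12 * 3), 12, 3),
                      paste0("a", 1:3), ids),
    b = feature_space("b", matrix(rnorm(12 * 2), 12, 2),
                      paste0("b", 1:2), ids))
  # noiseless generative data through the same standardization path
  fs_std <- lapply(fs, function(f) {
    st <- standardize(f$X)
    feature_space(f$name, st$train, colnames(st$train), f$stimulus_ids)
  })
  designs <- build_design(ev, fs_std, n_tr, tr_s)
  gt <- make_ground_truth(designs, 8, c(0.6, 0.4), noise_sd = 0, seed = 2)
  Y <- simulate_bold(designs, gt)
  cv <- cross_validate(ev, fs, Y, n_tr, tr_s, n_outer = 3, n_inner = 2,
                       n_random = 6, lambda_range = c(1e-7, 1e-5), seed = 5)
  # every run tested exactly once
  expect_true(all(!is.na(cv$pred)))
  expect_equal(sort(unique(cv$fold_of_row)), 1:3)
  run_of_row <- rep(1:n_runs, each = n_tr)
  for (k in 1:3) {
    expect_equal(length(unique(run_of_row[cv$fold_of_row == k])), 2)
  }
  # noiseless joint accuracy r = 1 (on TRs with any signal present)
  acc <- accuracy(cv$Y, cv$pred, cv$fold_of_row)
  expect_true(all(acc$r > 1 - 1e-6))
  # leakage probe: perturbing test-run data leaves training weights alone
  Y2 <- Y
  test_rows_f1 <- which(cv$fold_of_row == 1)
  Y2[test_rows_f1, ] <- Y2[test_rows_f1, ] + 5
  cv2 <- cross_validate(ev, fs, Y2, n_tr, tr_s, n_outer = 3, n_inner = 2,
                        n_random = 6, lambda_range = c(1e-7, 1e-5), seed = 5)
  expect_equal(cv2$fits[[1]]$W, cv$fits[[1]]$W, tolerance = 1e-12)
  expect_error(cross_validate(ev[ev$run == 1, ], fs, Y[1:n_tr, ], n_tr,
                              tr_s, n_outer = 3),
               "infeasible")
})
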