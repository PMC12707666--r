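# End-to-end pipeline: simulate -> features -> fit -> partition -> group,
# driven by a single config whose defaults reproduce the experimental
# design constants (12 runs over 2 sessions, 20 stimuli per run repeated
# 3 times plus 3 targets and 3 blanks, TR 2.3 s, 5 delays).

#' Pipeline configuration
#'
#' Defaults encode the experimental design constants; override any field.
#' The configuration round-trips through JSON unchanged.
#'
#' @param ... Named overrides of the default fields.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_possible = 60, n_impossible = 60, n_actors = 17,
    actions = dynbody_actions(),
    n_runs = 12, sessions = 2, stimuli_per_run = 20, reps = 3,
    n_targets = 3, n_blanks = 3,
    tr_s = 2.3, n_delays = 5, fps = 30,
    min_frames = 60, max_frames = 90,
    image_h = 128, image_w = 64, pixels_per_degree = 128 / 4.32,
    moten_orientations = c(0, 45, 90, 135),
    moten_spatial_freqs = c(0.5, 1, 2, 4, 8),
    moten_temporal_freqs = c(1, 2, 4, 8, 16),
    n_voxels = 200, n_subjects = 11,
    band_fractions = c(kp3d = 0.20, categorical = 0.125,
                       simdist = 0.30, moten = 0.375),
    snr = 0.111,
    n_outer = 3, n_inner = 4, n_random = 100, refine = 0,
    lambda_range = c(1e-3, 1e5),
    manifold_max_samples = 500
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Validate a pipeline configuration
#'
#' Fails fast on infeasible settings (e.g. too few runs for the
#' cross-validation scheme).
#' @param config A `pipeline_config`.
#' @return Invisibly TRUE.
#' @export
validate_config <- function(config) {
  with(config, {
    if (n_runs %% sessions != 0) stop("n_runs must divide into sessions")
    rps <- n_runs / sessions
    if (n_runs %% n_outer != 0 || n_runs < n_outer * 2) {
      stop("cross-validation infeasible: cannot split ", n_runs,
           " runs into ", n_outer, " outer folds of train/test runs")
    }
    train_runs <- n_runs - n_runs / n_outer
    if (train_runs %% n_inner != 0) {
      stop("cross-validation infeasible: ", train_runs,
           " training runs not divisible into ", n_inner, " inner folds")
    }
    if ((n_possible + n_impossible) %% (rps * stimuli_per_run) != 0) {
      stop("stimulus pool does not partition into run-sets")
    }
    if (any(band_fractions < 0) || sum(band_fractions) > 1 + 1e-12) {
      stop("band_fractions must be nonnegative with sum <= 1")
    }
  })
  invisible(TRUE)
}

#' Serialize / load a pipeline config as JSON
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$band_fractions <- as.list(cfg$band_fractions)  # keep names in JSON
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$band_fractions <- unlist(raw$band_fractions)
  do.call(pipeline_config, raw)
}

#' Simulate the stimulus set of a config
#'
#' Possible trajectories cycle over actions and actors (actor stature
#' scales the skeleton); each impossible stimulus is the mirrored twin of
#' its possible counterpart.
#'
#' @param config A `pipeline_config`.
#' @return List with `skeletons` (per actor), `trajectories` (named list,
#'   pos_*/imp_*), `pool` (stimulus data.frame).
#' @export
simulate_stimulus_set <- function(config) {
  pool <- stimulus_pool(config$n_possible, config$n_impossible)
  scales <- with_seed(derive_seed(config$seed, "actors"),
                      stats::runif(config$n_actors, 0.9, 1.1))
  trajectories <- list()
  for (i in seq_len(config$n_possible)) {
    action <- config$actions[((i - 1) %% length(config$actions)) + 1]
    actor <- ((i - 1) %% config$n_actors) + 1
    sk <- movi_skeleton(actor_scale = scales[actor])
    frames <- with_seed(derive_seed(config$seed, paste0("dur", i)), {
      sample(config$min_frames:config$max_frames, 1)
    })
    tr <- simulate_possible_trajectory(
      sk, action, frames, seed = derive_seed(config$seed, paste0("traj", i)),
      fps = config$fps)
    trajectories[[sprintf("pos_%02d", i)]] <- tr
    trajectories[[sprintf("imp_%02d", i)]] <- make_impossible(tr)
  }
  list(trajectories = trajectories[pool$stimulus_id], pool = pool)
}

#' Compute the four feature spaces for a stimulus set
#'
#' @param stimuli Output of [simulate_stimulus_set()].
#' @param config A `pipeline_config`.
#' @param render If FALSE, skip the motion-energy band (no videos
#'   rendered).
#' @return Named list of `feature_space` objects.
#' @export
compute_feature_spaces <- function(stimuli, config, render = TRUE) {
  trajs <- stimuli$trajectories
  sk <- trajs[[1]]$skeleton
  keypoints <- lapply(trajs, function(tr) forward_kinematics(tr$skeleton, tr))
  fs <- list()
  fs$kp3d <- extract_kp3d(keypoints, sk)
  fs$categorical <- categorical_features(
    stats::setNames(stimuli$pool$plausibility, stimuli$pool$stimulus_id))
  possible <- trajs[stimuli$pool$stimulus_id[
    stimuli$pool$plausibility == "possible"]]
  manifold <- build_manifold(possible,
                             max_samples = config$manifold_max_samples,
                             seed = derive_seed(config$seed, "manifold"))
  fs$simdist <- simdist_features(trajs, manifold)
  if (render) {
    bank <- build_filter_bank(
      config$image_h, config$image_w, config$pixels_per_degree,
      fps = config$fps, orientations = config$moten_orientations,
      spatial_freqs = config$moten_spatial_freqs,
      temporal_freqs = config$moten_temporal_freqs)
    videos <- lapply(seq_along(trajs), function(i) {
      kp <- keypoints[[i]]
      # center the figure on the fixation point
      ctr <- apply(kp, 3, mean)
      render_stick_video(kp, skeleton_bones(sk),
                         image_h = config$image_h, image_w = config$image_w,
                         center_world = ctr)
    })
    names(videos) <- names(trajs)
    fs$moten <- moten_features(videos, bank)
  }
  fs
}

#' Run the full pipeline
#'
#' Stages: simulate (stimuli + events), features (four feature spaces),
#' fit (synthetic BOLD from the generative twin + nested-CV banded
#' ridge), partition (accuracy and variance fractions), group
#' (multi-subject maps + sign-flip permutation + FDR). Each stage writes
#' its outputs under `out_dir/<stage>/` (written to a temporary directory
#' first and moved into place on success, so failed stages leave only a
#' quarantined `<stage>.failed/`), and a `manifest.json` records seeds,
#' hashes and timings.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory.
#' @param stages Subset of c("simulate","features","fit","partition",
#'   "group"); later stages require earlier ones in the same call.
#' @param render Render videos for the motion-energy band (default TRUE).
#' @return Invisibly, a list of in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "features", "fit",
                                    "partition", "group"),
                         render = TRUE) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("dynbody")),
                   seed = config$seed, stages = list())
  state <- list(config = config)
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    tmp <- file.path(out_dir, paste0(name, ".tmp"))
    final <- file.path(out_dir, name)
    unlink(tmp, recursive = TRUE)
    dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
    ok <- tryCatch({ fun(tmp); TRUE }, error = function(e) {
      file.rename(tmp, file.path(out_dir, paste0(name, ".failed")))
      stop(sprintf("stage '%s' failed (partial outputs quarantined): %s",
                   name, conditionMessage(e)), call. = FALSE)
    })
    unlink(final, recursive = TRUE)
    file.rename(tmp, final)
    files <- list.files(final, full.names = TRUE, recursive = TRUE)
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      files = as.list(tools::md5sum(files)))
    message(sprintf("[dynbody] stage %-9s done in %6.1fs", name,
                    manifest$stages[[name]]$seconds))
  }

  if ("simulate" %in% stages) run_stage("simulate", function(dir) {
    state$stimuli <<- simulate_stimulus_set(config)
    state$events <<- make_event_schedule(
      stimulus_pool(config$n_possible, config$n_impossible),
      n_runs = config$n_runs, sessions = config$sessions,
      stimuli_per_run = config$stimuli_per_run, reps = config$reps,
      n_targets = config$n_targets, n_blanks = config$n_blanks,
      tr_s = config$tr_s, seed = derive_seed(config$seed, "schedule"))
    write_events(state$events, file.path(dir, "events.tsv"))
  })

  if ("features" %in% stages) run_stage("features", function(dir) {
    state$feature_spaces <<- compute_feature_spaces(state$stimuli, config,
                                                    render = render)
    for (fs in state$feature_spaces) {
      write_features(fs, file.path(dir, paste0(fs$name, ".tsv")))
    }
  })

  if ("fit" %in% stages) run_stage("fit", function(dir) {
    n_tr <- attr(state$events, "n_tr")
    fs_std <- lapply(state$feature_spaces, function(fs) {
      st <- standardize(fs$X)
      feature_space(fs$name, st$train, colnames(st$train), fs$stimulus_ids)
    })
    designs <- build_design(state$events, fs_std, n_tr, config$tr_s,
                            config$n_delays)
    gt <- make_ground_truth(designs, config$n_voxels,
                            config$band_fractions[names(designs)],
                            snr = config$snr,
                            seed = derive_seed(config$seed, "weights"))
    state$ground_truth <<- gt
    Y <- simulate_bold(designs, gt, runs = attr(designs[[1]], "runs"),
                       seed = derive_seed(config$seed, "noise"))
    state$Y <<- Y
    state$cv <<- cross_validate(
      state$events, state$feature_spaces, Y, n_tr, config$tr_s,
      config$n_delays, n_outer = config$n_outer, n_inner = config$n_inner,
      n_random = config$n_random, refine = config$refine,
      lambda_range = config$lambda_range,
      seed = derive_seed(config$seed, "cv"))
    write_timeseries(Y, file.path(dir, "bold.tsv"))
    jsonlite::write_json(lapply(state$cv$lambdas, as.list),
                         file.path(dir, "lambdas.json"), auto_unbox = TRUE)
  })

  if ("partition" %in% stages) run_stage("partition", function(dir) {
    cv <- state$cv
    acc <- accuracy(cv$Y, cv$pred, cv$fold_of_row)
    part <- partial_contribution(cv$Y, cv$band_pred)
    state$accuracy <<- acc
    state$partition <<- part
    df <- data.frame(voxel = seq_along(acc$r), r_joint = acc$r,
                     R2_joint = part$R2_joint, t(part$fraction),
                     check.names = FALSE)
    # the composite needs all four bands (no moten when render = FALSE)
    if (all(c("kp3d", "categorical", "simdist", "moten") %in%
              rownames(part$fraction))) {
      fr <- part$fraction
      fr[is.na(fr)] <- 0
      comp <- hsv_composite(fr, acc$r)
      df$H <- comp$H; df$S <- comp$S; df$V <- comp$V
      state$composite <<- comp
    }
    .write_tsv(df, file.path(dir, "maps.tsv"))
    manifest$joint_r_mean <<- mean(acc$r)
  })

  if ("group" %in% stages) run_stage("group", function(dir) {
    # per-subject maps: shared signal, subject-specific noise draws
    n_tr <- attr(state$events, "n_tr")
    maps <- t(vapply(seq_len(config$n_subjects), function(s) {
      fs_std <- lapply(state$feature_spaces, function(fs) {
        st <- standardize(fs$X)
        feature_space(fs$name, st$train, colnames(st$train), fs$stimulus_ids)
      })
      designs <- build_design(state$events, fs_std, n_tr, config$tr_s,
                              config$n_delays)
      Ys <- simulate_bold(designs, state$ground_truth,
                          runs = attr(designs[[1]], "runs"),
                          seed = derive_seed(config$seed, paste0("subj", s)))
      cvs <- cross_validate(state$events, state$feature_spaces, Ys, n_tr,
                            config$tr_s, config$n_delays,
                            n_outer = config$n_outer,
                            n_inner = config$n_inner,
                            n_random = max(4, config$n_random %/% 10),
                            lambda_range = config$lambda_range,
                            seed = derive_seed(config$seed, paste0("cvs", s)))
      accuracy(cvs$Y, cvs$pred, cvs$fold_of_row)$r
    }, numeric(config$n_voxels)))
    perm <- signflip_permutation(maps,
                                 seed = derive_seed(config$seed, "perm"))
    df <- data.frame(voxel = seq_len(ncol(maps)),
                     mean_r = perm$observed, p = perm$p, q = perm$q)
    .write_tsv(df, file.path(dir, "group.tsv"))
    manifest$n_permutations <<- perm$n_permutations
    state$group <<- perm
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  state$manifest <- manifest
  invisible(state)
}
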