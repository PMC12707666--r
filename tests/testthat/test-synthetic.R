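# synthetic_data module: skeleton, trajectories, mirroring, forward
# kinematics, rendering, schedules and BOLD generation.

test_that("default skeleton has 71 joints, 56 rotating, and a valid tree", {
  sk <- movi_skeleton()
  expect_equal(n_joints(sk), 71)
  expect_equal(sum(sk$rotating), 56)
  expect_equal(sum(!sk$rotating), 15)
  expect_equal(sk$joint_names[sk$root], "root")
  # every non-root joint has a parent that appears earlier in topo order
  pos <- match(seq_len(71), sk$topo_order)
  ok <- vapply(seq_len(71), function(j) {
    p <- sk$parent_index[j]
    is.na(p) || pos[p] < pos[j]
  }, TRUE)
  expect_true(all(ok))
})

test_that("cyclic or malformed skeletons are rejected", {
  df <- data.frame(name = c("a", "b"), parent = c("b", "a"),
                   dx = 1, dy = 0, dz = 0, rotating = TRUE,
                   flexion_axis = NA, group = "g")
  expect_error(skeleton(df), "root")
  df3 <- data.frame(name = c("r", "a", "b"), parent = c(NA, "b", "a"),
                    dx = c(0, 1, 1), dy = 0, dz = 0, rotating = TRUE,
                    flexion_axis = NA, group = "g")
  expect_error(skeleton(df3), "cyclic")
})

test_that("trajectory generator is deterministic and respects limits", {
  sk <- movi_skeleton()
  t1 <- simulate_possible_trajectory(sk, "wave", 70, seed = 11)
  t2 <- simulate_possible_trajectory(sk, "wave", 70, seed = 11)
  expect_identical(t1$euler, t2$euler)
  expect_error(simulate_possible_trajectory(sk, "flyy", 70), "unknown action")
  expect_error(simulate_possible_trajectory(sk, "kick", 50), "60")
  # zero amplitude -> static pose
  ts <- simulate_possible_trajectory(sk, "kick", 60, seed = 1,
                                     amplitude_scale = 0)
  expect_true(all(ts$euler == 0))
  # elbow/knee flexion never below the anatomical limit over a seed sweep
  flex <- which(!is.na(sk$flexion_axis))
  ord <- strsplit(sk$rotation_order, "")[[1]]
  mins <- vapply(1:100, function(s) {
    tr <- simulate_possible_trajectory(sk, "kick", 60, seed = s)
    min(vapply(flex, function(j) {
      min(tr$euler[, j, match(sk$flexion_axis[j], ord)])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(mins >= 0))
})

test_that("forward kinematics matches the independent path-composition oracle", {
  sk <- movi_skeleton()
  tr <- simulate_possible_trajectory(sk, "jump", 60, seed = 5)
  kp <- forward_kinematics(sk, tr)
  for (f in c(1, 30, 60)) {
    expect_equal(kp[f, , ], fk_oracle(sk, tr$euler[f, , ]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # identity pose: positions are cumulative offsets along each chain
  tr0 <- simulate_possible_trajectory(sk, "kick", 60, seed = 1,
                                      amplitude_scale = 0)
  kp0 <- forward_kinematics(sk, tr0)
  expect_equal(kp0[1, , ], fk_oracle(sk, tr0$euler[1, , ] * 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  # 90-degree rotation about z with offset (1,0,0) sends the tip to (0,1,0)
  ch <- tiny_chain(c(1, 0, 0))
  e <- array(0, c(1, 2, 3)); e[1, 1, 1] <- 90  # ZXY: first channel is Z
  kp1 <- forward_kinematics(ch, e)
  expect_equal(drop(kp1[1, 2, ]), c(0, 1, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("mirroring reverses elbow/knee flexion and preserves end-effectors", {
  sk <- movi_skeleton()
  tr <- simulate_possible_trajectory(sk, "point", 64, seed = 9)
  im <- make_impossible(tr)
  expect_equal(im$plausibility, "impossible")
  flex <- which(!is.na(sk$flexion_axis))
  ord <- strsplit(sk$rotation_order, "")[[1]]
  for (j in flex) {
    ch <- match(sk$flexion_axis[j], ord)
    expect_equal(im$euler[, j, ch], -tr$euler[, j, ch])
  }
  # involution on the mirrored joints
  back <- make_impossible(joint_trajectory(im$euler, sk,
                                           plausibility = "possible"))
  expect_equal(back$euler[, flex, ], tr$euler[, flex, ], tolerance = 1e-8)
  # fixed point: zero elbow/knee rotation
  e0 <- tr$euler
  e0[, flex, ] <- 0
  tr0 <- joint_trajectory(e0, sk, plausibility = "possible")
  im0 <- make_impossible(tr0)
  expect_equal(im0$euler, tr0$euler, tolerance = 1e-8)
  # end-effector world orientations match the original (FK oracle)
  for (f in c(1, 32, 64)) {
    for (jn in c("l_hand", "r_hand", "l_foot", "r_foot")) {
      R0 <- world_rotation_oracle(sk, tr$euler[f, , ], jn)
      R1 <- world_rotation_oracle(sk, im$euler[f, , ], jn)
      dev <- matrix_to_axis_angle(t(R0) %*% R1)
      expect_lt(sqrt(sum(dev^2)), 1e-6)
    }
  }
})

test_that("stick-figure rendering projects and shifts linearly", {
  sk <- movi_skeleton()
  tr <- simulate_possible_trajectory(sk, "wave", 60, seed = 2)
  kp <- forward_kinematics(sk, tr)
  bones <- skeleton_bones(sk)
  # static pose -> identical frames
  kps <- kp; for (f in 2:dim(kps)[1]) kps[f, , ] <- kps[1, , ]
  vid_s <- render_stick_video(kps, bones, 64, 32)
  expect_true(all(vid_s[1, , ] == vid_s[30, , ]))
  expect_true(min(vid_s) >= 0 && max(vid_s) <= 1)
  # translate +x -> centroid shifts right proportionally
  ppm <- 64 / 2.2
  kp_t <- kp; kp_t[, , 1] <- kp_t[, , 1] + 0.2
  v0 <- render_stick_video(kp, bones, 64, 32, pixels_per_meter = ppm)
  v1 <- render_stick_video(kp_t, bones, 64, 32, pixels_per_meter = ppm)
  cx <- function(img) sum(t(img) * ((1:32) - 0.5)) / sum(img)
  expect_equal(cx(v1[1, , ]) - cx(v0[1, , ]), 0.2 * ppm, tolerance = 0.35)
  # moving clip has higher temporal pixel variance than a static one
  vid_m <- render_stick_video(kp, bones, 64, 32)
  tv <- function(v) sum(apply(v, c(2, 3), var))
  expect_gt(tv(vid_m), tv(vid_s) + 1)
  expect_error(render_stick_video(kp, bones, 1, 0), "degenerate")
})

test_that("event schedules satisfy the printed design constraints", {
  ev <- make_event_schedule(seed = 4)
  expect_equal(length(unique(ev$run)), 12)
  per_run <- table(ev$run[ev$trial_type != "blank"])
  expect_true(all(per_run == 63))
  expect_true(all(table(ev$run[ev$trial_type == "stimulus"]) == 60))
  # each stimulus appears 6 times in total (3 reps x 2 sessions)
  counts <- table(ev$stimulus_id[ev$trial_type == "stimulus"])
  expect_equal(length(counts), 120)
  expect_true(all(counts == 6))
  # sessions share run content
  s1 <- sort(unique(ev$stimulus_id[ev$run == 3 & ev$trial_type == "stimulus"]))
  s2 <- sort(unique(ev$stimulus_id[ev$run == 9 & ev$trial_type == "stimulus"]))
  expect_identical(s1, s2)
  # onsets strictly increasing within run, ISI in {2,3,4} TRs
  tr_s <- attr(ev, "tr_s")
  for (r in unique(ev$run)) {
    on <- ev$onset_s[ev$run == r] / tr_s
    expect_true(all(diff(on) > 0))
    expect_true(all(round(diff(on) - 1, 6) %in% 2:4))
  }
  # reduced schedule: one rep, no targets/blanks -> 20 trials per run
  ev1 <- make_event_schedule(reps = 1, n_targets = 0, n_blanks = 0, seed = 1)
  expect_true(all(table(ev1$run) == 20))
  expect_error(make_event_schedule(stimulus_pool(55, 60)), "partition")
})

test_that("simulated BOLD follows the generative linear model", {
  X <- random_band_designs(400, 6, c("a", "b"), seed = 3)
  # noiseless single band: Y is exactly X W
  gt0 <- make_ground_truth(X["a"], 5, 1, noise_sd = 0, seed = 1)
  Y0 <- simulate_bold(X["a"], gt0)
  expect_equal(unclass(Y0)[, ], X$a %*% gt0$band_weights$a,
               ignore_attr = TRUE)
  # zero weights: pure noise with sd within 5 percent at 1e4 samples
  gt_n <- make_ground_truth(X, 25, c(0, 0), noise_sd = 1.3, seed = 2)
  Yn <- simulate_bold(X, gt_n)
  expect_equal(sd(as.numeric(Yn)), 1.3, tolerance = 0.05)
  # requested variance fractions are realized empirically
  Xl <- random_band_designs(10000, 8, c("a", "b", "c", "d"), seed = 4)
  fr <- c(0.5, 0.3, 0.2, 0)
  gt <- make_ground_truth(Xl, 10, fr, snr = 1e6, seed = 5)
  Yf <- simulate_bold(Xl, gt)
  bs <- attr(Yf, "band_signals")
  v <- vapply(bs, function(S) mean(apply(S, 2, var)), numeric(1))
  expect_equal(unname(v / sum(v)), fr, tolerance = 0.02)
  # determinism and dimension checks
  expect_identical(simulate_bold(X, gt_n), simulate_bold(X, gt_n))
  expect_error(simulate_bold(X["a"], gt_n), "mismatch|length")
  expect_error(make_ground_truth(X, 5, c(0.8, 0.9)), "sum")
})
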