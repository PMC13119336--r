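test_that("label runs split at noise, missing frames and trial boundaries", {
  trials <- trial_structure(n_trials = 2, practice_s = 0.05, rest_s = 0.025,
                            fps = 120)  # 6 practice + 3 rest frames per trial
  # trial 1 practice frames 0..5, trial 2 practice frames 9..14
  lab <- rep(NA_integer_, trials$n_frames)
  lab[1:6] <- c(2L, 2L, 2L, -1L, 2L, 2L)
  lab[10:15] <- c(2L, 2L, 0L, 0L, NA, 0L)
  runs <- label_runs(lab, trials)
  expect_equal(nrow(runs), 5)
  r1 <- runs[runs$trial == 1, ]
  expect_equal(r1$start_frame, c(0, 4))
  expect_equal(r1$end_frame, c(3, 6))
  # the label-2 run continuing from trial 1 into trial 2 is split
  r2 <- runs[runs$trial == 2, ]
  expect_equal(r2$label, c(2, 0, 0))
  expect_equal(r2$start_frame[1], 9)
  # all-noise trial yields nothing
  lab[10:15] <- -1L
  expect_equal(sum(label_runs(lab, trials)$trial == 2), 0)
})

test_that("occurrence kinematics reproduce count, rate and duration", {
  fps <- 120
  trials <- trial_structure(n_trials = 1, practice_s = 2, rest_s = 0.5,
                            fps = fps)
  lab <- rep(-1L, trials$n_frames)
  # one occurrence of 840 ms (101 frames ~ frames 24..124)
  lab[25:(24 + round(0.84 * fps))] <- 0L
  runs <- label_runs(lab, trials)
  t0 <- 24 / fps * 1000
  log <- data.frame(t_ms = t0 + seq(50, 800, length.out = 5),
                    key = c(4L, 1L, 3L, 2L, 4L), trial = 1L)
  ser <- simulate_session(session_config(n_trials = 1, practice_s = 2,
                                         rest_s = 0.5, seed = 1))$series
  occ <- occurrence_kinematics(runs, ser, log)
  expect_equal(occ$kp_count, 5)
  expect_equal(occ$duration_s, 0.84, tolerance = 0.01)
  expect_equal(occ$kp_rate, 5 / 0.84, tolerance = 0.05)  # ~6 kp/s
  expect_equal(occ$key_string, "4-1-3-2-4")
  # zero-keypress occurrence
  occ0 <- occurrence_kinematics(runs, ser,
                                data.frame(t_ms = numeric(0),
                                           key = integer(0),
                                           trial = integer(0)))
  expect_equal(occ0$kp_count, 0)
  expect_equal(occ0$kp_rate, 0)
})

test_that("overlap fraction equals the brute-force frame count", {
  fps <- 120
  n <- 240
  pos <- array(0, c(n, 4, 2))
  # digits 1 and 2 ramp together during frames 61..120 (half of the 1-s
  # interval 61..180 at 2 px/frame) and then hold still: overlap 0.5
  pos[61:120, 1, 1] <- cumsum(rep(2, 60))
  pos[121:n, 1, 1] <- pos[120, 1, 1]
  pos[61:120, 2, 2] <- cumsum(rep(2, 60))
  pos[121:n, 2, 2] <- pos[120, 2, 2]
  ser <- pose_series(pos, matrix(1, n, 4), fps = fps)
  occ <- data.frame(label = 0L, trial = 1L, start_frame = 60L,
                    end_frame = 180L)
  log <- data.frame(t_ms = numeric(0), key = integer(0), trial = integer(0))
  got <- occurrence_kinematics(occ, ser, log, move_threshold = 1)
  sp <- rbind(0, sqrt(apply(diff(pos[, , 1]), c(1, 2), identity)^2 +
                        apply(diff(pos[, , 2]), c(1, 2), identity)^2))
  brute <- mean(rowSums(sp[61:180, ] > 1) >= 2)
  expect_equal(got$overlap_frac, brute)
  expect_equal(got$overlap_frac, 0.5)
})

test_that("trial distributions normalize over non-noise labels", {
  lab <- c(0L, 0L, 1L, -1L)
  d <- trial_distribution(lab, c(0, 4))
  expect_equal(d, c(`0` = 2 / 3, `1` = 1 / 3))
  expect_equal(sum(d), 1)
  expect_equal(trial_distribution(c(2L, 2L), c(0, 2)), c(`2` = 1))
  expect_null(trial_distribution(rep(-1L, 4), c(0, 4)))
  expect_error(trial_distribution(lab, c(2, 2)), "empty")
})

test_that("keypress composition is duration-weighted within trials", {
  occ <- data.frame(label = c(0L, 1L), trial = 1L,
                    start_frame = c(0L, 300L), end_frame = c(240L, 540L),
                    duration_s = c(2, 2), kp_count = c(1L, 3L),
                    kp_rate = c(0.5, 1.5), overlap_frac = c(0, 0.4),
                    key_string = c("4", "1-3-2"))
  comp <- keypress_composition_by_trial(occ, n_trials = 2)
  expect_equal(comp$frac_k1[1], 0.5)
  expect_equal(comp$frac_k3[1], 0.5)
  expect_equal(comp$mean_kp_count[1], 2)
  expect_true(all(is.na(comp$mean_kp_count[2])))
  # single occurrence -> all mass at its count
  comp1 <- keypress_composition_by_trial(occ[2, ], n_trials = 1)
  expect_equal(comp1$frac_k3, 1)
  # row fractions partition the occupied time
  expect_equal(sum(comp[1, paste0("frac_k", 0:5)]), 1)
})

test_that("usage classes partition labels at the documented bin edges", {
  # label 0: 60%, label 1: exactly 5%, label 2: 35%
  lab <- rep(c(0L, 1L, 2L, -1L), c(120, 10, 70, 40))
  u <- classify_usage(lab)
  expect_equal(sum(u$pct_usage), 100)
  expect_equal(as.character(u$class[u$label == 0]), "expert")
  expect_equal(as.character(u$class[u$label == 1]), "exploratory")  # 5% edge
  expect_equal(as.character(u$class[u$label == 2]), "trial_initiation")
  # a 100%-usage synergy is expert; just below 5% is novice
  expect_equal(as.character(classify_usage(rep(0L, 10))$class), "expert")
  lab2 <- rep(c(0L, 1L), c(97, 3))
  expect_equal(as.character(classify_usage(lab2)$class[2]), "novice")
  expect_equal(nrow(classify_usage(rep(-1L, 5))), 0)
})

test_that("modal key strings summarize occurrence content", {
  occ <- data.frame(label = c(0L, 0L, 0L, 1L),
                    key_string = c("4-1", "4-1", "3", ""))
  ks <- synergy_key_strings(occ)
  expect_equal(ks$key_string[ks$label == 0], "4-1")
  expect_false(1 %in% ks$label)   # only empty strings -> dropped
})

test_that("occurrence durations + noise + missing account for practice time", {
  trials <- trial_structure(n_trials = 3, practice_s = 1, rest_s = 0.5,
                            fps = 120)
  set.seed(8)
  lab <- rep(NA_integer_, trials$n_frames)
  pf <- practice_frames(trials)
  lab[pf] <- sample(c(-1L, 0L, 1L, NA), length(pf), replace = TRUE)
  runs <- label_runs(lab, trials)
  occ_frames <- sum(runs$end_frame - runs$start_frame)
  noise_frames <- sum(lab[pf] == -1, na.rm = TRUE)
  missing_frames <- sum(is.na(lab[pf]))
  expect_equal(occ_frames + noise_frames + missing_frames, length(pf))
})
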