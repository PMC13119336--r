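# Independent brute-force reference for the greedy sequence scan, written
# directly from the counting rule (window equals a rotation -> advance 5,
# else advance 1).
brute_count <- function(keys, sequence = c(4L, 1L, 3L, 2L, 4L)) {
  rots <- lapply(0:4, function(s) sequence[((0:4 + s) %% 5) + 1])
  count <- 0L
  i <- 1L
  while (i + 4L <= length(keys)) {
    if (any(vapply(rots, function(r) all(keys[i:(i + 4)] == r), logical(1)))) {
      count <- count + 1L
      i <- i + 5L
    } else i <- i + 1L
  }
  count
}

test_that("correct-sequence counting follows the greedy rotation rule", {
  expect_equal(count_correct_sequences(c(4, 1, 3, 2, 4, 4, 1, 3, 2, 4)), 2)
  expect_equal(count_correct_sequences(c(1, 3, 2, 4, 4)), 1)  # a rotation
  expect_equal(count_correct_sequences(integer(0)), 0)
  expect_equal(count_correct_sequences(c(1, 3, 2, 4)), 0)     # too short
  # an error press interrupts but the scan resumes after it
  expect_equal(count_correct_sequences(c(4, 1, 3, 2, 4, 2, 4, 1, 3, 2, 4)), 2)
  expect_error(count_correct_sequences(c(1, 2), sequence = c(1, 2, 3)),
               "length 5")
})

test_that("sequence counting agrees with brute force on random streams", {
  set.seed(31)
  for (i in 1:100) {
    keys <- sample(1:4, sample(5:60, 1), replace = TRUE)
    expect_equal(count_correct_sequences(keys), brute_count(keys))
  }
})

test_that("counting continuous typing is invariant to the starting rotation", {
  base <- c(4L, 1L, 3L, 2L, 4L)
  for (s in 0:4) {
    stream <- rep(base[((0:4 + s) %% 5) + 1], 8)   # 8 cycles from rotation s
    expect_equal(count_correct_sequences(stream), 8)
  }
})

test_that("instantaneous speed is matched presses / 5 per second", {
  ev <- data.frame(t_ms = seq(0, 900, by = 100),
                   key = rep(c(4, 1, 3, 2, 4), 2))
  # 10 matched presses in 1 s -> 2 cs/s
  expect_equal(instantaneous_speed(ev, c(0, 1000)), 2)
  # only unmatched presses -> 0
  ev2 <- data.frame(t_ms = c(0, 100, 200), key = c(1, 1, 1))
  expect_equal(instantaneous_speed(ev2, c(0, 1000)), 0)
  # 6 matched sequences over a 10-s trial -> 0.6 cs/s
  ev3 <- data.frame(t_ms = seq(0, by = 150, length.out = 30),
                    key = rep(c(4, 1, 3, 2, 4), 6))
  expect_equal(instantaneous_speed(ev3, c(0, 10000)), 0.6)
  expect_error(instantaneous_speed(ev, c(5, 5)), "positive length")
})

test_that("noiseless learning-curve refit recovers parameters and cutoff", {
  L <- function(t) 0.2 + 0.6 * (1 - exp(-0.3 * t))
  fit <- fit_learning_curve(L(1:36))
  expect_equal(unname(coef(fit)), c(0.2, 0.6, 0.3), tolerance = 1e-6)
  # smallest t with 1 - exp(-0.3 t) >= 0.95 is ceil(ln(20)/0.3) = 10
  expect_equal(fit$cutoff_trial, 10)
  expect_true(fit$identifiable)
  expect_equal(predict(fit, 1:36), fit$fitted, tolerance = 1e-12)
  expect_equal(residuals(fit), L(1:36) - fit$fitted)
})

test_that("flat input yields the degenerate fit, flagged non-identifiable", {
  fit <- fit_learning_curve(rep(0.5, 12))
  expect_equal(fit$C1, 0.5, tolerance = 1e-8)
  expect_equal(fit$C2, 0, tolerance = 1e-8)
  expect_false(fit$identifiable)
  expect_error(fit_learning_curve(c(1, 2, 3)), "at least 4")
})

test_that("cutoff trial is non-increasing in the rate constant", {
  cuts <- vapply(c(0.1, 0.2, 0.3, 0.5, 1, 2), function(lam) {
    fit <- fit_learning_curve(0.2 + 0.6 * (1 - exp(-lam * (1:36))))
    fit$cutoff_trial
  }, integer(1))
  expect_true(all(diff(cuts) <= 0))
})

test_that("noisy refits recover lambda at the ideal-NLS floor", {
  set.seed(5)
  err_lam <- err_c2 <- gap_c2 <- numeric(200)
  for (i in 1:200) {
    y <- 0.2 + 0.6 * (1 - exp(-0.3 * (1:36))) + rnorm(36, 0, 0.05)
    fit <- fit_learning_curve(y)
    err_lam[i] <- abs(fit$lam - 0.3)
    err_c2[i] <- abs(fit$C2 - 0.6)
    # reference: unconstrained nls started at the true parameters
    ref <- tryCatch(stats::nls(y ~ C1 + C2 * (1 - exp(-lam * t)),
                               data.frame(t = 1:36, y = y),
                               start = list(C1 = 0.2, C2 = 0.6, lam = 0.3)),
                    error = function(e) NULL)
    gap_c2[i] <- if (is.null(ref)) NA
                 else abs(fit$C2 - stats::coef(ref)[["C2"]])
  }
  expect_lt(median(err_lam), 0.1)
  # the multi-start bounded fit matches the oracle fit, i.e. the remaining
  # C2 error (~0.053 at this noise and design) is estimator variance, not
  # optimization failure
  expect_lt(median(gap_c2, na.rm = TRUE), 1e-4)
  expect_lt(median(err_c2), 0.06)
})

test_that("micro-gains decompose and telescope exactly", {
  cfg <- session_config(n_trials = 8, seed = 12)
  log <- generate_keypress_schedule(cfg)
  trials <- trial_structure(8)
  mg <- micro_gains(log, trials, early_window = 8)
  g <- mg$gains
  expect_equal(g$online, g$last_s - g$first_s)
  expect_equal(g$offline[-8], g$first_s[-1] - g$last_s[-8])
  # telescoping identity: sum online + sum offline = last(K) - first(1)
  expect_equal(mg$cum_online + mg$cum_offline, mg$total_early,
               tolerance = 1e-12)
  expect_error(micro_gains(log, trials, early_window = 9), "exceeds")
})

test_that("trial speeds track the planted learning curve", {
  cfg <- session_config(error_rate = 0, seed = 42)
  sp <- trial_speeds(generate_keypress_schedule(cfg), trial_structure(36))
  fit <- fit_learning_curve(sp)
  expect_lt(abs(fit$C1 - 0.2), 0.08)
  expect_lt(abs(fit$C2 - 0.6), 0.08)
  expect_lt(abs(fit$lam - 0.3), 0.1)
})
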