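test_that("js_measure matches hand-computed values and the disjoint ceiling", {
  # identical distributions
  expect_equal(js_measure(c(a = 0.3, b = 0.7), c(a = 0.3, b = 0.7)), 0)
  # disjoint supports attain the distance ceiling sqrt(ln 2)
  expect_equal(js_measure(c(a = 1), c(b = 1)), sqrt(log(2)), tolerance = 1e-12)
  expect_equal(round(js_measure(c(a = 1), c(b = 1)), 4), 0.8326)
  # (0.5, 0.5) vs (1, 0): JSD = 0.5*KL(p||m) + 0.5*KL(q||m) with m = (.75, .25)
  # = 0.5*(0.5 log(2/3) + 0.5 log 2) + 0.5*log(4/3) = 0.215762, sqrt = 0.46450
  expect_equal(js_measure(c(a = 0.5, b = 0.5), c(a = 1)), 0.4645014,
               tolerance = 1e-6)
  expect_equal(js_measure(c(a = 0.5, b = 0.5), c(a = 1), type = "divergence"),
               0.2157616, tolerance = 1e-6)
})

test_that("js_measure is symmetric and bounded on random distribution pairs", {
  set.seed(42)
  for (i in 1:200) {
    kp <- sample(2:6, 1)
    kq <- sample(2:6, 1)
    p <- stats::setNames(rexp(kp), letters[1:kp])
    q <- stats::setNames(rexp(kq), letters[1:kq])
    v <- js_measure(p, q)
    expect_gte(v, 0)
    expect_lte(v, sqrt(log(2)) + 1e-12)
    expect_equal(v, js_measure(q, p), tolerance = 1e-12)
  }
})

test_that("js_measure rejects empty or malformed distributions", {
  expect_error(js_measure(numeric(0), c(a = 1)), "empty")
  expect_error(js_measure(c(a = 0), c(a = 1)), "empty")
  expect_error(js_measure(c(a = -1, b = 2), c(a = 1)), "negative")
})

test_that("permutation test: identical multisets give observed 0 and p = 1", {
  lab <- rep(c(0, 1, 2), c(50, 40, 30))
  r <- permutation_test(lab, lab, n_perm = 500, seed = 3)
  expect_equal(r$observed, 0)
  expect_equal(r$p_perm, 1)
  expect_equal(r$z, 0)
})

test_that("permutation test: disjoint labels in large windows hit the p floor", {
  r <- permutation_test(rep(0, 200), rep(1, 200), n_perm = 1000, seed = 3)
  expect_equal(r$observed, sqrt(log(2)), tolerance = 1e-12)
  expect_equal(r$p_perm, 1 / 1000)
})

test_that("permutation p-values are invariant to the sqrt convention", {
  # the distance is a monotone transform of the divergence, so the two
  # conventions must induce identical permutation p-values
  set.seed(9)
  for (i in 1:10) {
    a <- sample(0:2, 120, replace = TRUE, prob = c(.5, .3, .2))
    b <- sample(0:2, 120, replace = TRUE, prob = c(.2, .3, .5))
    r1 <- permutation_test(a, b, n_perm = 400, seed = i)
    r2 <- permutation_test(a, b, n_perm = 400, seed = i, type = "divergence")
    expect_equal(r1$p_perm, r2$p_perm)
  }
})

test_that("permutation test drops noise labels and validates inputs", {
  a <- c(rep(0, 60), rep(-1, 60))
  b <- c(rep(1, 60), rep(-1, 60))
  r <- permutation_test(a, b, n_perm = 200, seed = 1)
  expect_equal(r$n_a, 60)   # noise excluded from the window
  expect_equal(r$n_b, 60)
  expect_error(permutation_test(a, b, n_perm = 50, seed = 1), "n_perm")
  expect_error(permutation_test(rep(-1, 10), b, n_perm = 200, seed = 1),
               "non-noise")
})

test_that("p_to_z follows the two-sided convention", {
  expect_equal(p_to_z(1), 0)
  expect_equal(p_to_z(0.0456), qnorm(1 - 0.0228))
  expect_gte(p_to_z(1e-6), 0)
  expect_error(p_to_z(0), "0, 1")
  expect_error(p_to_z(1.2), "0, 1")
})

test_that("Stouffer combination follows the closed form", {
  # n copies of the same z give Z = z * sqrt(n)
  for (z in c(0.5, 1.3)) {
    for (n in c(4, 9)) {
      s <- stouffer_combine(rep(z, n))
      expect_equal(s$Z_combined, z * sqrt(n), tolerance = 1e-12)
      expect_equal(s$p_combined, 2 * (1 - pnorm(z * sqrt(n))),
                   tolerance = 1e-12)
    }
  }
  expect_error(stouffer_combine(numeric(0)), "at least one")
})

test_that("micro_jsd computes per-trial window divergences at fps frames", {
  fps <- 120
  trials <- trial_structure(n_trials = 3, practice_s = 2, rest_s = 1,
                            fps = fps)
  n <- trials$n_frames
  lab <- rep(0L, n)
  # trial 1 and 2 all label 0; trial 3 all label 1: planted switch at the
  # rest break between trials 2 and 3
  w3 <- trials$windows[3, ]
  lab[(w3$practice_start + 1):w3$practice_end] <- 1L
  mj <- micro_jsd(lab, trials, window_s = 1)
  expect_equal(nrow(mj), 3)
  expect_equal(mj$online, c(0, 0, 0))
  expect_equal(mj$offline[1], 0)
  expect_equal(mj$offline[2], sqrt(log(2)), tolerance = 1e-12)
  expect_true(is.na(mj$offline[3]))
})

test_that("micro_jsd returns NA, not zero, for all-noise windows", {
  trials <- trial_structure(n_trials = 2, practice_s = 2, rest_s = 1,
                            fps = 60)
  lab <- rep(0L, trials$n_frames)
  w1 <- trials$windows[1, ]
  lab[(w1$practice_start + 1):(w1$practice_start + 60)] <- -1L  # first 1 s
  mj <- micro_jsd(lab, trials, window_s = 1)
  expect_true(is.na(mj$online[1]))
  expect_false(is.na(mj$online[2]))
})

test_that("cohort reference tables load with consistent p/z columns", {
  for (cmp in c("trial1_vs_trial12", "trial12_vs_trial36", "day1_vs_day2")) {
    tab <- cohort_jsd_table(cmp)
    expect_true(all(c("participant", "observed_jsd", "p_perm", "z") %in%
                      names(tab)))
    expect_true(all(tab$observed_jsd <= sqrt(log(2)) + 1e-4))
    # printed z agrees with the two-sided transform of the printed p up to
    # the propagated rounding of p (half an ULP of p scaled by the normal
    # density) plus half an ULP of z itself
    tol <- 5e-5 / dnorm(tab$z) + 5e-5
    expect_true(all(abs(p_to_z(tab$p_perm) - tab$z) <= tol))
  }
  expect_equal(nrow(cohort_jsd_table("day1_vs_day2")), 10)
})

test_that("block permutation matches its coarse combinatorial null", {
  # disjoint labels in 8 pure blocks of 30: only the two extreme block
  # partitions reach the observed ceiling, so p -> 2 / choose(8, 4) = 0.0286
  r <- permutation_test(rep(0, 120), rep(1, 120), n_perm = 2000, seed = 2,
                        block = 30)
  expect_equal(r$observed, sqrt(log(2)), tolerance = 1e-12)
  expect_lt(abs(r$p_perm - 2 / choose(8, 4)), 0.01)
  # identical windows: p = 1 under the block null too
  lab <- rep(c(0, 1), each = 60)
  r2 <- permutation_test(lab, lab, n_perm = 200, seed = 2, block = 30)
  expect_equal(r2$p_perm, 1)
  expect_identical(r2$block, 30)
})
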