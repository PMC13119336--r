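# Shared fixtures built in code.

# Three dense Gaussian blobs (n = 1000 each) + 5% uniform background in
# 2-D; the oracle labels for this exact point set (fixed RNG) are frozen in
# fixtures/hdbscan_oracle_labels.csv.
make_blob_fixture <- function() {
  set.seed(7)
  X <- rbind(cbind(rnorm(1000), rnorm(1000)),
             cbind(rnorm(1000) + 8, rnorm(1000)),
             cbind(rnorm(1000) + 4, rnorm(1000) + 7),
             cbind(runif(150, -4, 12), runif(150, -4, 11)))
  truth <- rep(c(0L, 1L, 2L, -1L), c(1000, 1000, 1000, 150))
  list(X = X, truth = truth)
}

# Small planted-regime session shared by the slower clustering tests:
# 6 trials, two regimes switching at the rest break after trial 3.
make_two_regime_session <- function(seed = 11) {
  session_config(
    n_trials = 6, learn_C1 = 0.4, learn_C2 = 0, error_rate = 0,
    noise_sd = 1, dropout_rate = 0.002,
    regime_schedule = list(list(trials = c(1, 3), regime = 1),
                           list(trials = c(4, 6), regime = 3)),
    seed = seed)
}

# Adjusted Rand index (Hubert & Arabie) for label agreement, computed from
# the contingency table; independent of any clustering code under test.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Minimal pose series: one moving channel given as a function of time.
tone_series <- function(n = 1200, fps = 120, digit = 2, axis = 2,
                        f = function(t) rep(0, length(t))) {
  t <- (0:(n - 1)) / fps
  pos <- array(0, c(n, 4, 2))
  pos[, , 1] <- 500
  pos[, , 2] <- 300
  pos[, digit, axis] <- pos[, digit, axis] + f(t)
  pose_series(pos, matrix(1, n, 4), fps = fps)
}
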