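test_that("density clustering matches the reference labels on planted blobs", {
  fix <- make_blob_fixture()
  oracle <- read.csv(test_path("fixtures", "hdbscan_oracle_labels.csv"))$label
  hb <- hdbscan_cluster(fix$X, min_cluster_size = 200, min_samples = 30)
  expect_equal(hb$n_clusters, 3)
  # agreement with the independently computed reference clustering
  expect_gte(ari(hb$labels, oracle), 0.95)
  expect_lte(abs(sum(hb$labels == -1) - sum(oracle == -1)), 20)
  # and with the generating partition
  expect_gte(ari(hb$labels[fix$truth != -1], fix$truth[fix$truth != -1]),
             0.95)
  # background is mostly noise
  expect_gt(mean(hb$labels[fix$truth == -1] == -1), 0.5)
})

test_that("min_cluster_size above all blob sizes yields an all-noise result", {
  fix <- make_blob_fixture()
  hb <- hdbscan_cluster(fix$X, min_cluster_size = 1100, min_samples = 30)
  expect_equal(hb$n_clusters, 0)
  expect_true(all(hb$labels == -1))
})

test_that("label counts conserve: members + noise = all points", {
  fix <- make_blob_fixture()
  hb <- hdbscan_cluster(fix$X, min_cluster_size = 200, min_samples = 30)
  expect_equal(sum(hb$cluster_sizes) + sum(hb$labels == -1), nrow(fix$X))
})

test_that("clustering is stable under 90% subsampling", {
  fix <- make_blob_fixture()
  set.seed(15)
  for (i in 1:3) {
    idx <- sample(nrow(fix$X), round(0.9 * nrow(fix$X)))
    hb <- hdbscan_cluster(fix$X[idx, ], min_cluster_size = 100,
                          min_samples = 10)
    expect_equal(hb$n_clusters, 3)
  }
})

test_that("two separated 40-D blobs embed linearly separable", {
  set.seed(44)
  n <- 1000
  mu <- rep(0, 40)
  X1 <- matrix(rnorm(n * 40), n) + matrix(rep(mu, each = n), n)
  X2 <- matrix(rnorm(n * 40), n)
  X2[, 1] <- X2[, 1] + 12
  feats <- list(mat = rbind(X1, X2) + 20, frame_valid = rep(TRUE, 2 * n),
                freqs = c(0.75, 1.45, 1.95, 2.35, 2.75),
                omega0 = 6, fps = 120)
  class(feats) <- "wavelet_features"
  emb <- embed_frames(feats, n_epochs = 300, seed = 2)
  grp <- rep(c(0, 1), each = n)
  # held-out linear classifier on the 2-D coordinates
  train <- c(1:800, 1001:1800)
  fit <- MASS::lda(x = emb$coords[train, ], grouping = grp[train])
  pred <- predict(fit, emb$coords[-train, ])$class
  expect_gte(mean(pred == grp[-train]), 0.99)
})

test_that("embedding is deterministic given the seed, duplicates coincide", {
  set.seed(3)
  X <- matrix(rnorm(300 * 40), 300)
  X[151:300, ] <- X[1:150, ]           # exact duplicates
  feats <- structure(list(mat = X, frame_valid = rep(TRUE, 300)),
                     class = "wavelet_features")
  e1 <- embed_frames(feats, n_epochs = 200, seed = 9)
  e2 <- embed_frames(feats, n_epochs = 200, seed = 9)
  expect_identical(e1$coords, e2$coords)
  dup <- sqrt(rowSums((e1$coords[1:150, ] - e1$coords[151:300, ])^2))
  alld <- as.matrix(dist(e1$coords[sample(300, 100), ]))
  expect_lt(median(dup), quantile(alld[upper.tri(alld)], 0.01))
  # too few valid frames errors
  feats$frame_valid <- c(rep(TRUE, 10), rep(FALSE, 290))
  expect_error(embed_frames(feats), "n_neighbors")
})

test_that("cluster profiles are feature means; constant rows give themselves", {
  fix <- make_blob_fixture()
  # treat the 2-D fixture as features of 1000 frames, pad to constant cols
  mat <- cbind(fix$X, matrix(2, nrow(fix$X), 3))
  colnames(mat) <- paste0("f", 1:5)
  feats <- structure(list(mat = mat, frame_valid = rep(TRUE, nrow(mat))),
                     class = "wavelet_features")
  emb <- list(coords = fix$X, frames = seq_len(nrow(mat)),
              n_frames = nrow(mat))
  class(emb) <- "frame_embedding"
  lab <- cluster_frames(emb, feats, min_cluster_size = 200, min_samples = 30)
  expect_equal(lab$n_clusters, 3)
  # canonical ids: descending size
  expect_true(all(diff(lab$sizes) <= 0))
  for (cl in 0:2) {
    members <- which(lab$label == cl)
    expect_equal(unname(lab$profiles[cl + 1, ]),
                 unname(colMeans(mat[members, ])), tolerance = 1e-12)
  }
  expect_equal(unname(lab$profiles[, 3]), rep(2, 3))  # constant column
  # accounting: clusters + noise = embedded frames
  expect_equal(sum(lab$sizes) + sum(lab$label == -1, na.rm = TRUE),
               length(emb$frames))
})

test_that("all-noise clustering warns and returns an empty synergy set", {
  set.seed(5)
  emb <- list(coords = matrix(runif(400, 0, 100), 200), frames = 1:200,
              n_frames = 200)
  class(emb) <- "frame_embedding"
  expect_warning(lab <- cluster_frames(emb, min_cluster_size = 150,
                                       min_samples = 30), "noise")
  expect_equal(lab$n_clusters, 0)
  expect_true(all(lab$label == -1))
})

test_that("joint clustering of a duplicated session matches across days", {
  cfg <- make_two_regime_session(seed = 31)
  sess <- simulate_session(cfg)
  wf <- morlet_amplitudes(filter_and_interpolate(sess$series))
  pf <- practice_frames(sess$trials)
  jc <- joint_embed_cluster(wf, wf, frames_a = pf, frames_b = pf,
                            min_cluster_size = 150, min_samples = 30,
                            n_epochs = 800, seed = 4)
  lab_a <- jc$labels$label[seq_len(sess$series$n_frames)]
  lab_b <- jc$labels$label[jc$offset_b + seq_len(sess$series$n_frames)]
  # identical inputs: per-trial label distributions agree across "days"
  for (t in seq_len(nrow(sess$trials$windows))) {
    w <- sess$trials$windows[t, ]
    da <- trial_distribution(lab_a, c(w$practice_start, w$practice_end))
    db <- trial_distribution(lab_b, c(w$practice_start, w$practice_end))
    if (is.null(da)) {
      expect_null(db)
    } else {
      expect_equal(js_measure(da, db), 0, tolerance = 0.05)
    }
  }
  # dimensionality mismatch errors
  wf80 <- morlet_amplitudes(filter_and_interpolate(sess$series), phase = TRUE)
  expect_error(joint_embed_cluster(wf, wf80), "dimensionality")
})
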