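#' Embed wavelet features into two dimensions with UMAP
#'
#' Embeds the per-frame amplitude vectors with Uniform Manifold Approximation
#' and Projection (via \pkg{uwot}), using 15 nearest neighbours and a minimum
#' distance of 0.1 by default, Euclidean metric (all amplitude dimensions
#' share pixel units). Invalid frames are excluded from the fit and receive
#' no coordinates. The run is single-threaded and seeded, so results are
#' reproducible.
#'
#' @param features A [morlet_amplitudes()] result.
#' @param frames Optional 1-based frame indices to embed (e.g. practice
#'   frames only); intersected with the features' validity mask. Default:
#'   all valid frames.
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param init Layout initialization (default `"pca"`). With strongly
#'   separated behavioural states the 15-neighbour graph can fall into
#'   several connected components, where spectral initialization places
#'   components independently and can superimpose them; PCA initialization
#'   keeps the global geometry of the feature space.
#' @param init_sdev Scale (standard deviation) of the initial layout
#'   (default 10). Shrinking the initialization to a point-like scale -- the
#'   upstream default -- discards the global separation the PCA
#'   initialization carries; keeping it at the scale of the final layout
#'   preserves it through optimization.
#' @param n_epochs Optimization epochs (default 1500; high-frame-rate
#'   trajectories embed as long filaments that need a long optimization to
#'   untangle).
#' @param seed Integer seed (required for reproducibility).
#' @return An object of class `"frame_embedding"`: list with `coords`
#'   (embedded points x 2), `frames` (1-based frame index of each embedded
#'   point), `n_frames` (total frames in the session), `params`.
#' @export
embed_frames <- function(features, frames = NULL, n_neighbors = 15,
                         min_dist = 0.1, init = "pca", init_sdev = 10,
                         n_epochs = 1500, seed = 1) {
  n <- nrow(features$mat)
  keep <- which(features$frame_valid)
  if (!is.null(frames)) keep <- intersect(keep, frames)
  if (length(keep) < n_neighbors)
    stop("fewer valid frames (", length(keep), ") than n_neighbors (",
         n_neighbors, ")")
  X <- features$mat[keep, , drop = FALSE]
  coords <- withr_seed(seed, withCallingHandlers(
    uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
               init = init, init_sdev = init_sdev, n_epochs = n_epochs,
               metric = "euclidean", n_threads = 1, n_sgd_threads = 0,
               verbose = FALSE),
    # uwot flags any init layout at sd >= 10 as unusually wide; here the
    # wide initialization is deliberate (preserves global separation)
    warning = function(w) {
      if (grepl("Initial embedding standard deviation", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  structure(list(coords = coords, frames = keep, n_frames = n,
                 params = list(n_neighbors = n_neighbors,
                               min_dist = min_dist, init = init,
                               init_sdev = init_sdev, n_epochs = n_epochs,
                               seed = seed)),
            class = "frame_embedding")
}

#' @export
print.frame_embedding <- function(x, ...) {
  cat(sprintf("2-D embedding of %d/%d frames (n_neighbors = %d, min_dist = %g, seed = %d)\n",
              nrow(x$coords), x$n_frames, x$params$n_neighbors,
              x$params$min_dist, x$params$seed))
  invisible(x)
}

#' Cluster an embedding into motor synergies
#'
#' Applies density-based clustering ([hdbscan_cluster()]) to the 2-D
#' embedding. Each persistent density cluster is a motor synergy; sparse
#' regions get the noise label -1. Frames that were excluded upstream
#' (invalid, or outside the embedded subset) are a separate "missing"
#' category, reported as `NA` rather than conflated with noise, so the
#' frame-count accounting `clusters + noise + missing = all frames` always
#' holds. Cluster ids are canonicalized by descending member count
#' (cluster 0 is the largest).
#'
#' @param embedding A [embed_frames()] result.
#' @param features Optional [morlet_amplitudes()] result from which mean
#'   per-cluster amplitude profiles are computed.
#' @param min_cluster_size Minimum cluster size (default 200).
#' @param min_samples Core-distance neighbourhood size (default 30).
#' @return An object of class `"synergy_labels"`: list with `label` (integer
#'   per session frame: cluster id, -1 noise, `NA` missing), `frames`
#'   (embedded frame indices), `n_clusters`, `sizes`, `profiles` (cluster x
#'   feature matrix or `NULL`), `params`.
#' @export
cluster_frames <- function(embedding, features = NULL,
                           min_cluster_size = 200, min_samples = 30) {
  hb <- hdbscan_cluster(embedding$coords,
                        min_cluster_size = min_cluster_size,
                        min_samples = min_samples)
  lab <- hb$labels
  if (hb$n_clusters == 0) {
    warning("all points labeled noise; empty synergy set")
  } else {
    # canonical order: descending size
    ord <- order(hb$cluster_sizes, decreasing = TRUE)
    remap <- integer(hb$n_clusters)
    remap[ord] <- seq_len(hb$n_clusters) - 1L
    lab[lab >= 0] <- remap[lab[lab >= 0] + 1L]
  }
  label <- rep(NA_integer_, embedding$n_frames)
  label[embedding$frames] <- lab
  sizes <- if (hb$n_clusters) tabulate(lab + 1L, nbins = hb$n_clusters)
           else integer(0)
  profiles <- NULL
  if (!is.null(features) && hb$n_clusters > 0) {
    profiles <- t(vapply(seq_len(hb$n_clusters) - 1L, function(cl)
      colMeans(features$mat[embedding$frames[lab == cl], , drop = FALSE]),
      numeric(ncol(features$mat))))
    rownames(profiles) <- paste0("synergy_", seq_len(hb$n_clusters) - 1L)
    colnames(profiles) <- colnames(features$mat)
  }
  structure(list(label = label, frames = embedding$frames,
                 n_clusters = hb$n_clusters, sizes = sizes,
                 profiles = profiles,
                 params = list(min_cluster_size = min_cluster_size,
                               min_samples = min_samples)),
            class = "synergy_labels")
}

#' @export
print.synergy_labels <- function(x, ...) {
  cat(sprintf("Synergy labels: %d clusters over %d embedded frames (%d noise, %d missing)\n",
              x$n_clusters, length(x$frames),
              sum(x$label == -1, na.rm = TRUE), sum(is.na(x$label))))
  if (x$n_clusters > 0)
    cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Joint embedding and clustering of two sessions
#'
#' Concatenates the feature matrices of two sessions (e.g. two training
#' days), constructs a single embedding from the combined data, and clusters
#' it once, so one label space spans both sessions and any two epochs can be
#' compared by indexing frame ranges.
#'
#' @param features_a,features_b [morlet_amplitudes()] results with identical
#'   feature dimensionality.
#' @param frames_a,frames_b Optional per-session frame subsets (1-based).
#' @param n_neighbors,min_dist,init,init_sdev,n_epochs,seed Passed to
#'   [embed_frames()].
#' @param min_cluster_size,min_samples Passed to [cluster_frames()].
#' @return A list with `labels` (a `synergy_labels` over the concatenation),
#'   `offset_b` (frame offset of session B within the joint label vector),
#'   and `embedding`.
#' @export
joint_embed_cluster <- function(features_a, features_b,
                                frames_a = NULL, frames_b = NULL,
                                n_neighbors = 15, min_dist = 0.1,
                                init = "pca", init_sdev = 10,
                                n_epochs = 1500, seed = 1,
                                min_cluster_size = 200, min_samples = 30) {
  if (ncol(features_a$mat) != ncol(features_b$mat))
    stop("feature dimensionality differs between sessions")
  na <- nrow(features_a$mat)
  joint <- list(mat = rbind(features_a$mat, features_b$mat),
                frame_valid = c(features_a$frame_valid,
                                features_b$frame_valid),
                freqs = features_a$freqs, omega0 = features_a$omega0,
                fps = features_a$fps)
  class(joint) <- "wavelet_features"
  frames <- NULL
  if (!is.null(frames_a) || !is.null(frames_b)) {
    if (is.null(frames_a)) frames_a <- seq_len(na)
    if (is.null(frames_b)) frames_b <- seq_len(nrow(features_b$mat))
    frames <- c(frames_a, frames_b + na)
  }
  emb <- embed_frames(joint, frames = frames, n_neighbors = n_neighbors,
                      min_dist = min_dist, init = init,
                      init_sdev = init_sdev, n_epochs = n_epochs,
                      seed = seed)
  labels <- cluster_frames(emb, joint, min_cluster_size = min_cluster_size,
                           min_samples = min_samples)
  list(labels = labels, offset_b = na, embedding = emb)
}

#' Write per-frame synergy labels as CSV
#'
#' @param labels A [cluster_frames()] result.
#' @param trials Optional [trial_structure()] used to attach trial numbers.
#' @param path Output path.
#' @export
write_labels_csv <- function(labels, path, trials = NULL) {
  df <- data.frame(frame = seq_along(labels$label) - 1L,
                   label = labels$label)
  if (!is.null(trials)) {
    tr <- rep(NA_integer_, length(labels$label))
    for (t in seq_len(nrow(trials$windows))) {
      w <- trials$windows[t, ]
      tr[(w$practice_start + 1):w$rest_end] <- t
    }
    df$trial <- tr
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
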