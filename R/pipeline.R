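#' Load a recorded session from files
#'
#' @param pose_csv Path to a markerless-pose CSV ([read_pose_csv()]).
#' @param keypress_csv Path to a keypress log CSV ([read_keypress_csv()]).
#' @param trials A [trial_structure()] describing the session.
#' @param fps Sampling rate (default taken from `trials`).
#' @return List with `series`, `log`, `trials`, usable by [run_pipeline()].
#' @export
load_session <- function(pose_csv, keypress_csv, trials, fps = trials$fps) {
  list(series = read_pose_csv(pose_csv, fps = fps),
       log = read_keypress_csv(keypress_csv),
       trials = trials)
}

# Deterministic fan-out of one pipeline seed into per-stage seeds
# (multiplicative Lehmer step, kept below 2^31).
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage) %% 2147483647)
}

#' Run the full synergy-analysis pipeline on one session
#'
#' End-to-end composition of the stages: confidence filtering and gap
#' interpolation, Morlet wavelet featurization, 2-D embedding of practice
#' frames, density clustering into synergies, occurrence kinematics and
#' usage taxonomy, learning-curve fit with micro-gain decomposition, and
#' Jensen-Shannon divergence statistics (micro-online/offline divergences
#' plus a permutation test comparing the first trial's synergy distribution
#' with the early-learning cutoff trial's, and the cutoff trial's with the
#' final trial's). Identical inputs and seed give identical results.
#'
#' @param session Either a [session_config()] (a synthetic session is
#'   simulated) or a list with `series`, `log`, `trials` (see
#'   [load_session()]).
#' @param conf_threshold,max_gap Preprocessing parameters (0.95, 3).
#' @param freqs,omega0 Featurization parameters.
#' @param n_neighbors,min_dist,init,init_sdev,n_epochs Embedding parameters
#'   (see [embed_frames()]).
#' @param min_cluster_size,min_samples Clustering parameters (200, 30).
#' @param move_threshold Movement threshold for overlap, px/frame (1).
#' @param n_perm Permutations for the divergence tests (default 100000).
#' @param window_s Micro-window length in seconds (1).
#' @param early_window Early-learning window K for micro-gains (default
#'   `min(12, n_trials)`).
#' @param include_rest If `TRUE`, rest frames also enter the embedding
#'   (default `FALSE`: practice frames only).
#' @param seed Pipeline seed; fans out deterministically to the embedding
#'   and permutation stages.
#' @param out_dir If non-`NULL`, the result bundle (labels, occurrences,
#'   composition, usage, fit, divergences, manifest) is written there.
#' @return An object of class `"synergy_session"`.
#' @export
run_pipeline <- function(session = session_config(),
                         conf_threshold = 0.95, max_gap = 3,
                         freqs = MOVEMENT_FREQS, omega0 = 6,
                         n_neighbors = 15, min_dist = 0.1, init = "pca",
                         init_sdev = 10, n_epochs = 1500,
                         min_cluster_size = 200, min_samples = 30,
                         move_threshold = 1, n_perm = 100000, window_s = 1,
                         early_window = NULL, include_rest = FALSE,
                         seed = 1, out_dir = NULL) {
  if (inherits(session, "session_config"))
    session <- simulate_session(session)
  series <- filter_and_interpolate(session$series, conf_threshold, max_gap)
  trials <- session$trials
  log <- session$log
  n_trials <- nrow(trials$windows)
  invisible(segment_trials(series, trials))  # validates extent

  feats <- morlet_amplitudes(series, freqs = freqs, omega0 = omega0)
  frames <- if (include_rest) NULL else practice_frames(trials)
  emb <- embed_frames(feats, frames = frames, n_neighbors = n_neighbors,
                      min_dist = min_dist, init = init,
                      init_sdev = init_sdev, n_epochs = n_epochs,
                      seed = stage_seed(seed, 1))
  labels <- cluster_frames(emb, feats, min_cluster_size = min_cluster_size,
                           min_samples = min_samples)

  occ <- occurrence_kinematics(label_runs(labels, trials), series, log,
                               move_threshold = move_threshold)
  composition <- keypress_composition_by_trial(occ, n_trials)
  usage <- classify_usage(labels)
  keystrings <- synergy_key_strings(occ)

  speeds <- trial_speeds(log, trials)
  fit <- fit_learning_curve(speeds)
  if (is.null(early_window)) early_window <- min(12, n_trials)
  gains <- micro_gains(log, trials, early_window = early_window,
                       window_s = window_s)
  mj <- micro_jsd(labels$label, trials, window_s = window_s)

  perm <- list()
  dist_of_trial <- function(t) {
    w <- trials$windows[t, ]
    lab <- labels$label[(w$practice_start + 1):w$practice_end]
    lab[!is.na(lab) & lab != -1]
  }
  cut_t <- fit$cutoff_trial
  cmp <- list(early = c(1, cut_t), late = c(cut_t, n_trials))
  for (nm in names(cmp)) {
    a <- dist_of_trial(cmp[[nm]][1]); b <- dist_of_trial(cmp[[nm]][2])
    perm[[nm]] <- if (length(a) && length(b) &&
                      cmp[[nm]][1] != cmp[[nm]][2])
      permutation_test(a, b, n_perm = n_perm, seed = stage_seed(seed, 2))
    else NULL
  }

  res <- structure(list(
    series = series, log = log, trials = trials, features = feats,
    embedding = emb, labels = labels, occurrences = occ,
    composition = composition, usage = usage, key_strings = keystrings,
    speeds = speeds, fit = fit, gains = gains, micro_jsd = mj,
    permutation = perm,
    params = list(conf_threshold = conf_threshold, max_gap = max_gap,
                  freqs = freqs, omega0 = omega0, n_neighbors = n_neighbors,
                  min_dist = min_dist, init = init, init_sdev = init_sdev,
                  n_epochs = n_epochs,
                  min_cluster_size = min_cluster_size,
                  min_samples = min_samples, move_threshold = move_threshold,
                  n_perm = n_perm, window_s = window_s,
                  early_window = early_window, include_rest = include_rest,
                  seed = seed)),
    class = "synergy_session")
  if (!is.null(out_dir)) write_bundle(res, out_dir)
  res
}

#' @export
print.synergy_session <- function(x, ...) {
  cat("Synergy pipeline result\n")
  print(x$trials)
  print(x$labels)
  print(x$fit)
  print(x$gains)
  invisible(x)
}

#' @export
summary.synergy_session <- function(object, ...) {
  print(object)
  cat("Usage classes:\n")
  print(object$usage, row.names = FALSE)
  if (!is.null(object$permutation$early)) {
    cat("Trial 1 vs cutoff-trial synergy-map divergence:\n  ")
    print(object$permutation$early)
  }
  invisible(object)
}

#' @export
plot.synergy_session <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$fit, main = "learning curve")
  lab <- x$labels$label[x$labels$frames]
  cols <- ifelse(lab == -1, "grey80", grDevices::hcl.colors(
    max(x$labels$n_clusters, 1), "Dark 3")[lab + 1])
  graphics::plot(x$embedding$coords, col = cols, pch = ".",
                 xlab = "UMAP 1", ylab = "UMAP 2", main = "synergy map")
  invisible(x)
}

#' Run the joint two-day pipeline
#'
#' Featurizes both sessions with identical settings, constructs one
#' embedding and one clustering over the concatenated frames, and compares
#' epoch synergy distributions across days in the shared label space. The
#' default epoch comparison is the final trial of session A against trial 3
#' of session B (trained-performance vs first transfer trial).
#'
#' @param session_a,session_b Session lists (`series`, `log`, `trials`) or
#'   [session_config()] objects.
#' @param epoch_a Trial of session A to compare (default: last).
#' @param epoch_b Trial of session B to compare (default: 3).
#' @inheritParams run_pipeline
#' @return An object of class `"joint_synergy_session"`: list with `joint`
#'   (labels/embedding over the concatenation), `offset_b`, per-day label
#'   vectors, the epoch comparison permutation test, and `params`.
#' @export
run_joint_pipeline <- function(session_a, session_b,
                               epoch_a = NULL, epoch_b = 3,
                               conf_threshold = 0.95, max_gap = 3,
                               freqs = MOVEMENT_FREQS, omega0 = 6,
                               n_neighbors = 15, min_dist = 0.1,
                               init = "pca", init_sdev = 10,
                               n_epochs = 1500,
                               min_cluster_size = 200, min_samples = 30,
                               n_perm = 100000, seed = 1) {
  prep <- function(s) {
    if (inherits(s, "session_config")) s <- simulate_session(s)
    s$series <- filter_and_interpolate(s$series, conf_threshold, max_gap)
    s$features <- morlet_amplitudes(s$series, freqs = freqs, omega0 = omega0)
    s
  }
  a <- prep(session_a); b <- prep(session_b)
  jc <- joint_embed_cluster(a$features, b$features,
                            frames_a = practice_frames(a$trials),
                            frames_b = practice_frames(b$trials),
                            n_neighbors = n_neighbors, min_dist = min_dist,
                            init = init, init_sdev = init_sdev,
                            n_epochs = n_epochs,
                            seed = stage_seed(seed, 1),
                            min_cluster_size = min_cluster_size,
                            min_samples = min_samples)
  lab_a <- jc$labels$label[seq_len(a$series$n_frames)]
  lab_b <- jc$labels$label[jc$offset_b + seq_len(b$series$n_frames)]
  if (is.null(epoch_a)) epoch_a <- nrow(a$trials$windows)
  epoch_labels <- function(lab, trials, t) {
    w <- trials$windows[t, ]
    v <- lab[(w$practice_start + 1):w$practice_end]
    v[!is.na(v) & v != -1]
  }
  la <- epoch_labels(lab_a, a$trials, epoch_a)
  lb <- epoch_labels(lab_b, b$trials, epoch_b)
  transfer <- if (length(la) && length(lb))
    permutation_test(la, lb, n_perm = n_perm, seed = stage_seed(seed, 2))
  else NULL
  structure(list(joint = jc, offset_b = jc$offset_b,
                 labels_a = lab_a, labels_b = lab_b,
                 trials_a = a$trials, trials_b = b$trials,
                 epoch = c(a = epoch_a, b = epoch_b), transfer = transfer,
                 params = list(n_neighbors = n_neighbors,
                               min_dist = min_dist,
                               min_cluster_size = min_cluster_size,
                               min_samples = min_samples, n_perm = n_perm,
                               seed = seed)),
            class = "joint_synergy_session")
}

#' @export
print.joint_synergy_session <- function(x, ...) {
  cat("Joint two-session synergy analysis\n")
  print(x$joint$labels)
  cat(sprintf("Epoch comparison: session A trial %d vs session B trial %d\n",
              x$epoch["a"], x$epoch["b"]))
  if (!is.null(x$transfer)) print(x$transfer)
  invisible(x)
}

# Write the result bundle of a single-session run.
write_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_labels_csv(res$labels, file.path(out_dir, "labels.csv"), res$trials)
  utils::write.csv(res$occurrences, file.path(out_dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(res$composition, file.path(out_dir, "composition.csv"),
                   row.names = FALSE)
  utils::write.csv(res$usage, file.path(out_dir, "usage.csv"),
                   row.names = FALSE)
  utils::write.csv(res$gains$gains, file.path(out_dir, "micro_gains.csv"),
                   row.names = FALSE)
  utils::write.csv(res$micro_jsd, file.path(out_dir, "micro_jsd.csv"),
                   row.names = FALSE)
  fitj <- list(C1 = res$fit$C1, C2 = res$fit$C2, lambda = res$fit$lam,
               cutoff_trial = res$fit$cutoff_trial,
               identifiable = res$fit$identifiable,
               speeds = res$speeds)
  jsonlite::write_json(fitj, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)
  perm <- lapply(res$permutation, function(p) if (is.null(p)) NULL else
    list(observed = p$observed, p_perm = p$p_perm, z = p$z,
         n_perm = p$n_perm))
  jsonlite::write_json(perm, file.path(out_dir, "divergence.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c(res$params,
                list(package_version = as.character(utils::packageVersion("synkin")),
                     n_trials = nrow(res$trials$windows),
                     fps = res$trials$fps))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
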