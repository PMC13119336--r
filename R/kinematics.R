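#' Run-length encode synergy labels into occurrence intervals
#'
#' Maximal runs of the same non-noise label within each trial's practice
#' window become synergy occurrences; noise (-1) and missing (`NA`) runs are
#' dropped and runs never span trial boundaries (a raw run crossing a rest
#' break is split).
#'
#' @param labels A `synergy_labels` object from [cluster_frames()], or a raw
#'   integer label vector (one per session frame).
#' @param trials A [trial_structure()].
#' @return Data frame of occurrences: `label`, `trial`, `start_frame`,
#'   `end_frame` (0-based, half-open).
#' @export
label_runs <- function(labels, trials) {
  lab <- if (inherits(labels, "synergy_labels")) labels$label else labels
  out <- list()
  for (t in seq_len(nrow(trials$windows))) {
    w <- trials$windows[t, ]
    seg <- lab[(w$practice_start + 1):w$practice_end]
    key <- ifelse(is.na(seg), -2L, seg)     # make NA rle-able
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values >= 0
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      label = r$values[keep], trial = t,
      start_frame = w$practice_start + starts[keep] - 1L,
      end_frame = w$practice_start + ends[keep])
  }
  if (length(out) == 0)
    return(data.frame(label = integer(0), trial = integer(0),
                      start_frame = integer(0), end_frame = integer(0)))
  do.call(rbind, out)
}

# Per-frame, per-digit movement speed (px/frame): Euclidean displacement
# between consecutive frames; first frame gets 0.
digit_speeds <- function(series) {
  n <- series$n_frames
  sp <- matrix(0, n, 4)
  dx <- series$pos[-1, , 1, drop = FALSE] - series$pos[-n, , 1, drop = FALSE]
  dy <- series$pos[-1, , 2, drop = FALSE] - series$pos[-n, , 2, drop = FALSE]
  sp[-1, ] <- sqrt(dx[, , 1]^2 + dy[, , 1]^2)
  sp
}

#' Kinematic properties of synergy occurrences
#'
#' Fills each occurrence with its duration, keypress count and rate, the
#' inter-digit overlap fraction, and the ordered key string of presses inside
#' it. A digit counts as "moving" in a frame when its displacement from the
#' previous frame exceeds `move_threshold` px; the overlap fraction is the
#' proportion of the occurrence's frames in which at least two digits move
#' concurrently.
#'
#' @param occurrences Data frame from [label_runs()].
#' @param series A [pose_series()].
#' @param log Keypress log data frame (`t_ms`, `key`, `trial`).
#' @param move_threshold Movement threshold in px/frame (default 1).
#' @return The occurrence data frame with added columns `duration_s`,
#'   `kp_count`, `kp_rate`, `overlap_frac`, `key_string`.
#' @export
occurrence_kinematics <- function(occurrences, series, log,
                                  move_threshold = 1) {
  fps <- series$fps
  sp <- digit_speeds(series)
  moving2 <- rowSums(sp > move_threshold) >= 2
  n <- nrow(occurrences)
  duration_s <- (occurrences$end_frame - occurrences$start_frame) / fps
  kp_count <- integer(n)
  overlap <- numeric(n)
  key_string <- character(n)
  for (i in seq_len(n)) {
    a <- occurrences$start_frame[i]; b <- occurrences$end_frame[i]
    t0 <- a * 1000 / fps; t1 <- b * 1000 / fps
    inside <- log$t_ms >= t0 & log$t_ms < t1
    kp_count[i] <- sum(inside)
    key_string[i] <- paste(log$key[inside], collapse = "-")
    overlap[i] <- mean(moving2[(a + 1):b])
  }
  occurrences$duration_s <- duration_s
  occurrences$kp_count <- kp_count
  occurrences$kp_rate <- ifelse(duration_s > 0, kp_count / duration_s, 0)
  occurrences$overlap_frac <- overlap
  occurrences$key_string <- key_string
  occurrences
}

#' Synergy-label distribution of a frame window
#'
#' Relative frequency of each non-noise label among the frames of a window;
#' noise (-1) and missing (`NA`) frames are excluded before normalization.
#'
#' @param labels `synergy_labels` object or raw label vector.
#' @param window Length-2 integer vector `c(from, to)`, 0-based half-open.
#' @return Named probability vector summing to 1, or `NULL` when the window
#'   contains no non-noise frame (an empty distribution, which divergence
#'   operations reject).
#' @export
trial_distribution <- function(labels, window) {
  lab <- if (inherits(labels, "synergy_labels")) labels$label else labels
  if (window[2] <= window[1]) stop("empty window")
  window_label_dist(lab, window[1], window[2])
}

#' Per-trial composition of synergy deployment by keypress count
#'
#' For each trial, the fraction of synergy-occupied time spent in synergies
#' comprising k keypresses (k = 0..5; counts above 5 fold into 5), weighted
#' by occurrence duration, plus per-trial means of keypress count, keypress
#' rate, duration and overlap over occurrences.
#'
#' @param occurrences Data frame from [occurrence_kinematics()].
#' @param n_trials Number of trials to report (rows for trials with no
#'   occurrences carry `NA` means and zero fractions).
#' @param weighted If `TRUE`, weight the per-trial kinematic means by
#'   occurrence duration instead of averaging occurrences equally.
#' @return Data frame with one row per trial: `trial`, `frac_k0` ..
#'   `frac_k5`, `mean_kp_count`, `mean_kp_rate`, `mean_duration_s`,
#'   `mean_overlap`.
#' @export
keypress_composition_by_trial <- function(occurrences, n_trials,
                                          weighted = FALSE) {
  out <- data.frame(trial = seq_len(n_trials))
  for (k in 0:5) out[[paste0("frac_k", k)]] <- 0
  out$mean_kp_count <- NA_real_
  out$mean_kp_rate <- NA_real_
  out$mean_duration_s <- NA_real_
  out$mean_overlap <- NA_real_
  for (t in seq_len(n_trials)) {
    occ <- occurrences[occurrences$trial == t, , drop = FALSE]
    if (nrow(occ) == 0) next
    kk <- pmin(occ$kp_count, 5L)
    tot <- sum(occ$duration_s)
    for (k in 0:5)
      out[t, paste0("frac_k", k)] <-
        if (tot > 0) sum(occ$duration_s[kk == k]) / tot else 0
    w <- if (weighted) occ$duration_s else rep(1, nrow(occ))
    w <- w / sum(w)
    out$mean_kp_count[t] <- sum(w * occ$kp_count)
    out$mean_kp_rate[t] <- sum(w * occ$kp_rate)
    out$mean_duration_s[t] <- sum(w * occ$duration_s)
    out$mean_overlap[t] <- sum(w * occ$overlap_frac)
  }
  out
}

#' Classify synergies by session-level usage
#'
#' Percent usage of a synergy is the share of all non-noise frames carrying
#' its label, in percent. Synergies are binned into the four usage classes
#' `novice` `[0, 5)`, `exploratory` `[5, 20)`, `trial_initiation` `[20, 50)`
#' and `expert` `[50, 100]` (half-open bins closing the gaps between the
#' printed anchors).
#'
#' @param labels `synergy_labels` object or raw label vector for the full
#'   session.
#' @return Data frame with `label`, `pct_usage`, `class` (factor), sorted by
#'   descending usage. Zero rows when no synergy exists.
#' @export
classify_usage <- function(labels) {
  lab <- if (inherits(labels, "synergy_labels")) labels$label else labels
  lab <- lab[!is.na(lab) & lab != -1]
  classes <- c("novice", "exploratory", "trial_initiation", "expert")
  if (length(lab) == 0)
    return(data.frame(label = integer(0), pct_usage = numeric(0),
                      class = factor(character(0), levels = classes)))
  tab <- table(lab)
  pct <- 100 * as.numeric(tab) / sum(tab)
  cls <- cut(pct, breaks = c(0, 5, 20, 50, 100.000001), right = FALSE,
             labels = classes)
  out <- data.frame(label = as.integer(names(tab)), pct_usage = pct,
                    class = cls)
  out[order(-out$pct_usage), , drop = FALSE]
}

#' Modal key string per synergy
#'
#' The keypress content of a synergy is summarized as the most frequent
#' ordered key string over its occurrences (empty strings from
#' zero-keypress occurrences excluded).
#'
#' @param occurrences Data frame from [occurrence_kinematics()].
#' @return Data frame `label`, `key_string`, `n_occurrences`.
#' @export
synergy_key_strings <- function(occurrences) {
  occ <- occurrences[nzchar(occurrences$key_string), , drop = FALSE]
  labs <- sort(unique(occ$label))
  data.frame(
    label = labs,
    key_string = vapply(labs, function(l) {
      tab <- table(occ$key_string[occ$label == l])
      names(tab)[which.max(tab)]
    }, character(1)),
    n_occurrences = vapply(labs, function(l) sum(occ$label == l), integer(1)))
}
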