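DIGITS <- c("index", "middle", "ring", "little")
AXES <- c("x", "y")

#' Construct a pose series
#'
#' Container for per-frame digit positions sampled uniformly (default 120 Hz):
#' a `[frame, digit, axis]` position array in pixels, a per-digit likelihood
#' matrix in `[0, 1]`, and a per-digit validity mask. Frames are 0-based and
#' all windows over them are half-open `[start, end)`.
#'
#' @param pos Numeric array `n x 4 x 2` (digits index/middle/ring/little,
#'   axes x/y).
#' @param likelihood Numeric matrix `n x 4` in `[0, 1]`.
#' @param valid Logical matrix `n x 4`; defaults to all `TRUE`.
#' @param fps Frames per second (default 120).
#' @return An object of class `"pose_series"`.
#' @export
pose_series <- function(pos, likelihood, valid = NULL, fps = 120) {
  n <- dim(pos)[1]
  stopifnot(length(dim(pos)) == 3, dim(pos)[2] == 4, dim(pos)[3] == 2,
            nrow(likelihood) == n, ncol(likelihood) == 4, fps > 0)
  dimnames(pos) <- list(NULL, DIGITS, AXES)
  if (is.null(valid)) valid <- matrix(TRUE, n, 4)
  colnames(likelihood) <- DIGITS
  colnames(valid) <- DIGITS
  structure(list(pos = pos, likelihood = likelihood, valid = valid,
                 fps = fps, n_frames = n),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("Pose series: %d frames at %g fps (%.1f s), 4 digits x (x, y)\n",
              x$n_frames, x$fps, x$n_frames / x$fps))
  cat(sprintf("  valid digit-frames: %.1f%%\n", 100 * mean(x$valid)))
  invisible(x)
}

#' Read a markerless-pose CSV file
#'
#' Parses the common markerless-pose dialect: three header rows (scorer,
#' bodyparts, coords), a leading frame-index column, then `x`, `y`,
#' `likelihood` columns per bodypart. Bodyparts are mapped onto the four
#' digits by name; all frames and likelihoods are preserved (no filtering is
#' applied here -- see [filter_and_interpolate()]).
#'
#' @param path File path.
#' @param fps Sampling rate of the recording (default 120).
#' @param bodyparts Names expected in the bodyparts header row, in digit order
#'   index/middle/ring/little.
#' @return A [pose_series()].
#' @export
read_pose_csv <- function(path, fps = 120,
                          bodyparts = c("index", "middle", "ring", "little")) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         colClasses = "character")
  body_row <- as.character(unlist(hdr[2, -1]))
  coord_row <- as.character(unlist(hdr[3, -1]))
  dat <- utils::read.csv(path, header = FALSE, skip = 3)
  if (ncol(dat) != length(body_row) + 1)
    stop("ragged pose file: ", ncol(dat) - 1, " data columns vs ",
         length(body_row), " header columns")
  frame_idx <- dat[[1]]
  if (any(diff(frame_idx) <= 0))
    stop("non-monotone frame index at row ",
         which(diff(frame_idx) <= 0)[1] + 1)
  n <- nrow(dat)
  pos <- array(NA_real_, c(n, 4, 2))
  lik <- matrix(NA_real_, n, 4)
  for (d in seq_along(bodyparts)) {
    bp <- bodyparts[d]
    for (coord in c("x", "y", "likelihood")) {
      col <- which(body_row == bp & coord_row == coord)
      if (length(col) != 1)
        stop("missing bodypart column: ", bp, "/", coord)
      v <- as.numeric(dat[[col + 1]])
      if (coord == "likelihood") lik[, d] <- v
      else pos[, d, match(coord, AXES)] <- v
    }
  }
  pose_series(pos, lik, fps = fps)
}

#' Write a pose series as a markerless-pose CSV file
#'
#' @param series A [pose_series()].
#' @param path Output path.
#' @param scorer Scorer name placed in the first header row.
#' @export
write_pose_csv <- function(series, path, scorer = "synkin") {
  n <- series$n_frames
  cols <- list(frame = 0:(n - 1))
  body <- character(0); coords <- character(0)
  for (d in seq_along(DIGITS)) {
    for (coord in c("x", "y", "likelihood")) {
      v <- if (coord == "likelihood") series$likelihood[, d]
           else series$pos[, d, coord]
      cols[[paste(DIGITS[d], coord, sep = "_")]] <- v
      body <- c(body, DIGITS[d]); coords <- c(coords, coord)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("scorer", rep(scorer, length(body))), collapse = ","), con)
  writeLines(paste(c("bodyparts", body), collapse = ","), con)
  writeLines(paste(c("coords", coords), collapse = ","), con)
  utils::write.table(as.data.frame(cols), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Confidence filtering and short-gap interpolation
#'
#' Flags digit-frames whose likelihood falls below `conf_threshold` as low
#' confidence. Runs of at most `max_gap` consecutive low-confidence frames
#' flanked by valid frames are replaced by linear interpolation between the
#' flanking positions; longer runs -- and runs touching the series boundary,
#' which cannot be interpolated without extrapolating -- are marked invalid
#' and their values left untouched. Frames that were valid going in are never
#' altered, and no temporal smoothing of any kind is applied.
#'
#' The operation is idempotent: interpolated frames keep their original
#' (sub-threshold) likelihood, but re-running the filter reproduces the same
#' linear fill from the same flanking frames.
#'
#' @param series A [pose_series()].
#' @param conf_threshold Likelihood below which a frame is low confidence
#'   (default 0.95).
#' @param max_gap Longest run (frames) eligible for interpolation (default 3).
#' @return A [pose_series()] with interpolated positions and updated `valid`.
#' @export
filter_and_interpolate <- function(series, conf_threshold = 0.95, max_gap = 3) {
  pos <- series$pos
  valid <- series$valid
  n <- series$n_frames
  for (d in 1:4) {
    low <- series$likelihood[, d] < conf_threshold | !series$valid[, d]
    if (!any(low)) { valid[, d] <- TRUE; next }
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    v <- rep(TRUE, n)
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      a <- starts[k]; b <- ends[k]
      interior <- a > 1 && b < n
      if (r$lengths[k] <= max_gap && interior) {
        w <- seq_len(r$lengths[k]) / (r$lengths[k] + 1)
        for (ax in 1:2) {
          pos[a:b, d, ax] <- pos[a - 1, d, ax] * (1 - w) + pos[b + 1, d, ax] * w
        }
      } else {
        v[a:b] <- FALSE
      }
    }
    valid[, d] <- v
  }
  pose_series(pos, series$likelihood, valid, fps = series$fps)
}

#' Trial structure of a practice session
#'
#' Describes the alternating practice/rest windows of a session as 0-based,
#' half-open frame intervals.
#'
#' @param n_trials Number of trials (default 36).
#' @param practice_s,rest_s Practice and rest durations in seconds
#'   (defaults 10 and 10).
#' @param fps Frames per second (default 120).
#' @param day Day label (default 1).
#' @param offset_frames Frame offset of trial 1 (default 0; used to address
#'   the second session of a concatenated two-day recording).
#' @return An object of class `"trial_structure"`: list with `windows` (data
#'   frame `trial`, `practice_start`, `practice_end`, `rest_start`,
#'   `rest_end`), `fps`, `practice_s`, `rest_s`, `day`, `n_frames`.
#' @export
trial_structure <- function(n_trials = 36, practice_s = 10, rest_s = 10,
                            fps = 120, day = 1, offset_frames = 0) {
  stopifnot(n_trials >= 1, practice_s > 0, rest_s >= 0, fps > 0)
  pf <- as.integer(round(practice_s * fps))
  rf <- as.integer(round(rest_s * fps))
  t0 <- offset_frames + (seq_len(n_trials) - 1L) * (pf + rf)
  windows <- data.frame(trial = seq_len(n_trials),
                        practice_start = t0, practice_end = t0 + pf,
                        rest_start = t0 + pf, rest_end = t0 + pf + rf)
  structure(list(windows = windows, fps = fps, practice_s = practice_s,
                 rest_s = rest_s, day = day,
                 n_frames = n_trials * (pf + rf)),
            class = "trial_structure")
}

#' @export
print.trial_structure <- function(x, ...) {
  cat(sprintf("Trial structure: %d trials of %gs practice + %gs rest at %g fps (day %s)\n",
              nrow(x$windows), x$practice_s, x$rest_s, x$fps, x$day))
  invisible(x)
}

# Practice window of trial t in milliseconds, half-open.
practice_window_ms <- function(trials, t) {
  c(trials$windows$practice_start[t], trials$windows$practice_end[t]) *
    1000 / trials$fps
}

#' Segment a pose series into per-trial practice and rest views
#'
#' @param series A [pose_series()].
#' @param trials A [trial_structure()] whose extent must fit inside the
#'   series.
#' @return A list with one element per trial, each holding `practice` and
#'   `rest` integer frame-index vectors (1-based row indices into the series).
#' @export
segment_trials <- function(series, trials) {
  last <- max(trials$windows$rest_end)
  if (last > series$n_frames)
    stop("trial structure (", last, " frames) exceeds series length (",
         series$n_frames, ")")
  lapply(seq_len(nrow(trials$windows)), function(t) {
    w <- trials$windows[t, ]
    list(trial = t,
         practice = (w$practice_start + 1):w$practice_end,
         rest = if (w$rest_end > w$rest_start)
           (w$rest_start + 1):w$rest_end else integer(0))
  })
}

#' Practice-frame indices of a session
#'
#' @param trials A [trial_structure()].
#' @return 1-based row indices of all practice frames, in session order.
#' @export
practice_frames <- function(trials) {
  unlist(lapply(seq_len(nrow(trials$windows)), function(t) {
    w <- trials$windows[t, ]
    (w$practice_start + 1):w$practice_end
  }))
}

#' Read a trial structure from CSV
#'
#' Expects columns `trial`, `practice_start_ms`, `rest_start_ms`, one row
#' per trial in order. Each trial's practice window runs from its practice
#' start to its rest start; the rest window runs to the next trial's
#' practice start (the final rest reuses the previous rest duration).
#'
#' @param path File path.
#' @param fps Frames per second used to convert times to frames
#'   (default 120).
#' @param day Day label (default 1).
#' @return A [trial_structure()]-shaped object.
#' @export
read_trials_csv <- function(path, fps = 120, day = 1) {
  df <- utils::read.csv(path)
  need <- c("trial", "practice_start_ms", "rest_start_ms")
  if (!all(need %in% names(df)))
    stop("trial structure needs columns ", paste(need, collapse = ", "))
  df <- df[order(df$trial), , drop = FALSE]
  n <- nrow(df)
  to_frame <- function(ms) as.integer(round(ms * fps / 1000))
  ps <- to_frame(df$practice_start_ms)
  rs <- to_frame(df$rest_start_ms)
  if (any(rs <= ps) || any(diff(ps) <= 0) ||
      (n > 1 && any(rs[-n] > ps[-1])))
    stop("trial windows must be ordered and non-overlapping")
  last_rest <- if (n > 1) ps[2] - rs[1] else rs[n] - ps[n]
  re <- c(ps[-1], rs[n] + last_rest)
  windows <- data.frame(trial = df$trial, practice_start = ps,
                        practice_end = rs, rest_start = rs, rest_end = re)
  structure(list(windows = windows, fps = fps,
                 practice_s = stats::median(rs - ps) / fps,
                 rest_s = stats::median(re - rs) / fps, day = day,
                 n_frames = max(re)),
            class = "trial_structure")
}

#' Read a keypress log CSV
#'
#' Expects columns `t_ms`, `key`, `trial`; timestamps must be non-decreasing
#' and keys in 1..4.
#'
#' @param path File path.
#' @return Data frame with columns `t_ms`, `key`, `trial`.
#' @export
read_keypress_csv <- function(path) {
  log <- utils::read.csv(path)
  if (!all(c("t_ms", "key", "trial") %in% names(log)))
    stop("keypress log needs columns t_ms, key, trial")
  if (is.unsorted(log$t_ms)) stop("keypress timestamps must be non-decreasing")
  if (!all(log$key %in% 1:4)) stop("keys must lie in 1..4")
  log$key <- as.integer(log$key)
  log$trial <- as.integer(log$trial)
  log
}

#' Write a keypress log CSV
#' @param log Data frame with columns `t_ms`, `key`, `trial`.
#' @param path Output path.
#' @export
write_keypress_csv <- function(log, path) {
  utils::write.csv(log[, c("t_ms", "key", "trial")], path, row.names = FALSE)
  invisible(path)
}
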