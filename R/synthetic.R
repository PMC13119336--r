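#' Coordination-regime specification for the synthetic generator
#'
#' A regime describes how keypresses are rendered as digit kinematics: the
#' duration of the flexion bump elicited by one press, how strongly
#' consecutive presses coarticulate (anticipatory onset overlap), and the
#' bump amplitudes. Distinct regimes produce distinct wavelet signatures, so
#' a schedule of regimes plants a known cluster structure that the embedding
#' and clustering stages should recover.
#'
#' @param regime_id Integer id.
#' @param kernel_width_s Duration of the raised-cosine flexion bump (s).
#' @param coarticulation_overlap Fraction in `[0, 1)` by which a bump's onset
#'   anticipates its keypress (its center is shifted earlier by
#'   `overlap * width / 2`), making consecutive digit movements overlap.
#' @param amplitude_px Bump height on the y (flexion) axis, pixels.
#' @param lateral_drift_px Excursion on the x (lateral) axis per press.
#' @return An object of class `"regime_spec"`.
#' @export
regime_spec <- function(regime_id, kernel_width_s = 0.4,
                        coarticulation_overlap = 0, amplitude_px = 40,
                        lateral_drift_px = 10) {
  stopifnot(kernel_width_s > 0,
            coarticulation_overlap >= 0, coarticulation_overlap < 1)
  structure(list(regime_id = as.integer(regime_id),
                 kernel_width_s = kernel_width_s,
                 coarticulation_overlap = coarticulation_overlap,
                 amplitude_px = amplitude_px,
                 lateral_drift_px = lateral_drift_px),
            class = "regime_spec")
}

#' Default novice-to-expert regime set
#'
#' Three regimes spanning the kinematic shift seen across early learning:
#' slow isolated presses (wide bumps, no coarticulation, mostly vertical
#' flexion), an intermediate stage, and fast strongly coarticulated presses
#' (narrow overlapping bumps with pronounced lateral motion). Bump widths
#' set the spectral signature of each regime; the growing lateral drift
#' shifts energy from the y to the x channels, so the three regimes are
#' separated in the wavelet feature space along both axes.
#'
#' @return List of three [regime_spec()] objects with ids 1..3.
#' @export
default_regimes <- function() {
  list(regime_spec(1, kernel_width_s = 0.8, coarticulation_overlap = 0,
                   lateral_drift_px = 5),
       regime_spec(2, kernel_width_s = 0.4, coarticulation_overlap = 0.35,
                   lateral_drift_px = 20),
       regime_spec(3, kernel_width_s = 0.15, coarticulation_overlap = 0.75,
                   lateral_drift_px = 40))
}

#' Configuration of a synthetic practice session
#'
#' Defines the task structure (36 trials of 10 s practice + 10 s rest at
#' 120 fps by default, target sequence 4-1-3-2-4), the planted learning
#' dynamics -- per-trial correct-sequence speed following
#' \eqn{L(t) = C_1 + C_2(1 - e^{-\lambda t})} -- the error and measurement
#' noise levels, and the schedule mapping trial ranges to coordination
#' regimes.
#'
#' @param n_trials Number of trials (default 36).
#' @param practice_s,rest_s Practice/rest durations in seconds (10, 10).
#' @param fps Frames per second (120).
#' @param sequence Target key sequence (default `c(4, 1, 3, 2, 4)`).
#' @param learn_C1 Baseline speed, correct sequences/s (default 0.2).
#' @param learn_C2 Asymptotic gain, cs/s (default 0.6).
#' @param learn_lambda Rate constant, 1/trial (default 0.3).
#' @param error_rate Probability a press is a wrong key (default 0.02).
#' @param noise_sd Gaussian trajectory noise, px (default 1).
#' @param dropout_rate Per-digit-frame probability that tracking confidence
#'   drops below the 0.95 threshold (default 0.005).
#' @param regimes List of [regime_spec()] (default [default_regimes()]).
#' @param regime_schedule List of `list(trials = c(from, to), regime = id)`;
#'   ranges must tile `1..n_trials` without overlap. Default: regimes 1/2/3
#'   over trials 1-6, 7-12, 13-36 (novice to expert).
#' @param seed Integer seed (default 1).
#' @return An object of class `"session_config"`.
#' @export
session_config <- function(n_trials = 36, practice_s = 10, rest_s = 10,
                           fps = 120, sequence = c(4L, 1L, 3L, 2L, 4L),
                           learn_C1 = 0.2, learn_C2 = 0.6, learn_lambda = 0.3,
                           error_rate = 0.02, noise_sd = 1,
                           dropout_rate = 0.005, regimes = default_regimes(),
                           regime_schedule = NULL, seed = 1) {
  stopifnot(n_trials >= 1, fps > 0, practice_s > 0, rest_s >= 0,
            learn_lambda > 0, error_rate >= 0, error_rate < 1,
            noise_sd >= 0, dropout_rate >= 0, dropout_rate < 1)
  if (length(sequence) != 5 || !all(sequence %in% 1:4))
    stop("sequence must be 5 keys in 1..4")
  if (is.null(regime_schedule)) {
    ids <- vapply(regimes, `[[`, integer(1), "regime_id")
    breaks <- unique(pmin(c(6, 12, n_trials), n_trials))
    from <- c(1, utils::head(breaks, -1) + 1)
    keep <- from <= n_trials
    regime_schedule <- Map(function(f, t, r) list(trials = c(f, t), regime = r),
                           from[keep], breaks[keep],
                           ids[seq_len(sum(keep))])
  }
  covered <- integer(0)
  for (rs in regime_schedule) {
    stopifnot(length(rs$trials) == 2)
    covered <- c(covered, rs$trials[1]:rs$trials[2])
  }
  if (!identical(sort(covered), seq_len(n_trials)))
    stop("regime_schedule must tile trials 1..n_trials without overlap")
  structure(list(n_trials = n_trials, practice_s = practice_s,
                 rest_s = rest_s, fps = fps, sequence = as.integer(sequence),
                 learn_C1 = learn_C1, learn_C2 = learn_C2,
                 learn_lambda = learn_lambda, error_rate = error_rate,
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 regimes = regimes, regime_schedule = regime_schedule,
                 seed = as.integer(seed)),
            class = "session_config")
}

# Planted learning curve, cs/s at trial t.
planted_speed <- function(config, t) {
  config$learn_C1 + config$learn_C2 * (1 - exp(-config$learn_lambda * t))
}

# Regime id active in trial t.
regime_of_trial <- function(config, t) {
  for (rs in config$regime_schedule)
    if (t >= rs$trials[1] && t <= rs$trials[2]) return(as.integer(rs$regime))
  stop("trial ", t, " not covered by regime schedule")
}

# Digit pressing key k: keys 1..4 map to little/ring/middle/index.
digit_for_key <- function(key) 5L - as.integer(key)

#' Generate a keypress schedule for a synthetic session
#'
#' Presses occur only inside practice windows. Within trial `t` the nominal
#' inter-press interval is `1 / (5 L(t))` seconds -- so the expected
#' correct-sequence rate equals the planted learning curve `L(t)` -- jittered
#' by a uniform +/-10% to avoid perfectly metronomic spectra. Keys cycle
#' through the target sequence continuously across trials (so any window
#' starts on an arbitrary rotation); each press is replaced by a uniformly
#' chosen wrong key with probability `error_rate`.
#'
#' @param config A [session_config()].
#' @return Keypress log data frame (`t_ms`, `key`, `trial`).
#' @export
generate_keypress_schedule <- function(config) {
  rate_max <- 5 * planted_speed(config, config$n_trials)
  if (rate_max > config$fps / 2)
    stop("planted keypress rate ", signif(rate_max, 4),
         " kp/s exceeds fps/2; unresolvable at this sampling rate")
  trials <- trial_structure(config$n_trials, config$practice_s,
                            config$rest_s, fps = config$fps)
  withr_seed(config$seed, {
    t_ms <- integer(0); key <- integer(0); trial <- integer(0)
    phase <- 0L  # position within the cycled sequence
    for (t in seq_len(config$n_trials)) {
      win <- practice_window_ms(trials, t)
      gap <- 1000 / (5 * planted_speed(config, t))  # ms
      tc <- win[1] + gap / 2
      while (tc < win[2]) {
        k <- config$sequence[phase %% 5L + 1L]
        phase <- phase + 1L
        if (config$error_rate > 0 && stats::runif(1) < config$error_rate)
          k <- sample(setdiff(1:4, k), 1)
        t_ms <- c(t_ms, as.integer(round(tc)))
        key <- c(key, as.integer(k))
        trial <- c(trial, t)
        tc <- tc + gap * stats::runif(1, 0.9, 1.1)
      }
    }
    data.frame(t_ms = t_ms, key = key, trial = trial)
  })
}

# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  expr
}

#' Render digit trajectories from a keypress schedule
#'
#' Each press adds one raised-cosine flexion bump on the pressing digit's y
#' channel (and a smaller lateral excursion on x), with the width, amplitude
#' and anticipatory overlap of the regime active in that trial. Gaussian
#' noise of sd `noise_sd` px is added to every channel; likelihood is drawn
#' uniformly in `[0.95, 1]` except on i.i.d. dropout digit-frames, where it
#' falls below the confidence threshold. Frame count is exactly
#' `n_trials * (practice_s + rest_s) * fps`.
#'
#' @param schedule Keypress log from [generate_keypress_schedule()].
#' @param config A [session_config()].
#' @return A [pose_series()].
#' @export
render_trajectories <- function(schedule, config) {
  fps <- config$fps
  n <- config$n_trials * as.integer(round((config$practice_s + config$rest_s) * fps))
  regimes <- stats::setNames(config$regimes,
                             vapply(config$regimes, `[[`, integer(1), "regime_id"))
  base_x <- c(index = 760, middle = 640, ring = 520, little = 400)
  base_y <- 360
  pos <- array(0, c(n, 4, 2))
  for (d in 1:4) {
    pos[, d, 1] <- base_x[d]
    pos[, d, 2] <- base_y
  }
  tt <- (0:(n - 1)) / fps  # frame times, s
  withr_seed(config$seed + 2L, {
    # per-press motor variability: amplitudes and bump widths vary press to
    # press, as real keystrokes do
    amp_jit <- stats::runif(nrow(schedule), 0.8, 1.2)
    width_jit <- stats::runif(nrow(schedule), 0.9, 1.1)
  })
  if (nrow(schedule) > 0) {
    for (i in seq_len(nrow(schedule))) {
      reg <- regimes[[as.character(regime_of_trial(config, schedule$trial[i]))]]
      w <- reg$kernel_width_s * width_jit[i]
      tc <- schedule$t_ms[i] / 1000 - reg$coarticulation_overlap * w / 2
      d <- digit_for_key(schedule$key[i])
      a <- max(1L, as.integer(floor((tc - w / 2) * fps)) + 1L)
      b <- min(n, as.integer(ceiling((tc + w / 2) * fps)) + 1L)
      if (b < a) next
      idx <- a:b
      u <- (tt[idx] - tc) / w
      bump <- ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
      pos[idx, d, 2] <- pos[idx, d, 2] + amp_jit[i] * reg$amplitude_px * bump
      pos[idx, d, 1] <- pos[idx, d, 1] + amp_jit[i] * reg$lateral_drift_px * bump
    }
  }
  withr_seed(config$seed + 1L, {
    if (config$noise_sd > 0)
      pos <- pos + array(stats::rnorm(n * 8, 0, config$noise_sd), c(n, 4, 2))
    lik <- matrix(stats::runif(n * 4, 0.95, 1), n, 4)
    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * 4) < config$dropout_rate, n, 4)
      lik[drop] <- stats::runif(sum(drop), 0.5, 0.95)
    }
    pose_series(pos, lik, fps = fps)
  })
}

#' Simulate a full synthetic session
#'
#' Convenience wrapper generating the keypress schedule, rendering
#' trajectories, and attaching the trial structure and per-frame ground-truth
#' regime ids (the planted labels that clustering should recover; rest frames
#' carry the regime of their trial).
#'
#' @param config A [session_config()].
#' @return A list of class `"synthetic_session"`: `series` ([pose_series()]),
#'   `log` (keypress data frame), `trials` ([trial_structure()]),
#'   `regime_by_frame` (integer per frame), `config`.
#' @export
simulate_session <- function(config = session_config()) {
  log <- generate_keypress_schedule(config)
  series <- render_trajectories(log, config)
  trials <- trial_structure(config$n_trials, config$practice_s,
                            config$rest_s, fps = config$fps)
  frames_per_trial <- as.integer(round((config$practice_s + config$rest_s) * config$fps))
  regime_by_frame <- rep(vapply(seq_len(config$n_trials),
                                function(t) regime_of_trial(config, t),
                                integer(1)),
                         each = frames_per_trial)
  structure(list(series = series, log = log, trials = trials,
                 regime_by_frame = regime_by_frame, config = config),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("Synthetic session: %d trials, %d frames, %d keypresses, seed %d\n",
              x$config$n_trials, x$series$n_frames, nrow(x$log),
              x$config$seed))
  invisible(x)
}

#' Read a session configuration from a YAML or JSON file
#'
#' Any field of [session_config()] may be set; `regimes` entries are lists of
#' [regime_spec()] fields and `regime_schedule` entries are
#' `{trials: [from, to], regime: id}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [session_config()].
#' @export
read_session_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(vals$regimes))
    vals$regimes <- lapply(vals$regimes, function(r) do.call(regime_spec, r))
  if (!is.null(vals$regime_schedule))
    vals$regime_schedule <- lapply(vals$regime_schedule, function(rs)
      list(trials = as.integer(unlist(rs$trials)), regime = rs$regime))
  do.call(session_config, vals)
}
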