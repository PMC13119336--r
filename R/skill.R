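#' Match correct sequences in a keypress stream
#'
#' Greedy left-to-right scan: a window of 5 consecutive presses equal to the
#' target sequence or any of its cyclic rotations counts as one correct
#' sequence and the scan advances past it; otherwise the scan advances by one
#' press. Overlapping matches are therefore never counted twice -- continuous
#' correct typing of a 5-key sequence yields one match per 5 presses, making
#' the correct-sequence rate 1/5 of the matched-keypress rate.
#'
#' @param keys Integer vector of pressed key ids, in time order.
#' @param sequence The target sequence (length 5).
#' @return Integer vector the length of `keys`: the 1-based index of the
#'   matched sequence each press belongs to, or `NA` for unmatched presses.
#' @export
match_sequences <- function(keys, sequence = c(4L, 1L, 3L, 2L, 4L)) {
  if (length(sequence) != 5) stop("target sequence must have length 5")
  rot <- sequence_rotations(sequence)
  n <- length(keys)
  out <- rep(NA_integer_, n)
  i <- 1L
  seq_id <- 0L
  while (i + 4L <= n) {
    win <- keys[i:(i + 4L)]
    hit <- FALSE
    for (r in rot) {
      if (all(win == r)) { hit <- TRUE; break }
    }
    if (hit) {
      seq_id <- seq_id + 1L
      out[i:(i + 4L)] <- seq_id
      i <- i + 5L
    } else {
      i <- i + 1L
    }
  }
  out
}

sequence_rotations <- function(sequence) {
  k <- length(sequence)
  lapply(seq_len(k) - 1L, function(s) sequence[((seq_len(k) - 1L + s) %% k) + 1L])
}

#' Count correct sequences in a keypress stream
#'
#' @inheritParams match_sequences
#' @return Number of non-overlapping correct sequences under the greedy scan.
#' @examples
#' count_correct_sequences(c(4, 1, 3, 2, 4, 4, 1, 3, 2, 4))  # 2
#' count_correct_sequences(c(1, 3, 2, 4, 4))                 # a rotation: 1
#' @export
count_correct_sequences <- function(keys, sequence = c(4L, 1L, 3L, 2L, 4L)) {
  m <- match_sequences(keys, sequence)
  if (all(is.na(m))) 0L else max(m, na.rm = TRUE)
}

#' Instantaneous correct-sequence speed in a time window
#'
#' Keypresses are attributed to correct sequences by the greedy scan over the
#' whole supplied stream; the speed of a window is the number of matched
#' presses falling inside it divided by 5 times the window length, so a full
#' sequence contributes 1/5 of a sequence per matched press. This definition
#' makes cs/s proportional to the matched-keypress rate and exactly
#' decomposable over sub-windows.
#'
#' @param events Data frame with columns `t_ms` and `key` (one row per press).
#' @param window Numeric length-2 vector `c(t0, t1)` in milliseconds,
#'   half-open `[t0, t1)`.
#' @param sequence Target sequence for matching.
#' @return Speed in correct sequences per second (cs/s).
#' @export
instantaneous_speed <- function(events, window,
                                sequence = c(4L, 1L, 3L, 2L, 4L)) {
  if (diff(window) <= 0) stop("window must have positive length")
  if (nrow(events) == 0) return(0)
  m <- match_sequences(events$key, sequence)
  inside <- events$t_ms >= window[1] & events$t_ms < window[2]
  sum(!is.na(m) & inside) / (5 * diff(window) / 1000)
}

#' Per-trial correct-sequence speeds
#'
#' @param log A keypress log data frame (`t_ms`, `key`, `trial`).
#' @param trials A [trial_structure()].
#' @param sequence Target sequence.
#' @return Numeric vector of cs/s, one per trial, computed over each full
#'   practice window (greedy matching restricted to the trial's presses).
#' @export
trial_speeds <- function(log, trials, sequence = c(4L, 1L, 3L, 2L, 4L)) {
  vapply(seq_len(nrow(trials$windows)), function(t) {
    win <- practice_window_ms(trials, t)
    ev <- log[log$trial == t, , drop = FALSE]
    instantaneous_speed(ev, win, sequence)
  }, numeric(1))
}

#' Fit the exponential learning curve
#'
#' Fits \eqn{L(t) = C_1 + C_2 (1 - e^{-\lambda t})} to per-trial speeds by
#' bound-constrained nonlinear least squares (Levenberg-Marquardt with box
#' constraints, `minpack.lm::nlsLM`), with \eqn{C_1 \ge 0}, \eqn{C_2 \ge 0}
#' and \eqn{\lambda \in (0, 5]}. Exponential fits are initialization
#' sensitive, so five deterministic starts
#' (\eqn{\lambda \in \{0.05, 0.2, 0.5, 1, 2\}}, \eqn{C_1} = first-trial speed,
#' \eqn{C_2} = range) are tried and the best SSE kept.
#'
#' The early-learning cutoff is the smallest integer trial at which the fitted
#' curve has realised 95% of its asymptotic gain:
#' \eqn{1 - e^{-\lambda t} \ge 0.95}, i.e. \eqn{t \ge \ln(20)/\lambda}
#' (`cutoff_method = "gain"`). The alternative `"auc"` mode instead takes the
#' smallest trial at which the cumulative integral of the fitted gain
#' \eqn{L(u) - C_1} reaches 95% of its total over the session.
#'
#' @param speeds Numeric vector of per-trial cs/s (>= 4 trials).
#' @param cutoff_method `"gain"` (default) or `"auc"` (see Details).
#' @return An object of class `"learning_curve"`: a list with `C1`, `C2`,
#'   `lam`, `fitted`, `residuals`, `cutoff_trial`, `n_trials`, `sse`,
#'   `identifiable`, `speeds`.
#' @examples
#' L <- function(t) 0.2 + 0.6 * (1 - exp(-0.3 * t))
#' fit <- fit_learning_curve(L(1:36))
#' coef(fit)          # essentially (0.2, 0.6, 0.3)
#' fit$cutoff_trial   # 10
#' @export
fit_learning_curve <- function(speeds, cutoff_method = c("gain", "auc")) {
  cutoff_method <- match.arg(cutoff_method)
  n <- length(speeds)
  if (n < 4) stop("need at least 4 trials to fit the learning curve")
  tt <- seq_len(n)
  dat <- data.frame(t = tt, y = speeds)
  lower <- c(C1 = 0, C2 = 0, lam = 1e-6)
  upper <- c(C1 = Inf, C2 = Inf, lam = 5)

  identifiable <- stats::sd(speeds) > 1e-12
  best <- NULL
  if (identifiable) {
    c1_0 <- max(speeds[1], 0)
    c2_0 <- max(max(speeds) - min(speeds), 1e-3)
    for (lam0 in c(0.05, 0.2, 0.5, 1, 2)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ C1 + C2 * (1 - exp(-lam * t)), data = dat,
                          start = list(C1 = c1_0, C2 = c2_0, lam = lam0),
                          lower = lower, upper = upper,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(stats::residuals(fit)^2)
      if (is.null(best) || sse < best$sse - 1e-12)
        best <- list(coef = stats::coef(fit), sse = sse)
    }
  }
  if (is.null(best)) {
    # Degenerate/flat input: no gain to estimate.
    best <- list(coef = c(C1 = mean(speeds), C2 = 0, lam = lower[["lam"]]),
                 sse = sum((speeds - mean(speeds))^2))
    identifiable <- FALSE
  }
  co <- best$coef
  fitted <- co[["C1"]] + co[["C2"]] * (1 - exp(-co[["lam"]] * tt))
  cutoff <- learning_cutoff(co[["C1"]], co[["C2"]], co[["lam"]], n, cutoff_method)
  structure(list(C1 = co[["C1"]], C2 = co[["C2"]], lam = co[["lam"]],
                 fitted = fitted, residuals = speeds - fitted,
                 cutoff_trial = cutoff, n_trials = n, sse = best$sse,
                 identifiable = identifiable, speeds = speeds,
                 cutoff_method = cutoff_method),
            class = "learning_curve")
}

learning_cutoff <- function(C1, C2, lam, n, method) {
  if (C2 <= 0 || lam <= 0) return(n)
  if (method == "gain") {
    t95 <- log(20) / lam
  } else {
    # cumulative integral of the gain C2*(1 - e^(-lam u)) from 0 to t
    gain_int <- function(t) C2 * (t - (1 - exp(-lam * t)) / lam)
    total <- gain_int(n)
    t95 <- stats::uniroot(function(t) gain_int(t) - 0.95 * total,
                          c(1e-9, n))$root
  }
  max(1L, min(as.integer(ceiling(t95 - 1e-9)), n))
}

#' @export
print.learning_curve <- function(x, digits = 4, ...) {
  cat("Exponential learning curve  L(t) = C1 + C2 (1 - exp(-lambda t))\n")
  cat(sprintf("  C1 = %.*f cs/s   C2 = %.*f cs/s   lambda = %.*f /trial\n",
              digits, x$C1, digits, x$C2, digits, x$lam))
  cat(sprintf("  %d trials; 95%%-of-gain cutoff at trial %d%s\n",
              x$n_trials, x$cutoff_trial,
              if (x$identifiable) "" else "  [non-identifiable: flat input]"))
  invisible(x)
}

#' @export
summary.learning_curve <- function(object, ...) {
  print(object)
  cat(sprintf("  SSE = %.6g; residual sd = %.4g cs/s\n",
              object$sse, stats::sd(object$residuals)))
  invisible(object)
}

#' @export
coef.learning_curve <- function(object, ...) {
  c(C1 = object$C1, C2 = object$C2, lam = object$lam)
}

#' @export
residuals.learning_curve <- function(object, ...) object$residuals

#' @export
predict.learning_curve <- function(object, t = seq_len(object$n_trials), ...) {
  object$C1 + object$C2 * (1 - exp(-object$lam * t))
}

#' @export
plot.learning_curve <- function(x, ...) {
  tt <- seq_len(x$n_trials)
  graphics::plot(tt, x$speeds, xlab = "trial", ylab = "speed (cs/s)",
                 pch = 16, ...)
  graphics::lines(tt, x$fitted, col = "steelblue", lwd = 2)
  graphics::abline(v = x$cutoff_trial, lty = 2, col = "grey40")
  invisible(x)
}

#' Micro-online and micro-offline skill gains
#'
#' Decomposes trial-to-trial skill change into within-trial (micro-online) and
#' across-rest (micro-offline) components. For each trial the speed of the
#' first and last 1-second window of practice is computed; then
#' `online[t] = last[t] - first[t]` and `offline[t] = first[t+1] - last[t]`.
#' Cumulative sums are reported over the early-learning window (trials
#' `1..early_window`; offline sums run to `early_window - 1`), so the
#' telescoping identity
#' `sum(online) + sum(offline) = last[K] - first[1]` holds exactly.
#'
#' @param log Keypress log data frame (`t_ms`, `key`, `trial`).
#' @param trials A [trial_structure()].
#' @param early_window Number of early-learning trials K (default 12).
#' @param window_s Width of the first/last windows in seconds (default 1).
#' @param sequence Target sequence.
#' @return An object of class `"micro_gains"`: list with per-trial data frame
#'   `gains` (`trial`, `first_s`, `last_s`, `online`, `offline`),
#'   `cum_online`, `cum_offline`, `total_early`, `early_window`.
#' @export
micro_gains <- function(log, trials, early_window = 12, window_s = 1,
                        sequence = c(4L, 1L, 3L, 2L, 4L)) {
  n_trials <- nrow(trials$windows)
  if (early_window > n_trials)
    stop("early_window exceeds the number of trials")
  first_s <- last_s <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    win <- practice_window_ms(trials, t)
    ev <- log[log$trial == t, , drop = FALSE]
    w_ms <- window_s * 1000
    first_s[t] <- instantaneous_speed(ev, c(win[1], win[1] + w_ms), sequence)
    last_s[t] <- instantaneous_speed(ev, c(win[2] - w_ms, win[2]), sequence)
  }
  online <- last_s - first_s
  offline <- c(first_s[-1] - last_s[-n_trials], NA_real_)
  K <- early_window
  structure(list(
    gains = data.frame(trial = seq_len(n_trials), first_s = first_s,
                       last_s = last_s, online = online, offline = offline),
    cum_online = sum(online[seq_len(K)]),
    cum_offline = sum(offline[seq_len(K - 1)]),
    total_early = last_s[K] - first_s[1],
    early_window = K), class = "micro_gains")
}

#' @export
print.micro_gains <- function(x, digits = 3, ...) {
  cat(sprintf("Micro-gains over trials 1..%d:\n", x$early_window))
  cat(sprintf("  cumulative online  = %+.*f cs/s\n", digits, x$cum_online))
  cat(sprintf("  cumulative offline = %+.*f cs/s\n", digits, x$cum_offline))
  cat(sprintf("  total early gain   = %+.*f cs/s\n", digits, x$total_early))
  invisible(x)
}
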