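MOVEMENT_FREQS <- c(0.75, 1.45, 1.95, 2.35, 2.75)

#' Morlet wavelet amplitude features
#'
#' Decomposes each of the 8 trajectory channels (4 digits x 2 axes) with
#' complex Morlet wavelets at five movement-relevant frequencies, yielding a
#' 40-dimensional non-negative amplitude vector per frame. Each channel has
#' its mean (over valid frames) removed first -- raw pixel coordinates carry
#' large DC offsets that would otherwise leak into the low bands -- and the
#' transform is computed by frequency-domain multiplication with an analytic
#' Morlet filter (FFT, multiply, inverse FFT, modulus).
#'
#' The filter is calibrated so that a unit-amplitude sinusoid at a band's
#' center frequency yields amplitude 1 in that band: the analytic filter
#' \eqn{H(\omega) = 2 \exp(-s^2(\omega - \omega_c)^2 / 2)} for
#' \eqn{\omega > 0} (zero otherwise), with time scale
#' \eqn{s = \omega_0 / \omega_c}. Amplitudes are therefore in pixels and
#' scale linearly with the input.
#'
#' Edge handling: the convolution is circular, so the first and last half
#' wavelet support of the session is flagged invalid rather than trusted;
#' likewise frames within half a support of any invalid digit-frame are
#' flagged, since their amplitudes mix interpolable and excluded data. Half
#' support is taken as two Gaussian time constants of the widest (lowest
#' frequency) wavelet.
#'
#' @param series A [pose_series()] (ideally after
#'   [filter_and_interpolate()]).
#' @param freqs Center frequencies in Hz (default
#'   `c(0.75, 1.45, 1.95, 2.35, 2.75)`); all must be below Nyquist.
#' @param omega0 Morlet mother-wavelet parameter (default 6), the standard
#'   trade-off between time and frequency resolution.
#' @param phase If `TRUE`, append the 40 instantaneous phases (radians) to
#'   the feature matrix (80 columns total). Off by default.
#' @return An object of class `"wavelet_features"`: list with `mat` (frames x
#'   40 matrix, columns `amp_<digit>_<axis>_<freq>`), `frame_valid` (logical
#'   per frame), `freqs`, `omega0`, `fps`.
#' @export
morlet_amplitudes <- function(series, freqs = MOVEMENT_FREQS, omega0 = 6,
                              phase = FALSE) {
  fps <- series$fps
  if (any(freqs >= fps / 2))
    stop("frequencies must be below the Nyquist rate ", fps / 2, " Hz")
  n <- series$n_frames
  # angular frequency of each FFT bin (negative for the upper half)
  k <- 0:(n - 1)
  k_signed <- ifelse(k <= n / 2, k, k - n)
  omega <- 2 * pi * k_signed * fps / n

  amp <- matrix(NA_real_, n, 8 * length(freqs))
  ph <- if (phase) matrix(NA_real_, n, 8 * length(freqs)) else NULL
  cn <- character(8 * length(freqs))
  col <- 0L
  for (d in seq_along(DIGITS)) {
    for (ax in seq_along(AXES)) {
      x <- series$pos[, d, ax]
      ok <- series$valid[, d] & is.finite(x)
      mu <- mean(x[ok])
      x <- x - mu
      x[!ok] <- 0
      fx <- stats::fft(x)
      for (fi in seq_along(freqs)) {
        s <- omega0 / (2 * pi * freqs[fi])
        H <- 2 * exp(-(s * omega - omega0)^2 / 2)
        H[omega <= 0] <- 0
        z <- stats::fft(fx * H, inverse = TRUE) / n
        col <- col + 1L
        amp[, col] <- Mod(z)
        if (phase) ph[, col] <- Arg(z)
        cn[col] <- sprintf("amp_%s_%s_%g", DIGITS[d], AXES[ax], freqs[fi])
      }
    }
  }
  colnames(amp) <- cn
  if (phase) {
    colnames(ph) <- sub("^amp_", "phase_", cn)
    amp <- cbind(amp, ph)
  }

  half_support <- ceiling(2 * (omega0 / (2 * pi * min(freqs))) * fps)
  frame_valid <- rep(TRUE, n)
  edge <- min(half_support, n)
  frame_valid[seq_len(edge)] <- FALSE
  frame_valid[(n - edge + 1):n] <- FALSE
  bad <- which(!apply(series$valid, 1, all))
  if (length(bad) > 0) {
    lo <- pmax(bad - half_support, 1)
    hi <- pmin(bad + half_support, n)
    for (i in seq_along(bad)) frame_valid[lo[i]:hi[i]] <- FALSE
  }
  structure(list(mat = amp, frame_valid = frame_valid, freqs = freqs,
                 omega0 = omega0, fps = fps),
            class = "wavelet_features")
}

#' @export
print.wavelet_features <- function(x, ...) {
  cat(sprintf("Wavelet features: %d frames x %d dims (%s Hz, omega0 = %g); %.1f%% frames valid\n",
              nrow(x$mat), ncol(x$mat),
              paste(x$freqs, collapse = "/"), x$omega0,
              100 * mean(x$frame_valid)))
  invisible(x)
}

#' Write a wavelet feature matrix as CSV
#' @param features A [morlet_amplitudes()] result.
#' @param path Output path.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(frame = 0:(nrow(features$mat) - 1),
                   valid = features$frame_valid)
  utils::write.csv(cbind(df, as.data.frame(features$mat)), path,
                   row.names = FALSE)
  invisible(path)
}
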