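#' Jensen-Shannon measure between two synergy-label distributions
#'
#' Computes the Jensen-Shannon divergence (natural logarithm) between two
#' discrete probability distributions and, by default, reports its square
#' root -- the Jensen-Shannon distance, a metric bounded by
#' \eqn{\sqrt{\ln 2} \approx 0.8326}. Supports are unioned before comparison;
#' zero-probability terms contribute nothing (the \eqn{0 \log 0 := 0}
#' convention), so no pseudo-counts are required for the measure to be finite.
#'
#' @param p,q Named numeric vectors of non-negative weights (label
#'   distributions). Names are the cluster labels; vectors are normalized to
#'   sum to 1. Unnamed vectors of equal length are compared position-wise.
#' @param type `"distance"` (default) returns \eqn{\sqrt{JSD}};
#'   `"divergence"` returns the raw natural-log divergence.
#' @param eps Optional pseudo-count added to every cell of the union support
#'   before normalization (default 0, i.e. none).
#' @return A single non-negative number; at most \eqn{\sqrt{\ln 2}} for
#'   `type = "distance"` (\eqn{\ln 2} for `"divergence"`).
#' @examples
#' js_measure(c(a = 1), c(b = 1))            # disjoint supports: 0.8326
#' js_measure(c(a = .5, b = .5), c(a = .5, b = .5))  # identical: 0
#' @export
js_measure <- function(p, q, type = c("distance", "divergence"), eps = 0) {
  type <- match.arg(type)
  pq <- align_supports(p, q)
  p <- pq$p
  q <- pq$q
  if (eps > 0) {
    p <- p + eps
    q <- q + eps
  }
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  jsd <- 0.5 * kl_nat(p, m) + 0.5 * kl_nat(q, m)
  jsd <- min(max(jsd, 0), log(2))  # clamp tiny negative rounding
  if (type == "distance") sqrt(jsd) else jsd
}

# KL divergence with natural log and 0*log(0) := 0
kl_nat <- function(p, m) {
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - log(m[nz])))
}

# Union the supports of two (possibly named) weight vectors.
align_supports <- function(p, q) {
  if (length(p) == 0 || length(q) == 0 || sum(p) <= 0 || sum(q) <= 0)
    stop("empty distribution: both inputs need positive total weight")
  if (any(p < 0) || any(q < 0))
    stop("negative weights are not a distribution")
  if (is.null(names(p)) && is.null(names(q))) {
    if (length(p) != length(q))
      stop("unnamed distributions must have equal length")
    return(list(p = as.numeric(p), q = as.numeric(q)))
  }
  if (is.null(names(p)) || is.null(names(q)))
    stop("either both or neither distribution may be named")
  supp <- union(names(p), names(q))
  pa <- stats::setNames(numeric(length(supp)), supp)
  qa <- pa
  pa[names(p)] <- p
  qa[names(q)] <- q
  list(p = pa, q = qa)
}

# Tabulate a label vector (noise/missing already removed) into a named
# probability vector.
label_distribution <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return(NULL)
  tab <- table(as.character(labels))
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Pooled-label permutation test for a Jensen-Shannon measure
#'
#' Tests whether the Jensen-Shannon measure between the label distributions of
#' two frame windows exceeds chance. All labels are pooled and randomly
#' re-partitioned into two groups of the original sizes `n_perm` times; the
#' measure is recomputed on each induced pair of histograms and the empirical
#' p-value is the proportion of permuted values greater than or equal to the
#' observed one, floored at `1/n_perm`. Group sizes (the marginal structure)
#' are preserved while label correspondence is randomized.
#'
#' The re-partition is sampled exactly via sequential hypergeometric draws on
#' the pooled label counts, which is equivalent to permuting frame labels but
#' vectorizes over permutations.
#'
#' @param labels_a,labels_b Vectors of cluster labels (one per frame); noise
#'   (-1) and `NA` entries are dropped before pooling.
#' @param n_perm Number of permutations (default 100000; at least 100).
#' @param seed Integer seed making the permutation draw reproducible.
#' @param type Passed to [js_measure()].
#' @param block Optional block length in frames for a block-permutation
#'   sensitivity analysis: instead of exchanging single frames, contiguous
#'   blocks of labels are pooled and reassigned to the two groups,
#'   preserving the number of blocks per group. Respects temporal
#'   autocorrelation at the cost of a coarser null. Default `NULL`
#'   (frames exchangeable).
#' @return An object of class `"jsd_permutation"` with elements `observed`,
#'   `p_perm`, `z` (from [p_to_z()]), `n_perm`, `n_a`, `n_b`, and the null
#'   sample `perm_values`.
#' @seealso [js_measure()], [p_to_z()], [stouffer_combine()]
#' @export
permutation_test <- function(labels_a, labels_b, n_perm = 100000, seed = 1,
                             type = c("distance", "divergence"),
                             block = NULL) {
  type <- match.arg(type)
  if (n_perm < 100) stop("n_perm < 100 gives an uninterpretable p-value")
  labels_a <- labels_a[!is.na(labels_a) & labels_a != -1]
  labels_b <- labels_b[!is.na(labels_b) & labels_b != -1]
  if (length(labels_a) == 0 || length(labels_b) == 0)
    stop("both windows must contain at least one non-noise label")

  da <- label_distribution(labels_a)
  db <- label_distribution(labels_b)
  observed <- js_measure(da, db, type = type)
  if (!is.null(block))
    return(block_permutation(labels_a, labels_b, observed, n_perm, seed,
                             type, block))

  pool <- table(c(as.character(labels_a), as.character(labels_b)))
  counts <- as.numeric(pool)
  L <- length(counts)
  n_a <- length(labels_a)
  n_b <- length(labels_b)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  # Sequential multivariate-hypergeometric draw of group-A counts per label.
  xa <- matrix(0L, nrow = n_perm, ncol = L)
  remaining_k <- rep.int(n_a, n_perm)       # A-slots left
  remaining_n <- sum(counts)                # pool items left
  for (j in seq_len(L)) {
    if (j == L) {
      xa[, j] <- remaining_k
    } else {
      draw <- stats::rhyper(n_perm, m = counts[j],
                            n = remaining_n - counts[j], k = remaining_k)
      xa[, j] <- draw
      remaining_k <- remaining_k - draw
      remaining_n <- remaining_n - counts[j]
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  xb <- matrix(rep(counts, each = n_perm), nrow = n_perm) - xa
  perm_values <- js_rowwise(xa / n_a, xb / n_b)
  if (type == "distance") perm_values <- sqrt(perm_values)

  p_perm <- sum(perm_values >= observed - 1e-12) / n_perm
  p_perm <- max(p_perm, 1 / n_perm)

  structure(list(observed = observed, p_perm = p_perm, z = p_to_z(p_perm),
                 n_perm = n_perm, n_a = n_a, n_b = n_b, type = type,
                 perm_values = perm_values),
            class = "jsd_permutation")
}

# Block-permutation null: contiguous label blocks are pooled and shuffled
# between the two groups, preserving the block count per group.
block_permutation <- function(labels_a, labels_b, observed, n_perm, seed,
                              type, block) {
  split_blocks <- function(x)
    split(x, ceiling(seq_along(x) / block))
  blocks <- c(split_blocks(labels_a), split_blocks(labels_b))
  nba <- ceiling(length(labels_a) / block)
  perm_values <- numeric(n_perm)
  withr_seed(seed, {
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(blocks))
      ga <- unlist(blocks[idx[seq_len(nba)]], use.names = FALSE)
      gb <- unlist(blocks[idx[-seq_len(nba)]], use.names = FALSE)
      perm_values[i] <- js_measure(label_distribution(ga),
                                   label_distribution(gb), type = type)
    }
  })
  p_perm <- max(sum(perm_values >= observed - 1e-12) / n_perm, 1 / n_perm)
  structure(list(observed = observed, p_perm = p_perm, z = p_to_z(p_perm),
                 n_perm = n_perm, n_a = length(labels_a),
                 n_b = length(labels_b), type = type, block = block,
                 perm_values = perm_values),
            class = "jsd_permutation")
}

# Row-wise natural-log JSD between two matrices of row distributions.
js_rowwise <- function(P, Q) {
  M <- (P + Q) / 2
  term <- function(X) {
    V <- X * (log(X) - log(M))
    V[X == 0] <- 0
    rowSums(V)
  }
  jsd <- 0.5 * term(P) + 0.5 * term(Q)
  pmin(pmax(jsd, 0), log(2))
}

#' @export
print.jsd_permutation <- function(x, ...) {
  cat("Pooled-label permutation test (Jensen-Shannon",
      if (x$type == "distance") "distance)" else "divergence)", "\n")
  cat(sprintf("  observed = %.4f   p = %.4g   z = %.4f   (%d permutations, n = %d vs %d)\n",
              x$observed, x$p_perm, x$z, x$n_perm, x$n_a, x$n_b))
  invisible(x)
}

#' Convert a permutation p-value to a standard-normal deviate
#'
#' Uses the two-sided convention \eqn{z = \Phi^{-1}(1 - p/2)}, which maps
#' \eqn{p = 1} to \eqn{z = 0} and always yields a non-negative deviate.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Non-negative z-scores.
#' @examples
#' p_to_z(0.0228)  # 2.2763
#' p_to_z(1)       # 0
#' @export
p_to_z <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  stats::qnorm(1 - p / 2)
}

#' Combine per-participant z-scores with Stouffer's method
#'
#' \eqn{Z = \sum_i z_i / \sqrt{n}} with a two-sided combined p-value
#' \eqn{p = 2(1 - \Phi(Z))}.
#'
#' @param z Numeric vector of per-participant z-scores (length >= 1).
#' @return An object of class `"stouffer"` with `z` (the inputs),
#'   `Z_combined` and `p_combined`.
#' @export
stouffer_combine <- function(z) {
  if (length(z) == 0) stop("need at least one z-score")
  if (any(!is.finite(z))) stop("z-scores must be finite")
  Z <- sum(z) / sqrt(length(z))
  structure(list(z = z, Z_combined = Z,
                 p_combined = 2 * (1 - stats::pnorm(Z))),
            class = "stouffer")
}

#' @export
print.stouffer <- function(x, ...) {
  cat(sprintf("Stouffer combination of %d z-scores: Z = %.4f, two-sided p = %.4g\n",
              length(x$z), x$Z_combined, x$p_combined))
  invisible(x)
}

#' Micro-online and micro-offline synergy-map divergence
#'
#' For each trial, compares the synergy-label distribution of the first and
#' last `window_s`-second windows of practice (online reorganization), and the
#' last window of one trial with the first window of the next (offline
#' reorganization, across the intervening rest). Noise (-1) and missing (`NA`)
#' frames are excluded from the histograms; a window with no non-noise frames
#' yields `NA` for the comparisons it enters.
#'
#' @param labels Integer vector of per-frame cluster labels for the whole
#'   session (-1 = noise, `NA` = missing/invalid frames).
#' @param trials A [trial_structure()] describing practice/rest windows.
#' @param window_s Window length in seconds (default 1, i.e. `fps` frames).
#' @param type Passed to [js_measure()].
#' @return A data frame with one row per trial: `trial`, `online` (JS measure
#'   first vs last window of the trial) and `offline` (JS measure last window
#'   of the trial vs first window of the next; `NA` for the final trial).
#' @export
micro_jsd <- function(labels, trials, window_s = 1,
                      type = c("distance", "divergence")) {
  type <- match.arg(type)
  w <- as.integer(round(window_s * trials$fps))
  n_trials <- nrow(trials$windows)
  first_d <- vector("list", n_trials)
  last_d <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    ps <- trials$windows$practice_start[t]
    pe <- trials$windows$practice_end[t]
    first_d[[t]] <- window_label_dist(labels, ps, ps + w)
    last_d[[t]] <- window_label_dist(labels, pe - w, pe)
  }
  js_or_na <- function(a, b)
    if (is.null(a) || is.null(b)) NA_real_ else js_measure(a, b, type = type)
  online <- vapply(seq_len(n_trials),
                   function(t) js_or_na(first_d[[t]], last_d[[t]]), numeric(1))
  offline <- c(vapply(seq_len(max(n_trials - 1, 0)),
                      function(t) js_or_na(last_d[[t]], first_d[[t + 1]]),
                      numeric(1)), NA_real_)
  data.frame(trial = seq_len(n_trials), online = online, offline = offline)
}

# Distribution of non-noise labels in frames [from, to) (0-based, half-open).
window_label_dist <- function(labels, from, to) {
  win <- labels[(from + 1):to]
  win <- win[!is.na(win) & win != -1]
  label_distribution(win)
}
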