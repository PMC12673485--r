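# ---- fidelity, classification, calibration and inference metrics ----------

#' Confusion-matrix summary metrics
#'
#' @param tn,fp,fn,tp non-negative counts.
#' @return list with `accuracy`, `precision`, `recall`, `f1`. A metric whose
#'   denominator is zero is returned as `NA` with an `undefined` attribute
#'   naming it, never as `NaN`.
#' @examples
#' confusion_metrics(tn = 450, fp = 50, fn = 50, tp = 154)$accuracy  # 0.904
#' @export
confusion_metrics <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0)) stop("confusion_metrics: counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("confusion_metrics: empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  out <- list(accuracy = (tp + tn) / total, precision = precision,
              recall = recall, f1 = f1)
  undef <- names(out)[vapply(out, is.na, logical(1))]
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney form with midranks for ties:
#' `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where `R1` is the rank sum of the
#' positive class.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (0/1 or logical).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("roc_auc: need both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Log loss and Brier score for binary outcomes
#'
#' @param probs predicted probabilities of the positive class.
#' @param labels binary outcomes.
#' @param clamp probabilities are clamped to `[clamp, 1 - clamp]` before the
#'   log terms.
#' @export
log_loss <- function(probs, labels, clamp = 1e-15) {
  labels <- as.numeric(labels)
  p <- pmin(pmax(probs, clamp), 1 - clamp)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' @rdname log_loss
#' @export
brier_score <- function(probs, labels) {
  mean((probs - as.numeric(labels))^2)
}

#' Reliability (calibration) bins
#'
#' Equal-width bins on \[0, 1\]; probabilities exactly at a right edge fall in
#' the lower bin except 0, which falls in the first.
#'
#' @param probs predicted probabilities; @param labels binary outcomes.
#' @param n_bins number of equal-width bins.
#' @return data.frame with one row per bin: `bin`, `lower`, `upper`,
#'   `mean_prob`, `observed_rate`, `count`; empty bins carry `NA` rates.
#' @export
reliability_bins <- function(probs, labels, n_bins = 10) {
  stopifnot(all(probs >= 0 & probs <= 1))
  labels <- as.numeric(labels)
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(probs, edges, rightmost.closed = TRUE, left.open = TRUE)
  idx[probs == 0] <- 1L
  out <- data.frame(bin = seq_len(n_bins),
                    lower = edges[-(n_bins + 1)], upper = edges[-1])
  out$mean_prob <- vapply(seq_len(n_bins), function(b) {
    if (any(idx == b)) mean(probs[idx == b]) else NA_real_ }, numeric(1))
  out$observed_rate <- vapply(seq_len(n_bins), function(b) {
    if (any(idx == b)) mean(labels[idx == b]) else NA_real_ }, numeric(1))
  out$count <- vapply(seq_len(n_bins), function(b) sum(idx == b), integer(1))
  out
}

#' Maximum mean discrepancy (unbiased, RBF kernel)
#'
#' Unbiased U-statistic estimate of squared MMD with kernel
#' `k(x, y) = exp(-||x - y||^2 / (2 h^2))`. The bandwidth `h` defaults to the
#' median of the pooled non-zero pairwise distances (median heuristic). The
#' unbiased estimate can be slightly negative under the null; the returned
#' value is clamped at zero (the raw estimate is kept in the `"raw"`
#' attribute).
#'
#' @param X,Y sample matrices (rows = observations), same column count.
#' @param bandwidth kernel bandwidth h; `NULL` for the median heuristic.
#' @export
mmd_rbf <- function(X, Y, bandwidth = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 2 || nrow(Y) < 2)
    stop("mmd_rbf: need at least 2 samples per side")
  if (ncol(X) != ncol(Y)) stop("mmd_rbf: dimension mismatch")
  Z <- rbind(X, Y)
  D2 <- as.matrix(stats::dist(Z))^2
  if (is.null(bandwidth)) {
    d <- sqrt(D2[upper.tri(D2)])
    d <- d[d > 0]
    bandwidth <- if (length(d)) stats::median(d) else 1
  }
  K <- exp(-D2 / (2 * bandwidth^2))
  m <- nrow(X); n <- nrow(Y)
  Kxx <- K[seq_len(m), seq_len(m)]
  Kyy <- K[m + seq_len(n), m + seq_len(n)]
  Kxy <- K[seq_len(m), m + seq_len(n), drop = FALSE]
  raw <- (sum(Kxx) - m) / (m * (m - 1)) +
    (sum(Kyy) - n) / (n * (n - 1)) - 2 * mean(Kxy)
  structure(max(raw, 0), raw = raw, bandwidth = bandwidth)
}

#' Two-sample Kolmogorov-Smirnov statistic and asymptotic p-value
#'
#' `D` is the supremum gap between the two empirical CDFs; the p-value uses
#' the asymptotic Kolmogorov distribution
#' `Q(lambda) = 2 sum_k (-1)^(k-1) exp(-2 k^2 lambda^2)` with the
#' effective-size correction `lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) D`.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  x <- sort(x[is.finite(x)]); y <- sort(y[is.finite(y)])
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stop("ks_two_sample: empty sample")
  pts <- sort(unique(c(x, y)))
  Fx <- findInterval(pts, x) / n
  Fy <- findInterval(pts, y) / m
  D <- max(abs(Fx - Fy))
  ne <- n * m / (n + m)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(statistic = D, p_value = min(max(p, 0), 1))
}

ngram_counts <- function(tokens, n) {
  if (length(tokens) < n) return(table(character(0)))
  grams <- vapply(seq_len(length(tokens) - n + 1),
                  function(i) paste(tokens[i:(i + n - 1)], collapse = "\u1f"),
                  character(1))
  table(grams)
}

#' Corpus BLEU-4 with add-one smoothing
#'
#' Corpus-level BLEU with uniform weights over 1..4-grams, clipped n-gram
#' precision, add-one smoothing whenever an order's matched (or total) count
#' is zero, and the standard brevity penalty `exp(1 - r/c)` for `c < r`.
#'
#' @param references list of reference token vectors (one per candidate).
#' @param candidates list of candidate token vectors.
#' @param max_n largest n-gram order (default 4).
#' @export
bleu_corpus <- function(references, candidates, max_n = 4) {
  stopifnot(length(references) == length(candidates))
  if (!length(candidates)) stop("bleu_corpus: empty corpus")
  matched <- total <- numeric(max_n)
  r_len <- c_len <- 0
  for (i in seq_along(candidates)) {
    ref <- as.character(references[[i]]); cand <- as.character(candidates[[i]])
    r_len <- r_len + length(ref); c_len <- c_len + length(cand)
    for (n in seq_len(max_n)) {
      rc <- ngram_counts(ref, n); cc <- ngram_counts(cand, n)
      total[n] <- total[n] + sum(cc)
      if (length(cc)) {
        shared <- intersect(names(cc), names(rc))
        matched[n] <- matched[n] + sum(pmin(cc[shared], rc[shared]))
      }
    }
  }
  prec <- vapply(seq_len(max_n), function(n) {
    if (total[n] == 0 || matched[n] == 0)
      (matched[n] + 1) / (total[n] + 1)
    else matched[n] / total[n]
  }, numeric(1))
  bp <- if (c_len > r_len) 1 else exp(1 - r_len / max(c_len, 1))
  bp * exp(mean(log(prec)))
}

#' Percentile bootstrap confidence interval
#'
#' @param statistic function mapping a data subset (rows if matrix-like,
#'   elements otherwise) to a scalar.
#' @param data vector or matrix/data.frame of observations.
#' @param B number of resamples; @param level confidence level.
#' @param seed RNG seed (resampling is deterministic per seed).
#' @return list with `low`, `high`, `point`, `level`, `B`.
#' @export
bootstrap_ci <- function(statistic, data, B = 1000, level = 0.95, seed = 42) {
  take <- function(d, i) if (is.null(dim(d))) d[i] else d[i, , drop = FALSE]
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  point <- statistic(data)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  stats <- vapply(seq_len(B), function(b) {
    statistic(take(data, sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  a <- (1 - level) / 2
  q <- stats::quantile(stats, c(a, 1 - a), names = FALSE, type = 7)
  list(low = q[1], high = q[2], point = point, level = level, B = B)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; ties among absolute differences are
#' mid-ranked. For n <= `exact_n` (and no tied ranks) the null distribution is
#' enumerated exactly over all sign patterns; otherwise a normal approximation
#' with continuity correction and tie-corrected variance is used. If all
#' differences are zero the result is flagged degenerate with p = 1.
#'
#' @param a,b paired numeric vectors.
#' @param exact_n maximum n for exact enumeration (default 12).
#' @return list with `W` (positive-rank sum), `p_value` (two-sided), `n`
#'   (non-zero pairs), `degenerate`, `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_n = 12) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(W = NA_real_, p_value = 1, n = 0L, degenerate = TRUE,
                method = "degenerate"))
  r <- rank(abs(d), ties.method = "average")
  W <- sum(r[d > 0])
  if (n <= exact_n) {
    # exact: enumerate all 2^n sign assignments of the (mid-)ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.vector(signs %*% r)
    p <- mean(abs(Ws - n * (n + 1) / 4) >= abs(W - n * (n + 1) / 4) - 1e-12)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(W = W, p_value = min(p, 1), n = n, degenerate = FALSE, method = method)
}

#' Relative improvement in percent
#'
#' `100 * (augmented - baseline) / baseline`.
#'
#' @param baseline,augmented scalar metrics (baseline non-zero).
#' @export
improvement_pct <- function(baseline, augmented) {
  if (baseline == 0) stop("improvement_pct: baseline is zero")
  100 * (augmented - baseline) / baseline
}
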