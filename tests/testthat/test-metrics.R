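test_that("confusion metrics follow their defining formulas", {
  m <- confusion_metrics(tn = 450, fp = 50, fn = 50, tp = 154)
  expect_equal(m$accuracy, (450 + 154) / 704)
  expect_equal(m$precision, 154 / 204)
  expect_equal(m$recall, 154 / 204)
  m2 <- confusion_metrics(tn = 10, fp = 0, fn = 0, tp = 5)
  expect_equal(unlist(m2[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # degenerate denominators are flagged, not NaN
  m3 <- confusion_metrics(tn = 5, fp = 0, fn = 0, tp = 0)
  expect_true(is.na(m3$precision))
  expect_false(any(vapply(m3, is.nan, logical(1))))
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("confusion metrics agree with direct label counting", {
  set.seed(7)
  for (i in 1:20) {
    y <- rbinom(50, 1, 0.5)
    p <- rbinom(50, 1, 0.5)
    m <- confusion_metrics(tn = sum(y == 0 & p == 0), fp = sum(y == 0 & p == 1),
                           fn = sum(y == 1 & p == 0), tp = sum(y == 1 & p == 1))
    expect_equal(m$accuracy, mean(y == p))
  }
})

test_that("roc_auc matches brute-force pair enumeration", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    s <- round(rnorm(n), 2)   # induce ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    pos <- s[y == 1]; neg <- s[y == 0]
    u <- 0
    for (a in pos) for (b in neg) u <- u + (a > b) + 0.5 * (a == b)
    expect_equal(roc_auc(s, y), u / (length(pos) * length(neg)))
  }
})

test_that("log loss and Brier score evaluate known values", {
  expect_equal(log_loss(rep(0.5, 4), c(0, 1, 0, 1)), log(2))
  expect_equal(brier_score(rep(0.5, 4), c(0, 1, 0, 1)), 0.25)
  expect_lt(log_loss(c(1e-9, 1 - 1e-9), c(0, 1)), 1e-6)
  expect_equal(brier_score(c(0.9, 0.2), c(1, 0)), (0.01 + 0.04) / 2)
  expect_true(is.finite(log_loss(c(0, 1), c(1, 0))))  # clamped, not Inf
})

test_that("reliability bins conserve counts and track calibrated draws", {
  rb <- reliability_bins(rep(0.25, 10), rbinom(10, 1, 0.25))
  expect_equal(sum(rb$count), 10)
  expect_equal(sum(rb$count > 0), 1)
  set.seed(3)
  p <- runif(10000)
  y <- rbinom(10000, 1, p)
  rb <- reliability_bins(p, y)
  expect_equal(sum(rb$count), 10000)
  gaps <- abs(rb$mean_prob - rb$observed_rate)
  expect_lt(max(gaps, na.rm = TRUE), 0.05)
})

test_that("mmd estimator matches hand evaluation and is symmetric", {
  # two identical points per side, cross-kernel ~ 0: within-set means are 1,
  # so the unbiased squared-MMD estimate is 2
  X <- matrix(c(0, 0)); Y <- matrix(c(10, 10))
  expect_equal(as.numeric(mmd_rbf(X, Y, bandwidth = 1)), 2, tolerance = 1e-10)
  set.seed(5)
  A <- matrix(rnorm(40), 20); B <- matrix(rnorm(40), 20) + 1
  expect_equal(as.numeric(mmd_rbf(A, B)), as.numeric(mmd_rbf(B, A)))
  # null behaviour: same distribution, small value
  C <- matrix(rnorm(1000), 500); D <- matrix(rnorm(1000), 500)
  expect_lt(abs(attr(mmd_rbf(C, D), "raw")), 0.01)
  expect_gte(as.numeric(mmd_rbf(C, D)), 0)
  expect_error(mmd_rbf(matrix(1), matrix(1:2)), "2 samples")
})

test_that("two-sample KS matches an O(n^2) ECDF scan", {
  expect_equal(ks_two_sample(1:3, 2:4)$statistic, 1 / 3)
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$statistic, 1)
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.5)
    grid <- c(x, y)
    d_brute <- max(vapply(grid, function(g)
      abs(mean(x <= g) - mean(y <= g)), numeric(1)))
    expect_equal(ks_two_sample(x, y)$statistic, d_brute)
  }
  # asymptotic p agrees with stats::ks.test's asymptotic branch
  set.seed(14)
  x <- rnorm(60); y <- rnorm(70, 0.3)
  p_ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE)$p.value)
  expect_equal(ks_two_sample(x, y)$p_value, p_ref, tolerance = 0.06)
})

test_that("corpus BLEU matches manual n-gram counting", {
  ref <- list(c("the", "cat", "sat"))
  expect_equal(bleu_corpus(ref, ref), 1)
  # cand "the cat": p1 = p2 = 1, empty 3/4-gram orders smooth to 1,
  # brevity penalty exp(1 - 3/2)
  expect_equal(bleu_corpus(ref, list(c("the", "cat"))), exp(-0.5))
  expect_lt(bleu_corpus(list(paste0("a", 1:100)),
                        list(paste0("b", 1:100))), 0.02)
  # token vectors (integers) work the same way
  expect_equal(bleu_corpus(list(1:5), list(1:5)), 1)
})

test_that("bootstrap intervals are deterministic per seed with sane width", {
  b1 <- bootstrap_ci(mean, rep(3, 50), B = 200, seed = 9)
  expect_equal(b1$low, 3); expect_equal(b1$high, 3)
  x <- rnorm(100)
  b2 <- bootstrap_ci(mean, x, B = 500, seed = 4)
  b3 <- bootstrap_ci(mean, x, B = 500, seed = 4)
  expect_identical(b2, b3)
  expect_lt(b2$low, b2$point); expect_gt(b2$high, b2$point)
})

test_that("bootstrap percentile interval has near-nominal coverage", {
  set.seed(21)
  hits <- vapply(1:300, function(r) {
    x <- rnorm(200)
    ci <- bootstrap_ci(mean, x, B = 400, seed = r)
    ci$low <= 0 && 0 <= ci$high
  }, logical(1))
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)
})

test_that("wilcoxon signed-rank matches exact sign-pattern enumeration", {
  d <- c(1, 2, 3, 4, 5, -6)
  res <- wilcoxon_signed_rank(d, rep(0, 6))
  # independent oracle: enumerate all 2^6 sign assignments
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- 6 * 7 / 4
  Ws <- apply(as.matrix(expand.grid(rep(list(0:1), 6))), 1,
              function(s) sum(r * s))
  p_exact <- mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
  expect_equal(res$W, W_obs)
  expect_equal(res$p_value, p_exact)
  expect_equal(res$method, "exact")
})

test_that("wilcoxon handles degenerate and large-sample cases", {
  res <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  a <- rnorm(40); b <- rnorm(40, 0.1)
  r1 <- wilcoxon_signed_rank(a, b)
  r2 <- wilcoxon_signed_rank(b, a)
  n <- r1$n
  expect_equal(r1$W + r2$W, n * (n + 1) / 2)  # antisymmetry about the range
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$method, "normal")
  # sanity against the stats implementation on tie-free data
  set.seed(31)
  x <- rnorm(30); y <- rnorm(30, 0.4)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("improvement percentage follows its formula", {
  expect_equal(improvement_pct(0.99, 1.00), 100 / 99)
  expect_equal(improvement_pct(0.98, 1.00), 100 * 0.02 / 0.98)
  expect_equal(improvement_pct(2, 2), 0)
  expect_error(improvement_pct(0, 1), "zero")
})
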