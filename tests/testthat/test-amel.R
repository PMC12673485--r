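test_that("gating weights are a masked softmax on the simplex", {
  expect_equal(gating_weights(rep(1.7, 5)), rep(0.2, 5))
  expect_equal(gating_weights(c(0, log(2))), c(1 / 3, 2 / 3))
  a <- gating_weights(c(1, 2, 3, 4, 5), mask = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(a[3], 0)
  expect_equal(sum(a), 1)
  # masking then renormalising equals softmax over the remaining scores
  s <- c(1, 2, 3)
  a2 <- gating_weights(s, mask = c(TRUE, FALSE, TRUE))
  ref <- exp(s[c(1, 3)]) / sum(exp(s[c(1, 3)]))
  expect_equal(a2[c(1, 3)], ref)
  expect_error(gating_weights(1:3, mask = rep(FALSE, 3)), "masked")
  set.seed(41)
  A <- gating_weights(matrix(rnorm(40), 8),
                      matrix(runif(40) > 0.3, 8))
  expect_simplex(A)
})

test_that("ensemble prediction mixes expert probabilities correctly", {
  l1 <- matrix(log(c(0.8, 0.2)), 1)   # softmax gives (0.8, 0.2)
  l2 <- matrix(log(c(0.4, 0.6)), 1)
  y <- ensemble_predict(list(l1, l2), c(0.5, 0.5))
  expect_equal(as.vector(y), c(0.6, 0.4))
  # one-hot alpha selects that expert's probabilities
  y2 <- ensemble_predict(list(l1, l2), c(0, 1))
  expect_equal(as.vector(y2), c(0.4, 0.6))
  # identical experts make alpha irrelevant
  y3a <- ensemble_predict(list(l1, l1), c(0.9, 0.1))
  y3b <- ensemble_predict(list(l1, l1), c(0.2, 0.8))
  expect_equal(y3a, y3b)
  # logit-space variant is the plain weighted sum
  y4 <- ensemble_predict(list(l1, l2), c(0.5, 0.5), space = "logit")
  expect_equal(y4, 0.5 * l1 + 0.5 * l2)
})

test_that("gating entropy has its analytic extremes", {
  expect_equal(gating_entropy(rep(0.2, 5)), log(5))
  expect_equal(gating_entropy(c(1, 0, 0, 0, 0)), 0)
  set.seed(43)
  for (i in 1:25) {
    a <- runif(5); a <- a / sum(a)
    expect_lte(gating_entropy(a), log(5) + 1e-12)
  }
})

test_that("amel loss gradients match finite differences end to end", {
  set.seed(44)
  n <- 12
  inputs <- list(image = matrix(rnorm(n * 64), n),
                 eeg = matrix(rnorm(n * 4 * 250), n),
                 tabular = matrix(rnorm(n * 10), n),
                 latent = matrix(rnorm(n * 16), n))
  labels <- rep(0:1, 6)
  model <- amel_init(list(image_edge = 4, eeg_channels = 4, eeg_sfreq = 250,
                          eeg_samples = 250, tabular = 10, latent = 16),
                     config = gating_config(dropout = 0), seed = 44)
  adj <- mmsynth:::knn_adjacency(inputs$tabular)
  loss_of <- function(m) {
    fw <- mmsynth:::amel_forward(m, inputs, adj = adj)
    mmsynth:::amel_loss_grads(m, fw, labels)$loss
  }
  fw <- mmsynth:::amel_forward(model, inputs, adj = adj)
  lg <- mmsynth:::amel_loss_grads(model, fw, labels)
  eps <- 1e-6
  # tabular expert weight (gradient includes mixture + aux + gating paths)
  g_tab <- mmsynth:::mlp_backward(model$experts$tabular$net,
                                  fw$caches$tabular, lg$dLogits[[3]])$grads
  m2 <- model
  m2$experts$tabular$net$layers[[1]]$W[2, 3] <-
    m2$experts$tabular$net$layers[[1]]$W[2, 3] + eps
  num <- (loss_of(m2) - loss_of(model)) / eps
  l2 <- model$config$l2
  ana <- g_tab[[1]]$W[2, 3] +
    2 * l2 * model$experts$tabular$net$layers[[1]]$W[2, 3]
  expect_equal(ana, num, tolerance = 1e-3)
  # gating weight
  gb <- lg$gate_grads
  m3 <- model
  m3$gate$layers[[1]]$W[4, 5] <- m3$gate$layers[[1]]$W[4, 5] + eps
  num_g <- (loss_of(m3) - loss_of(model)) / eps
  expect_equal(gb[[1]]$W[4, 5], num_g, tolerance = 1e-3)
  # graph expert weight
  m4 <- model
  m4$experts$graph$W1[3, 2] <- m4$experts$graph$W1[3, 2] + eps
  num_gr <- (loss_of(m4) - loss_of(model)) / eps
  cg <- fw$caches$graph
  dAH1 <- lg$dLogits[[5]] %*% t(model$experts$graph$W2)
  dZ <- (t(cg$adj) %*% dAH1) * (cg$H1z > 0)
  ana_gr <- (crossprod(cg$adj %*% cg$X, dZ))[3, 2] +
    2 * l2 * model$experts$graph$W1[3, 2]
  expect_equal(ana_gr, num_gr, tolerance = 1e-3)
})

test_that("a single available expert is the ensemble", {
  set.seed(45)
  n <- 6
  inputs <- list(image = matrix(rnorm(n * 64), n),
                 eeg = matrix(rnorm(n * 1000), n),
                 tabular = matrix(rnorm(n * 10), n),
                 latent = matrix(rnorm(n * 16), n))
  model <- amel_init(list(image_edge = 4, eeg_channels = 4, eeg_sfreq = 250,
                          eeg_samples = 250, tabular = 10, latent = 16),
                     seed = 45)
  pr <- predict_amel(model, inputs,
                     available = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  solo <- mmsynth:::softmax_rows(pr$expert_logits$tabular)
  expect_equal(pr$yhat, solo, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(unname(pr$alpha[, 3]), rep(1, n))
})

test_that("missing-modality prediction redistributes weights gracefully", {
  set.seed(46)
  n <- 8
  inputs <- list(image = matrix(rnorm(n * 64), n),
                 eeg = matrix(rnorm(n * 1000), n),
                 tabular = matrix(rnorm(n * 10), n),
                 latent = matrix(rnorm(n * 16), n))
  model <- amel_init(list(image_edge = 4, eeg_channels = 4, eeg_sfreq = 250,
                          eeg_samples = 250, tabular = 10, latent = 16),
                     seed = 46)
  full <- predict_amel(model, inputs)
  expect_simplex(full$alpha)
  drop1 <- predict_amel(model, inputs,
                        available = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(unname(drop1$alpha[, 2]), rep(0, n))
  expect_simplex(drop1$alpha)
  # full availability equals the default path
  full2 <- predict_amel(model, inputs, available = rep(TRUE, 5))
  expect_equal(full2$yhat, full$yhat)
})

test_that("training reduces the loss and a dominant entropy weight uniformises", {
  set.seed(47)
  losses <- vapply(c(42, 123, 2025), function(s) {
    b <- benchmark_cohort(120, seed = s)
    n <- 120
    inputs <- list(image = matrix(rnorm(n * 64), n),
                   eeg = matrix(rnorm(n * 1000), n),
                   tabular = b$X$tabular,
                   latent = b$X$embedding[, 1:16])
    tr <- 1:80; va <- 81:120
    gi <- function(r) lapply(inputs, function(m) m[r, , drop = FALSE])
    model <- amel_init(list(image_edge = 4, eeg_channels = 4, eeg_sfreq = 250,
                            eeg_samples = 250, tabular = 14, latent = 16),
                       seed = s)
    fit <- train_amel(gi(tr), b$labels[tr] - 1, gi(va), b$labels[va] - 1,
                      model, epochs = 6, seed = s)
    fit$history$loss[6] - fit$history$loss[1]
  }, numeric(1))
  expect_lt(median(losses), 0)
  # lambda = 10 forces near-uniform gating
  b <- benchmark_cohort(100, seed = 1)
  n <- 100
  inputs <- list(image = matrix(rnorm(n * 64), n),
                 eeg = matrix(rnorm(n * 1000), n),
                 tabular = b$X$tabular, latent = b$X$embedding[, 1:16])
  tr <- 1:70; va <- 71:100
  gi <- function(r) lapply(inputs, function(m) m[r, , drop = FALSE])
  model <- amel_init(list(image_edge = 4, eeg_channels = 4, eeg_sfreq = 250,
                          eeg_samples = 250, tabular = 14, latent = 16),
                     config = gating_config(entropy_weight = 10),
                     seed = 1)
  fit <- train_amel(gi(tr), b$labels[tr] - 1, gi(va), b$labels[va] - 1,
                    model, epochs = 40, seed = 1)
  pr <- predict_amel(fit$model, gi(va))
  expect_gt(mean(apply(pr$alpha, 1, gating_entropy)), 0.95 * log(5))
})

test_that("gating down-weights an uninformative expert without entropy reward", {
  b <- benchmark_cohort(240, seed = 9)
  n <- 240
  set.seed(9)
  inputs <- list(image = matrix(rnorm(n * 64), n),   # pure noise modality
                 eeg = matrix(rnorm(n * 1000), n),   # pure noise modality
                 tabular = b$X$tabular,              # carries the signal
                 latent = b$X$embedding[, 1:16])
  tr <- 1:170; va <- 171:240
  gi <- function(r) lapply(inputs, function(m) m[r, , drop = FALSE])
  model <- amel_init(list(image_edge = 4, eeg_channels = 4, eeg_sfreq = 250,
                          eeg_samples = 250, tabular = 14, latent = 16),
                     config = gating_config(entropy_weight = 0), seed = 9)
  fit <- train_amel(gi(tr), b$labels[tr] - 1, gi(va), b$labels[va] - 1,
                    model, epochs = 120, seed = 9)
  pr <- predict_amel(fit$model, gi(va))
  expect_lt(mean(pr$alpha[, "image" == mmsynth:::expert_names()]), 1 / 5)
})

test_that("gating reports export per-sample weights", {
  set.seed(48)
  n <- 5
  inputs <- list(image = matrix(rnorm(n * 64), n),
                 eeg = matrix(rnorm(n * 1000), n),
                 tabular = matrix(rnorm(n * 10), n),
                 latent = matrix(rnorm(n * 16), n))
  model <- amel_init(list(image_edge = 4, eeg_channels = 4, eeg_sfreq = 250,
                          eeg_samples = 250, tabular = 10, latent = 16),
                     seed = 48)
  path <- tempfile(fileext = ".csv")
  rep <- gating_report(model, inputs, path)
  expect_equal(dim(rep), c(5, 5))
  expect_equal(names(rep), mmsynth:::expert_names())
  expect_true(file.exists(path))
  back <- utils::read.csv(path)
  expect_equal(unname(as.matrix(back)), unname(as.matrix(rep)),
               tolerance = 1e-10)
})
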