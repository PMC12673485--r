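test_that("scaled dot-product attention matches hand arithmetic", {
  # 2x2 toy, d_k = 2
  Q <- matrix(c(1, 0, 0, 1), 2)
  K <- matrix(c(1, 2, 3, 4), 2)
  V <- matrix(c(1, 0, 0, 1), 2)
  a <- attention(Q, K, V)
  S <- Q %*% t(K) / sqrt(2)
  W <- exp(S) / rowSums(exp(S))
  expect_equal(a$out, W %*% V, tolerance = 1e-12)
  expect_equal(a$weights, W, tolerance = 1e-12)
  # single token: softmax of one logit
  a1 <- attention(matrix(1, 1, 3), matrix(2, 1, 3), matrix(5, 1, 2))
  expect_equal(a1$weights, matrix(1))
  # all-equal keys: uniform rows 1/T
  aK <- attention(matrix(rnorm(6), 2), matrix(1, 4, 3), matrix(rnorm(8), 4))
  expect_equal(unname(aK$weights), matrix(0.25, 2, 4), tolerance = 1e-12)
})

test_that("attention rows are probability vectors for random inputs", {
  set.seed(17)
  for (i in 1:10) {
    a <- attention(matrix(rnorm(12), 4), matrix(rnorm(15), 5),
                   matrix(rnorm(10), 5))
    expect_simplex(a$weights)
  }
})

test_that("modality encoders produce row-stochastic attention and d_model output", {
  set.seed(20)
  cfg <- encoder_config("desk")
  enc <- mmsynth:::make_encoder(token_dim = 6, n_tokens = 5, cfg, "sin")
  h <- encode_modality(matrix(rnorm(30), 5), enc)
  expect_equal(dim(h), c(5, 32))
  att <- attr(h, "attention")
  for (head in att) expect_simplex(head)
  expect_error(encode_modality(matrix(0, 0, 6), enc), "empty")
  # deterministic forward
  h2 <- encode_modality(matrix(seq_len(30) / 10, 5), enc)
  h3 <- encode_modality(matrix(seq_len(30) / 10, 5), enc)
  expect_identical(h2, h3)
})

test_that("cross-modal fusion projects to d_latent and respects symmetry", {
  set.seed(21)
  st <- madsn_init(list(embedding = list(dim = 8), tabular = list(dim = 6)),
                   seed = 1)
  h1 <- matrix(rnorm(3 * 32), 3)
  h2 <- matrix(rnorm(2 * 32), 2)
  z <- cross_modal_fuse(list(a = h1, b = h2), st$fuser)
  expect_length(z, 16)
  expect_true(all(is.finite(z)))
  # identical embeddings: cross-attention equals self-attention on h1
  ca <- attention(h1 %*% st$fuser$Wq, h1 %*% st$fuser$Wk, h1 %*% st$fuser$Wv)
  zb <- cross_modal_fuse(list(a = h1, b = h1), st$fuser)
  pooled <- colMeans(ca$out)
  manual <- as.vector(c(pooled, pooled) %*% st$fuser$W_proj + st$fuser$b_proj)
  expect_equal(zb, manual, tolerance = 1e-12)
  # permuting modality order with permuted projection rows leaves z unchanged
  fuser_perm <- st$fuser
  fuser_perm$W_proj <- st$fuser$W_proj[c(33:64, 1:32), ]
  z_perm <- cross_modal_fuse(list(b = h2, a = h1), fuser_perm)
  expect_equal(z_perm, z, tolerance = 1e-10)
  expect_message(cross_modal_fuse(list(a = h1), st$fuser), "single modality")
})

test_that("consistency loss matches its formula and scales quadratically", {
  expect_equal(consistency_loss(list(c(1, 2), c(1, 2), c(1, 2))), 0)
  expect_equal(consistency_loss(list(c(1, 0), c(0, 1))), 4)
  h <- list(rnorm(5), rnorm(5), rnorm(5))
  base <- consistency_loss(h)
  expect_equal(consistency_loss(lapply(h, `*`, 3)), 9 * base)
  expect_gte(base, 0)
})

test_that("adversarial losses evaluate their closed forms", {
  expect_equal(loss_discriminator(0.5, 0.5), 2 * log(2))
  expect_equal(loss_discriminator(0.9, 0.1), -(log(0.9) + log(0.9)),
               tolerance = 1e-12)
  expect_lt(loss_discriminator(1 - 1e-9, 1e-9), 1e-5)
  expect_equal(loss_generator(1, 0, 0.1), 0, tolerance = 1e-6)
  expect_equal(loss_generator(0.5, 2, 0.1), log(2) + 0.2)
  expect_equal(loss_generator(0.5, 2, 0), log(2))
  # clamp keeps the losses finite at the boundary
  expect_true(is.finite(loss_discriminator(0, 1)))
})

test_that("mlp engine backpropagates exact gradients", {
  set.seed(23)
  net <- mmsynth:::mlp_init(c(4, 6, 3), act = "lrelu")
  X <- matrix(rnorm(20), 5)
  Y <- matrix(rnorm(15), 5)
  loss <- function(n) sum((mmsynth:::mlp_forward(n, X)$out - Y)^2)
  fw <- mmsynth:::mlp_forward(net, X)
  bw <- mmsynth:::mlp_backward(net, fw$cache, 2 * (fw$out - Y))
  eps <- 1e-6
  for (l in 1:2) {
    for (idx in list(c(1, 1), c(2, 3))) {
      n2 <- net
      n2$layers[[l]]$W[idx[1], idx[2]] <-
        n2$layers[[l]]$W[idx[1], idx[2]] + eps
      num <- (loss(n2) - loss(net)) / eps
      expect_equal(bw$grads[[l]]$W[idx[1], idx[2]], num, tolerance = 1e-3)
    }
  }
  # factored per-sample norms equal the norms of explicit per-sample grads
  G <- mmsynth:::per_sample_grad_matrix(bw$per_layer)
  expect_equal(mmsynth:::per_sample_grad_norms(bw$per_layer),
               sqrt(rowSums(G^2)), tolerance = 1e-10)
})

test_that("dp gradient path reduces to plain averaging when mechanism is off", {
  set.seed(24)
  net <- mmsynth:::mlp_init(c(3, 5, 2), act = "lrelu")
  X <- matrix(rnorm(12), 4)
  fw <- mmsynth:::mlp_forward(net, X)
  dOut <- matrix(rnorm(8), 4)
  bw <- mmsynth:::mlp_backward(net, fw$cache, dOut)
  gdp <- mmsynth:::dp_layer_grads(bw$per_layer, clip_norm = Inf,
                                  noise_multiplier = 0)
  for (l in 1:2) {
    expect_identical(gdp[[l]]$W, bw$grads[[l]]$W / 4)
    expect_identical(gdp[[l]]$b, bw$grads[[l]]$b / 4)
  }
  # paired-pass variant: every clipped per-sample norm is <= C
  bw2 <- mmsynth:::mlp_backward(net, fw$cache, dOut * 2)
  C <- 0.05
  g2 <- mmsynth:::dp_pair_grads(bw$per_layer, bw2$per_layer, C, 0)
  total <- sqrt(sum(vapply(g2, function(g) sum(g$W^2) + sum(g$b^2),
                           numeric(1)))) * 4
  expect_lte(total, 4 * C + 1e-10)  # sum of 4 clipped grads
})

test_that("generation is deterministic with configured shapes and conditions", {
  st <- madsn_init(list(embedding = list(dim = 8), tabular = list(dim = 6)),
                   seed = 2)
  set.seed(30)
  z <- matrix(rnorm(4 * 16), 4)
  eta <- matrix(rnorm(4 * 16), 4)
  out1 <- madsn_generate(st, z, eta, c(1, 2, 1, 2))
  expect_equal(dim(out1$embedding), c(4, 8))
  expect_equal(dim(out1$tabular), c(4, 6))
  out2 <- madsn_generate(st, z, eta, c(1, 2, 1, 2))
  expect_identical(out1, out2)
  expect_error(madsn_generate(st, z, eta, c(1, 3, 1, 2)), "condition")
})

test_that("dp-sgd training logs the ledger and respects the budget", {
  d <- gaussian_toy(42, n = 96)
  st <- madsn_init(list(embedding = list(dim = 8), tabular = list(dim = 6)),
                   seed = 42)
  fit <- train_madsn(d$X, d$y, st,
                     dp = dp_config(noise_multiplier = 1.2,
                                    epsilon_budget = 20),
                     epochs = 3, batch_size = 32, seed = 42)
  expect_equal(fit$ledger$steps, 9L)        # 3 discriminator steps per epoch
  expect_equal(nrow(fit$history), 3)
  expect_true(all(c("loss_d", "loss_g", "loss_cons", "d_accuracy",
                    "epsilon") %in% names(fit$history)))
  expect_true(all(diff(fit$history$epsilon) > 0))
  # an exhausted budget before one epoch is a configuration error
  expect_error(train_madsn(d$X, d$y, st,
                           dp = dp_config(noise_multiplier = 0.3,
                                          epsilon_budget = 0.01),
                           epochs = 1, batch_size = 32, seed = 1),
               "budget")
})

test_that("training improves fidelity on the planted gaussian toy", {
  res <- vapply(c(42, 123), function(s) {
    d <- gaussian_toy(s)
    st <- madsn_init(list(embedding = list(dim = 8), tabular = list(dim = 6)),
                     seed = s)
    gen_mmd <- function(state) {
      set.seed(s + 999)
      z <- matrix(rnorm(200 * 16), 200)
      eta <- matrix(rnorm(200 * 16), 200)
      xg <- madsn_generate(state, z, eta, d$y)
      as.numeric(mmd_rbf(do.call(cbind, d$X), cbind(xg$embedding, xg$tabular)))
    }
    m0 <- gen_mmd(st)
    fit <- train_madsn(d$X, d$y, st,
                       dp = dp_config(noise_multiplier = 0,
                                      epsilon_budget = 99),
                       epochs = 50, seed = s)
    m0 - gen_mmd(fit$state)
  }, numeric(1))
  expect_gt(median(res), 0)
})

test_that("conditioning recovers the planted class axis and marginals", {
  res <- sapply(c(42, 123, 2025), function(s) {
    b <- benchmark_cohort(400, seed = s)
    st <- madsn_init(list(embedding = list(dim = 32), tabular = list(dim = 14)),
                     lr = 5e-3, seed = s)
    fit <- train_madsn(b$X, b$labels, st,
                       dp = dp_config(noise_multiplier = 0,
                                      epsilon_budget = 99),
                       epochs = 200, seed = s)
    set.seed(s + 9)
    z <- matrix(rnorm(400 * 16), 400)
    eta <- matrix(rnorm(400 * 16), 400)
    cc <- rep(1:2, length.out = 400)
    Xg <- madsn_generate(fit$state, z, eta, cc)
    proj <- rowMeans(Xg$tabular[, 1:8]) - rowMeans(Xg$tabular[, 9:14])
    c(gap = mean(proj[cc == 2]) - mean(proj[cc == 1]),
      ks = ks_two_sample(Xg$tabular[, 1], b$X$tabular[, 1])$statistic)
  })
  # class-conditional means separate with the planted sign
  expect_gt(median(res["gap", ]), 0)
  # synthetic marginal of the planted feature stays distributionally close
  expect_lt(median(res["ks", ]), 0.35)
})

test_that("synthesized cohorts honour the condition mix and round-trip", {
  co <- generate_cohort(small_cohort_config(n = 80, seed = 42))
  suppressMessages(sp <- stratified_split(co, seed = 42))
  tab <- cohort_table(co)
  st <- fit_preprocess(tab[sp$split == "train", ])
  pp <- apply_preprocess(co, st)
  dims <- list(eeg = list(channels = 4, samples = 250),
               image = list(edge = 4), embedding = list(dim = 32),
               tabular = list(dim = ncol(pp$tabular)))
  ms <- madsn_init(dims, seed = 42)
  X <- list(eeg = pp$eeg, image = pp$image, embedding = pp$embedding,
            tabular = pp$tabular)
  fit <- train_madsn(X, pp$labels + 1L, ms,
                     dp = dp_config(noise_multiplier = 0,
                                    epsilon_budget = 99),
                     epochs = 2, seed = 42)
  syn <- madsn_synthesize(fit$state, 40, condition_mix = c(0.5, 0.5),
                          preprocess = st, template_config = co$config,
                          seed = 7)
  labs <- vapply(syn$records, `[[`, 0L, "label")
  expect_equal(sum(labs == 1), 20L)
  expect_true(isTRUE(syn$provenance$synthetic))
  expect_equal(dim(syn$records[[1]]$eeg), c(4, 250))
  expect_true(all(syn$records[[3]]$behavior_tokens >= 0 &
                    syn$records[[3]]$behavior_tokens < 16))
  dir <- file.path(tempdir(), "syn_rt")
  write_cohort(syn, dir)
  syn2 <- read_cohort(dir)
  expect_identical(syn2$records[[5]]$eeg, syn$records[[5]]$eeg)
  unlink(dir, recursive = TRUE)
  expect_error(madsn_synthesize(ms, 10, preprocess = st,
                                template_config = co$config),
               "trained")
})
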