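# ---- multimodal synthesis network: encoders, fusion, conditional GAN -------

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`. Every row of the weight matrix is a
#' probability vector.
#'
#' @param Q,K,V query/key/value matrices (rows = tokens); `K` and `V` share
#'   their token count, `Q` and `K` their width.
#' @return list with `out` and the row-stochastic `weights`.
#' @export
attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  W <- softmax_rows(Q %*% t(K) / sqrt(ncol(K)))
  list(out = W %*% V, weights = W)
}

#' Encoder/generator architecture configuration
#'
#' Full-scale defaults (6 layers, 8 heads, width 512, 256-d latent) follow
#' the published architecture; `profile = "desk"` shrinks to sizes a single
#' CPU trains in seconds (2 layers, 2 heads, width 32, 16-d latent).
#'
#' @param profile `"desk"` or `"paper"`.
#' @param n_layers,n_heads,d_model,d_latent,dropout_gen overrides.
#' @export
encoder_config <- function(profile = c("desk", "paper"), n_layers = NULL,
                           n_heads = NULL, d_model = NULL, d_latent = NULL,
                           dropout_gen = 0.3) {
  profile <- match.arg(profile)
  def <- if (profile == "paper")
    list(n_layers = 6L, n_heads = 8L, d_model = 512L, d_latent = 256L)
  else
    list(n_layers = 2L, n_heads = 2L, d_model = 32L, d_latent = 16L)
  cfg <- list(n_layers = n_layers %||% def$n_layers,
              n_heads = n_heads %||% def$n_heads,
              d_model = d_model %||% def$d_model,
              d_latent = d_latent %||% def$d_latent,
              dropout_gen = dropout_gen, profile = profile)
  if (cfg$d_model %% cfg$n_heads != 0)
    stop("encoder_config: d_model must be divisible by n_heads")
  if (dropout_gen < 0 || dropout_gen >= 1)
    stop("encoder_config: dropout_gen must be in [0, 1)")
  structure(cfg, class = "encoder_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sinusoidal_pe <- function(n_tokens, d_model) {
  pos <- seq_len(n_tokens) - 1
  i <- seq_len(d_model) - 1
  ang <- outer(pos, 10000^(-2 * (i %/% 2) / d_model))
  pe <- ang
  pe[, i %% 2 == 0] <- sin(ang[, i %% 2 == 0, drop = FALSE])
  pe[, i %% 2 == 1] <- cos(ang[, i %% 2 == 1, drop = FALSE])
  pe
}

# build a fixed (seeded at state init) transformer encoder for one modality.
# token_dim: width of one token; n_tokens: token count; positional: "sin"
# (EEG temporal patches) or "learned" (image sub-blocks, token embeddings)
make_encoder <- function(token_dim, n_tokens, cfg, positional = "sin") {
  d <- cfg$d_model
  rw <- function(a, b, sc = sqrt(1 / a)) matrix(stats::rnorm(a * b, sd = sc), a, b)
  layers <- lapply(seq_len(cfg$n_layers), function(l) list(
    Wq = rw(d, d), Wk = rw(d, d), Wv = rw(d, d), Wo = rw(d, d),
    W1 = rw(d, 2 * d), W2 = rw(2 * d, d)))
  list(W_embed = rw(token_dim, d),
       pos = if (positional == "sin") sinusoidal_pe(n_tokens, d)
             else rw(n_tokens, d, sc = 0.5),
       layers = layers, token_dim = token_dim, n_tokens = n_tokens,
       n_heads = cfg$n_heads, d_model = d)
}

multihead_self_attention <- function(X, layer, n_heads) {
  d <- ncol(X); dh <- d / n_heads
  out <- matrix(0, nrow(X), d)
  weights <- vector("list", n_heads)
  Q <- X %*% layer$Wq; K <- X %*% layer$Wk; V <- X %*% layer$Wv
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    a <- attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                   V[, cols, drop = FALSE])
    out[, cols] <- a$out
    weights[[h]] <- a$weights
  }
  list(out = out %*% layer$Wo, weights = weights)
}

#' Encode one modality into token embeddings
#'
#' Tokens (already cut from the raw tensor) are linearly embedded, positional
#' information is added (sinusoidal for temporal EEG patches, learned-style
#' fixed embeddings otherwise), and `n_layers` residual self-attention +
#' feed-forward blocks are applied. Attention weight rows are probability
#' vectors; the last layer's weights are attached as the
#' `"attention"` attribute.
#'
#' @param tokens n_tokens x token_dim matrix (at least one token).
#' @param encoder a `make_encoder()` structure (held inside a MADSN state).
#' @return n_tokens x d_model embedding matrix.
#' @export
encode_modality <- function(tokens, encoder) {
  tokens <- as.matrix(tokens)
  if (!nrow(tokens)) stop("encode_modality: empty token sequence")
  X <- tokens %*% encoder$W_embed + encoder$pos[seq_len(nrow(tokens)), ,
                                                drop = FALSE]
  att <- NULL
  for (layer in encoder$layers) {
    mha <- multihead_self_attention(X, layer, encoder$n_heads)
    X <- X + mha$out
    X <- X + pmax(X %*% layer$W1, 0) %*% layer$W2
    att <- mha$weights
  }
  attr(X, "attention") <- att
  X
}

#' Fuse per-modality embeddings into one latent vector
#'
#' For every ordered modality pair (i, j) a cross-attention block computes
#' `a_ij = softmax((Wq h_i)(Wk h_j)' / sqrt(d)) (Wv h_j)`; outputs are
#' mean-pooled over tokens and partners per modality, concatenated in
#' modality order, and linearly projected to `d_latent`. A single modality
#' degenerates to its pooled projection (with a message).
#'
#' @param h_list named list of token-embedding matrices (one per modality).
#' @param fuser fusion parameters from a MADSN state.
#' @return latent numeric vector of length `d_latent`.
#' @export
cross_modal_fuse <- function(h_list, fuser) {
  M <- length(h_list)
  if (M < 1) stop("cross_modal_fuse: no modalities")
  if (M == 1) {
    message("cross_modal_fuse: single modality, degenerate pooled projection")
    pooled <- colMeans(h_list[[1]] %*% fuser$Wv)
    reps <- do.call(c, rep(list(pooled), fuser$n_modalities))
    return(as.vector(reps %*% fuser$W_proj + fuser$b_proj))
  }
  pooled <- lapply(seq_len(M), function(i) {
    outs <- lapply(setdiff(seq_len(M), i), function(j) {
      a <- attention(h_list[[i]] %*% fuser$Wq, h_list[[j]] %*% fuser$Wk,
                     h_list[[j]] %*% fuser$Wv)
      colMeans(a$out)
    })
    Reduce(`+`, outs) / length(outs)
  })
  as.vector(do.call(c, pooled) %*% fuser$W_proj + fuser$b_proj)
}

#' Cross-modal consistency loss
#'
#' `sum_{i != j} || h_i - h_j ||^2` over ordered pairs of pooled modality
#' embeddings; non-negative, zero iff all embeddings are equal, and
#' homogeneous of degree 2.
#'
#' @param h_pooled list of pooled embedding vectors of equal length.
#' @export
consistency_loss <- function(h_pooled) {
  M <- length(h_pooled)
  if (M < 2) return(0)
  s <- 0
  for (i in seq_len(M)) for (j in seq_len(M)) if (i != j)
    s <- s + sum((h_pooled[[i]] - h_pooled[[j]])^2)
  s
}

#' Adversarial losses (non-saturating conditional GAN)
#'
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logs.
#' `loss_discriminator` is `-[log D(x_real, c) + log(1 - D(x_gen, c))]`;
#' `loss_generator` is `-log D(x_gen, c) + lambda_cons * L_cons`.
#'
#' @param d_real,d_fake discriminator probabilities on real/generated data.
#' @param l_cons consistency penalty value; @param lambda_cons its weight.
#' @export
loss_discriminator <- function(d_real, d_fake) {
  p <- function(x) pmin(pmax(x, 1e-7), 1 - 1e-7)
  mean(-(log(p(d_real)) + log(1 - p(d_fake))))
}

#' @rdname loss_discriminator
#' @export
loss_generator <- function(d_fake, l_cons = 0, lambda_cons = 0.1) {
  p <- function(x) pmin(pmax(x, 1e-7), 1 - 1e-7)
  mean(-log(p(d_fake))) + lambda_cons * l_cons
}

# ---- tokenisers -------------------------------------------------------------

# cut a flattened modality vector into tokens; spec per modality kind
make_tokenizer <- function(kind, dims) {
  switch(kind,
    eeg = {  # temporal patches, all channels per window
      ch <- dims$channels; ns <- dims$samples
      w <- max(1, min(50, ns))
      nt <- ns %/% w
      list(n_tokens = nt, token_dim = ch * w, positional = "sin",
           cut = function(x) {
             m <- matrix(x, ch, ns)
             t(vapply(seq_len(nt), function(t0)
               as.vector(m[, ((t0 - 1) * w + 1):(t0 * w)]),
               numeric(ch * w)))
           })
    },
    image = {  # 2x2x2 sub-blocks
      e <- dims$edge; b <- 2L
      nb <- e %/% b
      idx <- expand.grid(x = seq_len(nb), y = seq_len(nb), z = seq_len(nb))
      list(n_tokens = nrow(idx), token_dim = b^3, positional = "learned",
           cut = function(x) {
             a <- array(x, dim = c(e, e, e))
             t(vapply(seq_len(nrow(idx)), function(k) {
               i <- (idx$x[k] - 1) * b; j <- (idx$y[k] - 1) * b
               l <- (idx$z[k] - 1) * b
               as.vector(a[i + 1:2, j + 1:2, l + 1:2])
             }, numeric(b^3)))
           })
    },
    embedding = {  # fixed-width chunks of the behavioural embedding
      d <- dims$dim; w <- max(1, min(8, d))
      nt <- ceiling(d / w)
      list(n_tokens = nt, token_dim = w, positional = "learned",
           cut = function(x) {
             xp <- c(x, numeric(nt * w - d))
             matrix(xp, nt, w, byrow = TRUE)
           })
    },
    tabular = list(n_tokens = 1L, token_dim = dims$dim, positional = "learned",
                   cut = function(x) matrix(x, 1)),
    stop("unknown modality kind: ", kind)
  )
}

# ---- MADSN state ------------------------------------------------------------

#' Initialise a MADSN synthesis state
#'
#' Builds fixed seeded transformer encoders and a cross-modal fuser per
#' modality (forward-only featurisers), pooled linear embedding maps used by
#' the consistency penalty, a 4-layer LeakyReLU generator MLP and a
#' discriminator with a 3-layer shared trunk branching into per-modality
#' heads (averaged into one probability).
#'
#' @param modality_dims named list of modality descriptors:
#'   `eeg = list(channels, samples)`, `image = list(edge)`,
#'   `embedding = list(dim)`, `tabular = list(dim)` (any subset of >= 1).
#' @param n_classes number of condition classes.
#' @param config an [encoder_config()].
#' @param lambda_cons weight of the cross-modal consistency penalty.
#' @param lr Adam learning rate for both players.
#' @param hidden generator hidden width override (discriminator trunk scales
#'   with it); smaller nets concentrate the clipped DP gradient signal on
#'   fewer coordinates, which matters at small privacy budgets.
#' @param seed RNG seed for initialisation.
#' @return object of class `madsn_state`.
#' @export
madsn_init <- function(modality_dims, n_classes = 2,
                       config = encoder_config("desk"), lambda_cons = 0.1,
                       lr = 2e-3, hidden = NULL, seed = 42) {
  stopifnot(length(modality_dims) >= 1, lambda_cons >= 0)
  set.seed(seed)
  kinds <- names(modality_dims)
  toks <- lapply(kinds, function(k) make_tokenizer(k, modality_dims[[k]]))
  names(toks) <- kinds
  encoders <- lapply(kinds, function(k)
    make_encoder(toks[[k]]$token_dim, toks[[k]]$n_tokens, config,
                 toks[[k]]$positional))
  names(encoders) <- kinds
  d <- config$d_model
  rw <- function(a, b, sc = sqrt(1 / a)) matrix(stats::rnorm(a * b, sd = sc), a, b)
  fuser <- list(Wq = rw(d, d), Wk = rw(d, d), Wv = rw(d, d),
                W_proj = rw(length(kinds) * d, config$d_latent),
                b_proj = numeric(config$d_latent),
                n_modalities = length(kinds))

  # flat dimensionality of each modality and pooled linear embedding maps
  flat_dim <- vapply(kinds, function(k) {
    as.integer(switch(k,
           eeg = modality_dims$eeg$channels * modality_dims$eeg$samples,
           image = modality_dims$image$edge^3,
           embedding = modality_dims$embedding$dim,
           tabular = modality_dims$tabular$dim))
  }, integer(1))
  pool_mats <- lapply(kinds, function(k) {
    tk <- toks[[k]]
    P <- matrix(0, flat_dim[[k]], d)
    # push each token's slice of W_embed back onto the input indices that
    # feed it; the token cut applied to an index vector reveals the mapping
    idx_tok <- tk$cut(seq_len(flat_dim[[k]]))
    for (t0 in seq_len(nrow(idx_tok))) {
      ids <- idx_tok[t0, ]
      keep <- ids >= 1  # embedding padding introduces zeros
      P[ids[keep], ] <- P[ids[keep], ] +
        encoders[[k]]$W_embed[which(keep), , drop = FALSE] / tk$n_tokens
    }
    P
  })
  names(pool_mats) <- kinds

  total_dim <- sum(flat_dim)
  d_noise <- config$d_latent
  g_hidden <- hidden %||% if (config$profile == "paper") 512 else 64
  G <- mlp_init(c(config$d_latent + d_noise + n_classes,
                  g_hidden, g_hidden, g_hidden, total_dim),
                act = "lrelu")
  d_h <- if (config$profile == "paper") 512 else g_hidden
  D <- mlp_init(c(total_dim + n_classes, d_h, max(8, d_h %/% 2),
                  max(8, d_h %/% 4), length(kinds)),
                act = "lrelu")
  structure(list(config = config, modality_dims = modality_dims,
                 kinds = kinds, tokenizers = toks, encoders = encoders,
                 fuser = fuser, pool_mats = pool_mats, flat_dim = flat_dim,
                 n_classes = n_classes, d_noise = d_noise,
                 lambda_cons = lambda_cons, lr = lr,
                 G = G, D = D, z_stats = NULL, step = 0L, seed = seed),
            class = "madsn_state")
}

# encode + fuse one subject's flattened modality vectors into z
madsn_latent <- function(state, x_list) {
  h <- lapply(state$kinds, function(k)
    encode_modality(state$tokenizers[[k]]$cut(x_list[[k]]),
                    state$encoders[[k]]))
  names(h) <- state$kinds
  if (length(h) == 1)
    suppressMessages(cross_modal_fuse(h, state$fuser))
  else cross_modal_fuse(h, state$fuser)
}

# latent matrix for n subjects given per-modality matrices (rows = subjects)
madsn_latent_matrix <- function(state, X) {
  n <- nrow(X[[1]])
  t(vapply(seq_len(n), function(i)
    madsn_latent(state, lapply(X[state$kinds], function(m) m[i, ])),
    numeric(state$config$d_latent)))
}

split_modalities <- function(state, xflat) {
  ends <- cumsum(state$flat_dim)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- lapply(seq_along(state$kinds), function(i)
    xflat[, starts[i]:ends[i], drop = FALSE])
  names(out) <- state$kinds
  out
}

d_prob <- function(state, xflat, cond_onehot, return_cache = FALSE) {
  fw <- mlp_forward(state$D, cbind(xflat, cond_onehot))
  u <- rowMeans(fw$out)
  p <- 1 / (1 + exp(-u))
  if (return_cache) list(p = p, cache = fw$cache, u = u) else p
}

#' Generate synthetic modality tensors from latent inputs
#'
#' Deterministic given `(z, eta, c)` and the generator parameters (dropout is
#' a training-time mechanism only).
#'
#' @param state a trained or initialised `madsn_state`.
#' @param z latent matrix (rows = samples, `d_latent` columns).
#' @param eta noise matrix (same rows, `d_noise` columns).
#' @param cond integer class conditions in `1..n_classes`.
#' @return named list of per-modality matrices (rows = samples).
#' @export
madsn_generate <- function(state, z, eta, cond) {
  z <- matrix(z, ncol = state$config$d_latent)
  eta <- matrix(eta, ncol = state$d_noise)
  if (any(cond < 1 | cond > state$n_classes | cond != round(cond)))
    stop("madsn_generate: unknown condition class")
  C <- diag(state$n_classes)[cond, , drop = FALSE]
  out <- mlp_forward(state$G, cbind(z, eta, C))$out
  split_modalities(state, out)
}

# gradient of the consistency penalty w.r.t. the flat generated sample
cons_grad_flat <- function(state, xg_list) {
  pooled <- lapply(state$kinds, function(k)
    as.vector(xg_list[[k]] %*% state$pool_mats[[k]]))
  M <- length(pooled)
  l <- consistency_loss(pooled)
  grads <- lapply(seq_len(M), function(i) {
    gh <- Reduce(`+`, lapply(setdiff(seq_len(M), i), function(j)
      4 * (pooled[[i]] - pooled[[j]])))
    state$pool_mats[[i]] %*% gh
  })
  list(loss = l, grad = do.call(c, grads))
}

#' Train MADSN with a differentially private discriminator
#'
#' Alternates discriminator and generator Adam steps. Every discriminator
#' update uses per-sample gradient clipping plus Gaussian noise
#' (noise-on-sum, then averaged) and is logged in the privacy ledger; the
#' run stops early when the next step would exceed the epsilon budget.
#' Latent codes are the fused encoder outputs of the paired real samples
#' (batch-standardised; the standardisation moments are stored so that pure
#' sampling can draw z ~ N(0, I)).
#'
#' @param X named list of per-modality matrices (rows = subjects), in the
#'   order of `state$kinds`.
#' @param labels integer class labels in `1..n_classes`.
#' @param state a [madsn_init()] result.
#' @param dp a [dp_config()]; `noise_multiplier = 0` with infinite
#'   `clip_norm` reduces the update to standard (non-private) SGD.
#' @param epochs training epochs; @param batch_size mini-batch size.
#' @param seed RNG seed for batching/noise.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @return list with `state`, `ledger`, `history` (per-epoch `loss_d`,
#'   `loss_g`, `loss_cons`, `d_accuracy`, `epsilon`).
#' @export
train_madsn <- function(X, labels, state, dp = dp_config(), epochs = 20,
                        batch_size = 32, seed = 42, optimizer = "adam") {
  n <- nrow(X[[1]])
  stopifnot(length(labels) == n, all(labels %in% seq_len(state$n_classes)))
  set.seed(seed)
  q <- min(1, batch_size / n)
  steps_per_epoch <- max(1, floor(n / batch_size))
  # budget feasibility: one epoch of steps must fit
  probe <- ledger_compose(privacy_ledger(dp_config(
    clip_norm = dp$clip_norm, noise_multiplier = max(dp$noise_multiplier, 1e-12),
    sampling_rate = q, delta = dp$delta, epsilon_budget = dp$epsilon_budget)),
    steps = steps_per_epoch)
  if (dp$noise_multiplier > 0 && probe$epsilon > dp$epsilon_budget)
    stop("train_madsn: privacy budget exhausted before one epoch; ",
         "increase noise_multiplier or epsilon_budget")
  ledger <- privacy_ledger(dp_config(
    clip_norm = dp$clip_norm, noise_multiplier = max(dp$noise_multiplier, 1e-12),
    sampling_rate = q, delta = dp$delta, epsilon_budget = dp$epsilon_budget))

  Z <- madsn_latent_matrix(state, X)
  z_mu <- colMeans(Z)
  z_sd <- pmax(apply(Z, 2, stats::sd), 1e-8)
  Z <- sweep(sweep(Z, 2, z_mu), 2, z_sd, "/")
  state$z_stats <- list(mu = z_mu, sd = z_sd)
  Xflat <- do.call(cbind, X[state$kinds])
  Conehot <- diag(state$n_classes)[labels, , drop = FALSE]

  optG <- adam_init(state$G); optD <- adam_init(state$D)
  tG <- 0L; tD <- 0L
  hist <- data.frame(epoch = integer(), loss_d = numeric(),
                     loss_g = numeric(), loss_cons = numeric(),
                     d_accuracy = numeric(), epsilon = numeric())
  M <- length(state$kinds)
  stopped <- FALSE
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ld <- lg <- lc <- acc <- 0
    nb <- 0
    for (s in seq_len(steps_per_epoch)) {
      idx <- ord[((s - 1) * batch_size + 1):min(s * batch_size, n)]
      B <- length(idx)
      zb <- Z[idx, , drop = FALSE]
      cb <- Conehot[idx, , drop = FALSE]
      xr <- Xflat[idx, , drop = FALSE]

      # privacy feasibility of this D step
      if (dp$noise_multiplier > 0) {
        trial <- ledger_compose(ledger, 1)
        if (trial$epsilon > dp$epsilon_budget) { stopped <- TRUE; break }
        ledger <- trial
      } else ledger$steps <- ledger$steps + 1L

      eta <- matrix(stats::rnorm(B * state$d_noise), B)
      xg <- mlp_forward(state$G, cbind(zb, eta, cb),
                        dropout = state$config$dropout_gen,
                        training = TRUE)$out

      # --- discriminator step (DP) ---
      fr <- mlp_forward(state$D, cbind(xr, cb))
      ff <- mlp_forward(state$D, cbind(xg, cb))
      pr <- 1 / (1 + exp(-rowMeans(fr$out)))
      pf <- 1 / (1 + exp(-rowMeans(ff$out)))
      dUr <- matrix((pr - 1) / M, B, M)
      dUf <- matrix(pf / M, B, M)
      br <- mlp_backward(state$D, fr$cache, dUr)
      bf <- mlp_backward(state$D, ff$cache, dUf)
      gD <- dp_pair_grads(br$per_layer, bf$per_layer,
                          dp$clip_norm, dp$noise_multiplier)
      if (optimizer == "adam") {
        tD <- tD + 1L
        st <- adam_step(state$D, optD, gD, state$lr, tD)
        state$D <- st$net; optD <- st$opt
      } else state$D <- sgd_step(state$D, gD, state$lr)

      # --- generator step (non-private) ---
      eta2 <- matrix(stats::rnorm(B * state$d_noise), B)
      gf <- mlp_forward(state$G, cbind(zb, eta2, cb),
                        dropout = state$config$dropout_gen, training = TRUE)
      fd <- mlp_forward(state$D, cbind(gf$out, cb))
      pfd <- 1 / (1 + exp(-rowMeans(fd$out)))
      dU <- matrix((pfd - 1) / M, B, M)
      bD <- mlp_backward(state$D, fd$cache, dU)
      dXg <- bD$dX[, seq_len(sum(state$flat_dim)), drop = FALSE]
      cons <- 0
      if (state$lambda_cons > 0) {
        # training uses the per-pair, per-dimension mean so the penalty is
        # O(1) against the adversarial term regardless of latent width
        xg_list <- split_modalities(state, gf$out)
        nf <- 1 / (M * max(1, M - 1) * state$config$d_model)
        for (i in seq_len(B)) {
          cg <- cons_grad_flat(state, lapply(xg_list, function(m)
            m[i, , drop = FALSE]))
          cons <- cons + nf * cg$loss / B
          dXg[i, ] <- dXg[i, ] + state$lambda_cons * nf * cg$grad / B
        }
      }
      bG <- mlp_backward(state$G, gf$cache, dXg)
      gG <- lapply(bG$grads, function(g) list(W = g$W / B, b = g$b / B))
      if (optimizer == "adam") {
        tG <- tG + 1L
        st <- adam_step(state$G, optG, gG, state$lr, tG)
        state$G <- st$net; optG <- st$opt
      } else state$G <- sgd_step(state$G, gG, state$lr)

      ld <- ld + loss_discriminator(pr, pf)
      lg <- lg + loss_generator(pfd, cons, state$lambda_cons)
      lc <- lc + cons
      acc <- acc + (mean(pr > 0.5) + mean(pf < 0.5)) / 2
      nb <- nb + 1
    }
    if (nb > 0)
      hist <- rbind(hist, data.frame(
        epoch = ep, loss_d = ld / nb, loss_g = lg / nb, loss_cons = lc / nb,
        d_accuracy = acc / nb,
        epsilon = if (dp$noise_multiplier > 0) ledger$epsilon else NA_real_))
    if (stopped) break
  }
  state$step <- state$step + ledger$steps
  list(state = state, ledger = ledger, history = hist)
}

# DP-SGD gradients when each per-sample gradient is the sum of two backward
# passes (real + generated pair): per-layer norms use
# ||outer(ar,dr)+outer(af,df)||^2 = |ar|^2|dr|^2 + |af|^2|df|^2
#                                   + 2 (ar.af)(dr.df)
dp_pair_grads <- function(plr, plf, clip_norm, noise_multiplier) {
  n <- nrow(plr[[1]]$delta)
  s2 <- numeric(n)
  for (l in seq_along(plr)) {
    ar <- plr[[l]]$act; dr <- plr[[l]]$delta
    af <- plf[[l]]$act; df <- plf[[l]]$delta
    s2 <- s2 + rowSums(dr^2) * rowSums(ar^2) + rowSums(df^2) * rowSums(af^2) +
      2 * rowSums(ar * af) * rowSums(dr * df) +
      rowSums((dr + df)^2)  # bias block
  }
  scale <- 1 / pmax(1, sqrt(s2) / clip_norm)
  B <- length(scale)
  lapply(seq_along(plr), function(l) {
    Dr <- plr[[l]]$delta * scale; Df <- plf[[l]]$delta * scale
    W <- crossprod(plr[[l]]$act, Dr) + crossprod(plf[[l]]$act, Df)
    b <- colSums(Dr) + colSums(Df)
    if (noise_multiplier > 0) {
      W <- W + matrix(stats::rnorm(length(W),
                                   sd = noise_multiplier * clip_norm), nrow(W))
      b <- b + stats::rnorm(length(b), sd = noise_multiplier * clip_norm)
    }
    list(W = W / B, b = b / B)
  })
}

# greedy matching-pursuit decoding of an embedding into a token multiset
decode_tokens <- function(embedding, codebook, len) {
  v <- nrow(codebook)
  chosen <- integer(0)
  run <- numeric(ncol(codebook))
  for (k in seq_len(len)) {
    cand_mean <- sweep(codebook, 2, run * (k - 1), "+") / k
    d2 <- rowSums(sweep(cand_mean, 2, embedding)^2)
    j <- which.min(d2)
    chosen <- c(chosen, j - 1L)
    run <- (run * (k - 1) + codebook[j, ]) / k
  }
  chosen
}

#' Sample a synthetic cohort from a trained MADSN state
#'
#' Latents are drawn z ~ N(0, I) in the standardised latent space; generated
#' tabular blocks are inverse-transformed through the preprocessing state to
#' phenotype scale, categorical blocks are decoded by argmax, and behavioural
#' embeddings are decoded to token sequences by greedy nearest-codebook
#' matching pursuit. The result is a regular `cohort` that round-trips
#' through [write_cohort()] / [read_cohort()].
#'
#' @param state a trained `madsn_state` (with stored latent moments).
#' @param n number of synthetic subjects.
#' @param condition_mix class proportions (length `n_classes`, sums to 1).
#' @param preprocess the [fit_preprocess()] state used on the training data.
#' @param template_config the real cohort's [cohort_config()] (shapes).
#' @param seed RNG seed.
#' @return a `cohort` whose provenance records the generator seed and a
#'   `synthetic = TRUE` flag.
#' @export
madsn_synthesize <- function(state, n, condition_mix = NULL, preprocess,
                             template_config, seed = 42) {
  if (is.null(state$z_stats))
    stop("madsn_synthesize: state has not been trained")
  set.seed(seed)
  k <- state$n_classes
  if (is.null(condition_mix)) condition_mix <- rep(1 / k, k)
  stopifnot(length(condition_mix) == k, abs(sum(condition_mix) - 1) < 1e-8)
  counts <- largest_remainder(n, condition_mix)
  cond <- sample(rep(seq_len(k), times = counts))
  z <- matrix(stats::rnorm(n * state$config$d_latent), n)
  eta <- matrix(stats::rnorm(n * state$d_noise), n)
  Xg <- madsn_generate(state, z, eta, cond)

  cfg <- template_config
  cfg$n_subjects <- as.integer(n)
  codebook <- behavior_codebook(cfg$vocab_size, cfg$embed_dim)
  num_cols <- names(preprocess$feature_means)
  cat_cols <- names(preprocess$category_vocab)
  n_samp <- round(cfg$eeg_sfreq * cfg$eeg_epoch_sec)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    tabrow <- Xg$tabular[i, ]
    num <- tabrow[seq_along(num_cols)]
    vals <- preprocess$feature_means + num * preprocess$feature_sds
    off <- length(num_cols)
    demo <- list()
    for (cl in cat_cols) {
      vc <- preprocess$category_vocab[[cl]]
      block <- tabrow[off + seq_along(vc)]
      demo[[cl]] <- vc[which.max(block)]
      off <- off + length(vc)
    }
    emb <- Xg$embedding[i, ]
    toks <- decode_tokens(emb, codebook, TOKEN_LEN)
    sev <- pmax(0, unname(vals[paste0("A", 1:8)]))
    sev_sum <- sum(sev)
    records[[i]] <- list(
      subject_id = sprintf("G%05d", i),
      image_patch = array(Xg$image[i, ], dim = rep(cfg$image_patch_edge, 3)),
      eeg = matrix(Xg$eeg[i, ], cfg$eeg_channels, n_samp),
      behavior_tokens = toks, behavior_embedding = emb,
      demographics = list(age = max(4, unname(vals["age"])), sex = demo$sex,
                          site = demo$site,
                          relationship = demo$relationship),
      severity_items = sev, label = cond[i] - 1L,
      severity_class = if (sev_sum < 11) "mild" else if (sev_sum < 13.5)
        "moderate" else "severe")
  }
  structure(list(records = records, config = cfg,
                 provenance = list(seed = seed,
                                   generator = GENERATOR_VERSION,
                                   synthetic = TRUE)),
            class = "cohort")
}
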