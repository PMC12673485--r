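# ---- adaptive mixture-of-experts ensemble ----------------------------------

#' Gating configuration
#'
#' @param hidden gating MLP hidden width.
#' @param entropy_weight entropy regularisation weight lambda (>= 0); the
#'   entropy of the gating distribution is rewarded to prevent collapse onto
#'   a single expert.
#' @param dropout gating hidden-unit dropout (training only).
#' @param l2 per-expert L2 weight decay lambda_k (scalar or length-5).
#' @param gating_input `"logits"` (concatenated expert logits, default) or
#'   `"raw"` (the tabular features).
#' @param gate_lr_factor multiplier on the gating network's learning rate
#'   relative to the experts'.
#' @param gate_l2 weight decay on the gating MLP; bounded gating scores keep
#'   the softmax away from its saturated (vanishing-gradient) region so the
#'   gate can still re-allocate weight late in training.
#' @param aux_weight weight of the auxiliary per-expert cross-entropy term
#'   that trains every expert directly on the labels (the standard
#'   mixture-of-experts remedy against rich-get-richer collapse: an expert
#'   whose gate weight hits zero would otherwise stop learning).
#' @export
gating_config <- function(hidden = 128, entropy_weight = 0.01, dropout = 0.5,
                          l2 = 1e-4, gating_input = c("logits", "raw"),
                          aux_weight = 1, gate_lr_factor = 1,
                          gate_l2 = 5e-3) {
  if (entropy_weight < 0) stop("gating_config: 'entropy_weight' must be >= 0")
  if (any(l2 < 0)) stop("gating_config: 'l2' must be >= 0")
  structure(list(hidden = hidden, entropy_weight = entropy_weight,
                 dropout = dropout, l2 = l2,
                 gating_input = match.arg(gating_input),
                 aux_weight = aux_weight,
                 gate_lr_factor = gate_lr_factor, gate_l2 = gate_l2),
            class = "gating_config")
}

#' Shannon entropy of a gating weight vector
#'
#' `H = -sum alpha_k log alpha_k` with `0 log 0 := 0`; maximal (log K) iff
#' uniform.
#'
#' @param alpha probability vector.
#' @export
gating_entropy <- function(alpha) {
  a <- alpha[alpha > 0]
  -sum(a * log(a))
}

#' Masked softmax gating weights
#'
#' Softmax over available experts only (masked logits at -Inf); weights of
#' masked experts are exactly zero and the rest sum to 1.
#'
#' @param scores matrix (n x K) or vector of gating scores.
#' @param mask logical availability vector/matrix (TRUE = available).
#' @return matrix/vector of gating weights on the simplex.
#' @export
gating_weights <- function(scores, mask = NULL) {
  v <- is.null(dim(scores))
  S <- if (v) matrix(scores, 1) else as.matrix(scores)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(S), ncol(S))
  M <- if (is.null(dim(mask))) matrix(mask, nrow(S), length(mask),
                                      byrow = TRUE) else mask
  if (any(rowSums(M) == 0)) stop("gating_weights: all experts masked")
  S[!M] <- -Inf
  A <- softmax_rows(S)
  A[!M] <- 0
  if (v) A[1, ] else A
}

#' Combine expert predictions with gating weights
#'
#' Probability-space mixing: `yhat = sum_k alpha_k softmax(y_k)`; the result
#' is a probability vector. Raw-logit mixing (`space = "logit"`) follows the
#' weighted-sum form directly.
#'
#' @param expert_logits list of K matrices (n x n_classes) of expert logits.
#' @param alpha gating weight matrix (n x K).
#' @param space `"prob"` (default) or `"logit"`.
#' @export
ensemble_predict <- function(expert_logits, alpha, space = c("prob", "logit")) {
  space <- match.arg(space)
  alpha <- if (is.null(dim(alpha)))
    matrix(alpha, 1) else as.matrix(alpha)
  K <- length(expert_logits)
  stopifnot(ncol(alpha) == K)
  parts <- lapply(seq_len(K), function(k) {
    Y <- as.matrix(expert_logits[[k]])
    if (space == "prob") Y <- softmax_rows(Y)
    Y * alpha[, k]
  })
  Reduce(`+`, parts)
}

# ---- experts ----------------------------------------------------------------
#
# Every expert maps its modality input (rows = subjects) to n_classes logits
# and is fully trainable by analytic backprop. Convolutional experts use an
# im2col patch layer (a linear map over extracted patches), ReLU, mean
# pooling over patches and a linear head; the graph expert propagates over a
# fixed kNN adjacency.

expert_conv_init <- function(patch_dim, n_patches, filters, n_classes,
                             pooling = c("relu_mean", "square_log"),
                             Wc = NULL, freeze_filters = FALSE,
                             group_pool = NULL) {
  pooling <- match.arg(pooling)
  if (is.null(Wc))
    Wc <- matrix(stats::rnorm(patch_dim * filters, sd = sqrt(2 / patch_dim)),
                 patch_dim, filters)
  head_in <- if (is.null(group_pool)) ncol(Wc) else ncol(group_pool)
  list(type = "conv", Wc = Wc, bc = numeric(ncol(Wc)),
       head = mlp_init(c(head_in, n_classes), act = "relu"),
       n_patches = n_patches, patch_dim = patch_dim, pooling = pooling,
       freeze_filters = freeze_filters, group_pool = group_pool)
}

# sinusoidal (Gabor) filter bank: one sine and one cosine atom per channel
# and per band centre, so squared pooled responses estimate per-channel band
# energies (the classical EEG band-power frontend)
gabor_filterbank <- function(channels, width, sfreq,
                             freqs = c(3, 6, 10, 14, 20, 24, 30, 35)) {
  tt <- seq_len(width) / sfreq
  W <- matrix(0, channels * width, 2 * channels * length(freqs))
  j <- 0L
  for (ch in seq_len(channels)) for (f in freqs) {
    idx <- seq((ch - 1) * width + 1, ch * width)
    W[idx, j + 1L] <- sin(2 * pi * f * tt)
    W[idx, j + 2L] <- cos(2 * pi * f * tt)
    j <- j + 2L
  }
  W * sqrt(2 / width)
}

# patches: (n * n_patches) x patch_dim matrix, rows grouped by subject.
# pooling "relu_mean": ReLU then mean over patches (generic features);
# "square_log": square then mean then log -- the band-power detector used by
# shallow EEG convolutional nets, which makes a temporal filter's output an
# energy estimate.
conv_forward <- function(ex, patches, n) {
  Z <- sweep(patches %*% ex$Wc, 2, ex$bc, "+")
  A <- if (ex$pooling == "square_log") Z^2 else pmax(Z, 0)
  idx <- rep(seq_len(n), each = ex$n_patches)
  G <- rowsum(A, idx) / ex$n_patches
  if (!is.null(ex$group_pool)) G <- G %*% ex$group_pool
  Fm <- if (ex$pooling == "square_log") log(G + 1e-6) else G
  hf <- mlp_forward(ex$head, Fm)
  list(logits = hf$out, cache = list(Z = Z, G = G, Fm = Fm, hf = hf$cache,
                                     patches = patches))
}

conv_backward <- function(ex, cache, dLogits, n) {
  hb <- mlp_backward(ex$head, cache$hf, dLogits)
  dF <- hb$dX
  dG <- if (ex$pooling == "square_log") dF / (cache$G + 1e-6) else dF
  if (!is.null(ex$group_pool)) dG <- dG %*% t(ex$group_pool)
  dA <- dG[rep(seq_len(n), each = ex$n_patches), , drop = FALSE] /
    ex$n_patches
  dZ <- if (ex$pooling == "square_log") dA * 2 * cache$Z
        else dA * (cache$Z > 0)
  list(Wc = crossprod(cache$patches, dZ), bc = colSums(dZ),
       head = hb$grads)
}

im2col_image <- function(X, edge, block = 2L) {
  nb <- edge %/% block
  n <- nrow(X)
  out <- matrix(0, n * nb^3, block^3)
  r <- 1L
  for (i in seq_len(n)) {
    a <- array(X[i, ], dim = c(edge, edge, edge))
    for (z in seq_len(nb)) for (y in seq_len(nb)) for (x in seq_len(nb)) {
      out[r, ] <- a[(x - 1) * block + 1:2, (y - 1) * block + 1:2,
                    (z - 1) * block + 1:2]
      r <- r + 1L
    }
  }
  out
}

im2col_eeg <- function(X, channels, samples, width = 25L) {
  nw <- samples %/% width
  n <- nrow(X)
  out <- matrix(0, n * nw, channels * width)
  r <- 1L
  for (i in seq_len(n)) {
    m <- matrix(X[i, ], channels, samples)
    for (w in seq_len(nw)) {
      # channel-block layout: all samples of channel 1, then channel 2, ...
      out[r, ] <- as.vector(t(m[, (w - 1) * width + seq_len(width)]))
      r <- r + 1L
    }
  }
  out
}

knn_adjacency <- function(feats, ref = feats, k = 5) {
  # cosine kNN of rows of feats against rows of ref; row-normalised with
  # self-loop, mean aggregation
  nf <- feats / pmax(sqrt(rowSums(feats^2)), 1e-12)
  nr <- ref / pmax(sqrt(rowSums(ref^2)), 1e-12)
  S <- nf %*% t(nr)
  n <- nrow(feats)
  A <- matrix(0, n, nrow(ref))
  for (i in seq_len(n)) {
    ord <- order(S[i, ], decreasing = TRUE)
    ord <- setdiff(ord, if (identical(feats, ref)) i else integer(0))
    A[i, ord[seq_len(min(k, length(ord)))]] <- 1
  }
  A / pmax(rowSums(A), 1)
}

#' Initialise the five-expert adaptive ensemble
#'
#' Experts: a 3D-convolutional image expert (2x2x2 blocks), a
#' 1D-convolutional EEG expert (full-height temporal windows), a tabular MLP,
#' a fusion MLP over the fixed cross-modal latent, and a 2-layer
#' mean-aggregation graph network over a cosine kNN subject graph (k = 5) on
#' the tabular features. Gating is a 2-layer MLP (hidden `config$hidden`,
#' ReLU, dropout) over concatenated expert logits with masked softmax output.
#'
#' @param dims list with `image_edge`, `eeg_channels`, `eeg_samples`,
#'   `eeg_sfreq`, `tabular`, `latent` input descriptors.
#' @param n_classes number of outcome classes.
#' @param config a [gating_config()].
#' @param seed RNG seed.
#' @export
amel_init <- function(dims, n_classes = 2, config = gating_config(),
                      seed = 42) {
  set.seed(seed)
  nb <- (dims$image_edge %/% 2L)^3
  nw <- dims$eeg_samples %/% 25L
  eeg_w <- min(25L, dims$eeg_samples)
  n_bands <- 8L
  gp <- matrix(0, 2L * dims$eeg_channels * n_bands, n_bands)
  col <- 0L
  for (ch in seq_len(dims$eeg_channels)) for (f in seq_len(n_bands)) {
    gp[col + 1L, f] <- 1; gp[col + 2L, f] <- 1
    col <- col + 2L
  }
  experts <- list(
    image = expert_conv_init(8L, nb, 8L, n_classes),
    eeg = expert_conv_init(dims$eeg_channels * eeg_w, nw, NULL, n_classes,
                           pooling = "square_log",
                           Wc = gabor_filterbank(dims$eeg_channels, eeg_w,
                                                 dims$eeg_sfreq %||% 250),
                           freeze_filters = TRUE, group_pool = gp),
    tabular = list(type = "mlp",
                   net = mlp_init(c(dims$tabular, 8, n_classes), "relu")),
    fusion = list(type = "mlp",
                  net = mlp_init(c(dims$latent, 8, n_classes), "relu")),
    graph = list(type = "graph",
                 W1 = matrix(stats::rnorm(dims$tabular * 8,
                                          sd = sqrt(2 / dims$tabular)),
                             dims$tabular, 8),
                 b1 = numeric(8),
                 W2 = matrix(stats::rnorm(8 * n_classes, sd = sqrt(2 / 8)),
                             8, n_classes),
                 b2 = numeric(n_classes)))
  gate_in <- if (config$gating_input == "logits") 5L * n_classes
             else dims$tabular
  structure(list(experts = experts, config = config, dims = dims,
                 n_classes = n_classes,
                 gate = mlp_init(c(gate_in, config$hidden, 5L), "relu"),
                 train_feats = NULL, seed = seed),
            class = "amel_model")
}

expert_names <- function() c("image", "eeg", "tabular", "fusion", "graph")

# patch extraction for the convolutional experts; reusable across epochs
amel_precompute <- function(model, inputs) {
  d <- model$dims
  list(pat_img = im2col_image(inputs$image, d$image_edge),
       pat_eeg = im2col_eeg(inputs$eeg, d$eeg_channels, d$eeg_samples))
}

# forward all experts; inputs: list(image, eeg, tabular, latent) matrices
amel_experts_forward <- function(model, inputs, adj = NULL, pre = NULL) {
  n <- nrow(inputs$tabular)
  d <- model$dims
  if (is.null(pre)) pre <- amel_precompute(model, inputs)
  pat_img <- pre$pat_img
  pat_eeg <- pre$pat_eeg
  fi <- conv_forward(model$experts$image, pat_img, n)
  fe <- conv_forward(model$experts$eeg, pat_eeg, n)
  ft <- mlp_forward(model$experts$tabular$net, inputs$tabular)
  ff <- mlp_forward(model$experts$fusion$net, inputs$latent)
  if (is.null(adj)) adj <- knn_adjacency(inputs$tabular)
  gx <- model$experts$graph
  H1z <- adj %*% inputs$tabular %*% gx$W1
  H1z <- sweep(H1z, 2, gx$b1, "+")
  H1 <- pmax(H1z, 0)
  AH1 <- adj %*% H1
  glog <- sweep(AH1 %*% gx$W2, 2, gx$b2, "+")
  list(logits = list(image = fi$logits, eeg = fe$logits, tabular = ft$out,
                     fusion = ff$out, graph = glog),
       caches = list(image = fi$cache, eeg = fe$cache, tabular = ft$cache,
                     fusion = ff$cache,
                     graph = list(H1z = H1z, H1 = H1, AH1 = AH1, adj = adj,
                                  X = inputs$tabular)))
}

# full forward: experts -> gating -> mixture; mask: n x 5 logical
amel_forward <- function(model, inputs, mask = NULL, training = FALSE,
                         adj = NULL, pre = NULL) {
  ef <- amel_experts_forward(model, inputs, adj, pre)
  n <- nrow(inputs$tabular)
  K <- 5L
  if (is.null(mask)) mask <- matrix(TRUE, n, K)
  logit_cat <- do.call(cbind, ef$logits[expert_names()])
  gate_in <- if (model$config$gating_input == "logits") logit_cat
             else inputs$tabular
  gf <- mlp_forward(model$gate, gate_in,
                    dropout = model$config$dropout, training = training)
  alpha <- gating_weights(gf$out, mask)
  probs_k <- lapply(ef$logits[expert_names()], softmax_rows)
  yhat <- Reduce(`+`, lapply(seq_len(K), function(k)
    probs_k[[k]] * alpha[, k]))
  list(yhat = yhat, alpha = alpha, expert_logits = ef$logits,
       probs_k = probs_k, caches = ef$caches, gate_cache = gf$cache,
       gate_in = gate_in, mask = mask, scores = gf$out)
}

# cross-entropy + L2 - lambda * mean entropy; returns loss and all gradients
amel_loss_grads <- function(model, fw, labels) {
  n <- length(labels)
  K <- 5L
  nc <- model$n_classes
  Y <- diag(nc)[labels + 1L, , drop = FALSE]
  lam <- model$config$entropy_weight
  p <- pmax(fw$yhat, 1e-12)
  ce <- -mean(rowSums(Y * log(p)))
  Hbar <- mean(apply(fw$alpha, 1, gating_entropy))
  l2s <- model$config$l2
  if (length(l2s) == 1) l2s <- rep(l2s, K)
  l2pen <- 0
  for (k in seq_len(K)) {
    ex <- model$experts[[expert_names()[k]]]
    w2 <- switch(ex$type,
      conv = sum(ex$Wc^2) + sum(vapply(ex$head$layers,
                                       function(l) sum(l$W^2), 0)),
      mlp = sum(vapply(ex$net$layers, function(l) sum(l$W^2), 0)),
      graph = sum(ex$W1^2) + sum(ex$W2^2))
    l2pen <- l2pen + l2s[k] * w2
  }
  aux_w <- model$config$aux_weight %||% 0
  aux_ce <- 0
  if (aux_w > 0) {
    # summed (not averaged) over experts: each expert receives the full
    # auxiliary cross-entropy gradient regardless of the ensemble size
    aux_ce <- sum(vapply(seq_len(K), function(k)
      -mean(rowSums(Y * log(pmax(fw$probs_k[[k]], 1e-12)))), numeric(1)))
  }
  loss <- ce + l2pen - lam * Hbar + aux_w * aux_ce

  dY <- -(Y / p) / n                       # dCE/dyhat
  dAlpha <- matrix(0, n, K)
  dLogits <- vector("list", K)
  for (k in seq_len(K)) {
    dAlpha[, k] <- rowSums(dY * fw$probs_k[[k]])
    dPk <- dY * fw$alpha[, k]
    # softmax backward on expert k's logits
    pk <- fw$probs_k[[k]]
    dLogits[[k]] <- pk * (dPk - rowSums(dPk * pk))
    if (aux_w > 0)
      dLogits[[k]] <- dLogits[[k]] + aux_w * (pk - Y) / n
  }
  # entropy term: d(-lam * Hbar)/dalpha = lam/n * (log alpha + 1)
  a_safe <- pmax(fw$alpha, 1e-12)
  dAlpha <- dAlpha + lam / n * (log(a_safe) + 1) * (fw$alpha > 0)
  # masked-softmax backward: dscore = alpha * (dalpha - sum(dalpha * alpha))
  dScore <- fw$alpha * (dAlpha - rowSums(dAlpha * fw$alpha))
  gb <- mlp_backward(model$gate, fw$gate_cache, dScore)
  gate_grads <- gb$grads
  if (model$config$gating_input == "logits") {
    dIn <- gb$dX
    for (k in seq_len(K)) {
      cols <- ((k - 1) * nc + 1):(k * nc)
      dLogits[[k]] <- dLogits[[k]] + dIn[, cols, drop = FALSE]
    }
  }
  list(loss = loss, ce = ce, entropy = Hbar, dLogits = dLogits,
       gate_grads = gate_grads, l2s = l2s)
}

# generic Adam update for an arbitrary named list of arrays
adam_list_step <- function(params, grads, st, lr, t, b1 = 0.9, b2 = 0.999,
                           eps = 1e-8) {
  if (is.null(st)) st <- lapply(grads, function(g) list(m = g * 0, v = g * 0))
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st[[nm]]$m <- b1 * st[[nm]]$m + (1 - b1) * g
    st[[nm]]$v <- b2 * st[[nm]]$v + (1 - b2) * g^2
    mh <- st[[nm]]$m / (1 - b1^t); vh <- st[[nm]]$v / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, st = st)
}

net_as_list <- function(net) {
  out <- list()
  for (l in seq_along(net$layers)) {
    out[[paste0("W", l)]] <- net$layers[[l]]$W
    out[[paste0("b", l)]] <- net$layers[[l]]$b
  }
  out
}

net_from_list <- function(net, lst) {
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- lst[[paste0("W", l)]]
    net$layers[[l]]$b <- lst[[paste0("b", l)]]
  }
  net
}

grads_as_list <- function(grads) {
  out <- list()
  for (l in seq_along(grads)) {
    out[[paste0("W", l)]] <- grads[[l]]$W
    out[[paste0("b", l)]] <- grads[[l]]$b
  }
  out
}

amel_apply_grads <- function(model, fw, lg, labels, lr, opts, t,
                             update_gate = TRUE) {
  n <- length(labels)
  K <- 5L
  nms <- expert_names()
  for (k in seq_len(K)) {
    nm <- nms[k]
    ex <- model$experts[[nm]]
    dl <- lg$dLogits[[k]]
    l2 <- lg$l2s[k]
    if (ex$type == "conv") {
      g <- conv_backward(ex, fw$caches[[nm]], dl, n)
      pl <- net_as_list(ex$head)
      gl <- grads_as_list(g$head)
      gl$W1 <- gl$W1 + 2 * l2 * pl$W1
      if (!isTRUE(ex$freeze_filters)) {
        pl <- c(list(Wc = ex$Wc, bc = ex$bc), pl)
        gl <- c(list(Wc = g$Wc + 2 * l2 * ex$Wc, bc = g$bc), gl)
      }
      up <- adam_list_step(pl, gl, opts[[nm]], lr, t)
      if (!isTRUE(ex$freeze_filters)) {
        ex$Wc <- up$params$Wc; ex$bc <- up$params$bc
      }
      ex$head <- net_from_list(ex$head, up$params)
    } else if (ex$type == "mlp") {
      g <- mlp_backward(ex$net, fw$caches[[nm]], dl)$grads
      gl <- grads_as_list(g)
      pl <- net_as_list(ex$net)
      for (l in seq_along(ex$net$layers))
        gl[[paste0("W", l)]] <- gl[[paste0("W", l)]] +
          2 * l2 * pl[[paste0("W", l)]]
      up <- adam_list_step(pl, gl, opts[[nm]], lr, t)
      ex$net <- net_from_list(ex$net, up$params)
    } else {  # graph
      cg <- fw$caches$graph
      dAH1 <- dl %*% t(ex$W2)
      gW2 <- crossprod(cg$AH1, dl) + 2 * l2 * ex$W2
      gb2 <- colSums(dl)
      dH1 <- t(cg$adj) %*% dAH1
      dZ <- dH1 * (cg$H1z > 0)
      AX <- cg$adj %*% cg$X
      gW1 <- crossprod(AX, dZ) + 2 * l2 * ex$W1
      gb1 <- colSums(dZ)
      up <- adam_list_step(list(W1 = ex$W1, b1 = ex$b1, W2 = ex$W2,
                                b2 = ex$b2),
                           list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
                           opts[[nm]], lr, t)
      ex$W1 <- up$params$W1; ex$b1 <- up$params$b1
      ex$W2 <- up$params$W2; ex$b2 <- up$params$b2
    }
    opts[[nm]] <- up$st
    model$experts[[nm]] <- ex
  }
  if (update_gate) {
    up <- adam_list_step(net_as_list(model$gate),
                         grads_as_list(lg$gate_grads), opts$gate,
                         lr * (model$config$gate_lr_factor %||% 1), t)
    model$gate <- net_from_list(model$gate, up$params)
    opts$gate <- up$st
  }
  list(model = model, opts = opts)
}

#' Train the adaptive ensemble
#'
#' Full-batch Adam. Each epoch has two phases: the experts minimise the
#' mixture cross-entropy plus the auxiliary per-expert cross-entropy (with
#' L2 decay) on the training fold, and the gating network minimises the
#' ensemble cross-entropy minus `lambda` times the mean gating entropy on
#' the held-out validation labels, so combination weights reflect
#' generalisation rather than training-fold fit. Gradients flow through the
#' gating softmax; early stopping is on validation AUC.
#'
#' @param inputs_train,inputs_val lists with `image`, `eeg`, `tabular`,
#'   `latent` matrices (see [amel_init()] dims).
#' @param labels_train,labels_val binary labels (0/1).
#' @param model an [amel_init()] result.
#' @param epochs maximum epochs; @param lr learning rate.
#' @param patience early-stopping patience in epochs (defaults to `epochs`,
#'   i.e. the best-validation-AUC model is selected over the whole run; set
#'   lower to abort stalled runs early).
#' @param seed RNG seed (gating dropout).
#' @param mask_train optional n x 5 availability mask.
#' @return list with `model` (best validation AUC), `history` (per-epoch
#'   `loss`, `ce`, `entropy`, `val_auc`), `best_epoch`.
#' @export
train_amel <- function(inputs_train, labels_train, inputs_val, labels_val,
                       model, epochs = 250, lr = 0.03, patience = epochs,
                       seed = 42, mask_train = NULL) {
  set.seed(seed)
  model$train_feats <- inputs_train$tabular
  adj_tr <- knn_adjacency(inputs_train$tabular)
  adj_va <- knn_adjacency(inputs_val$tabular)
  pre_tr <- amel_precompute(model, inputs_train)
  pre_va <- amel_precompute(model, inputs_val)
  opts <- list()
  gopt <- NULL
  best <- list(auc = -Inf, model = model, epoch = 0L)
  hist <- data.frame()
  wait <- 0L
  for (ep in seq_len(epochs)) {
    # expert phase: training-fold labels drive expert parameters (the
    # gating gradients of this pass are discarded)
    fw <- amel_forward(model, inputs_train, mask = mask_train,
                       training = TRUE, adj = adj_tr, pre = pre_tr)
    lg <- amel_loss_grads(model, fw, labels_train)
    up <- amel_apply_grads(model, fw, lg, labels_train, lr, opts, ep,
                           update_gate = FALSE)
    model <- up$model; opts <- up$opts
    # gating phase: the combination weights minimise the ensemble
    # cross-entropy on held-out labels, so the gate allocates by
    # generalisation rather than by training-fold fit
    fwv <- amel_forward(model, inputs_val, training = TRUE, adj = adj_va,
                        pre = pre_va)
    lgv <- amel_loss_grads(model, fwv, labels_val)
    ggr <- grads_as_list(lgv$gate_grads)
    gl2 <- model$config$gate_l2 %||% 0
    if (gl2 > 0) {
      gpl <- net_as_list(model$gate)
      for (nm in names(ggr))
        if (startsWith(nm, "W")) ggr[[nm]] <- ggr[[nm]] + 2 * gl2 * gpl[[nm]]
    }
    gup <- adam_list_step(net_as_list(model$gate), ggr, gopt,
                          lr * (model$config$gate_lr_factor %||% 1), ep)
    model$gate <- net_from_list(model$gate, gup$params)
    gopt <- gup$st

    fwe <- amel_forward(model, inputs_val, adj = adj_va, pre = pre_va)
    vauc <- roc_auc(fwe$yhat[, 2], labels_val)
    hist <- rbind(hist, data.frame(epoch = ep, loss = lg$loss, ce = lg$ce,
                                   entropy = lg$entropy, val_auc = vauc))
    if (vauc > best$auc + 1e-6) {
      best <- list(auc = vauc, model = model, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  best$model$train_feats <- inputs_train$tabular
  list(model = best$model, history = hist, best_epoch = best$epoch,
       val_auc = best$auc)
}

#' Predict with optional missing modalities
#'
#' Experts of unavailable modalities are excluded before the gating softmax;
#' the remaining weights renormalise to 1 automatically. With a single
#' available expert the ensemble output equals that expert's probabilities.
#'
#' @param model a trained `amel_model`.
#' @param inputs list with `image`, `eeg`, `tabular`, `latent` matrices.
#' @param available logical length-5 vector or n x 5 matrix (order: image,
#'   eeg, tabular, fusion, graph); `NULL` = all available.
#' @return list with `yhat` (n x n_classes probabilities), `alpha`,
#'   `expert_logits`, `mask`.
#' @export
predict_amel <- function(model, inputs, available = NULL) {
  n <- nrow(inputs$tabular)
  mask <- if (is.null(available)) matrix(TRUE, n, 5)
          else if (is.null(dim(available)))
            matrix(available, n, 5, byrow = TRUE)
          else available
  # graph propagation for new subjects uses neighbours among themselves
  fw <- amel_forward(model, inputs, mask = mask, training = FALSE)
  list(yhat = fw$yhat, alpha = fw$alpha, expert_logits = fw$expert_logits,
       mask = mask)
}

#' Export per-sample gating weights
#'
#' @param model,inputs as in [predict_amel()].
#' @param path optional CSV path; when given the table is written there.
#' @return data.frame of gating weights, one column per expert.
#' @export
gating_report <- function(model, inputs, path = NULL) {
  fw <- predict_amel(model, inputs)
  out <- as.data.frame(fw$alpha)
  names(out) <- expert_names()
  if (!is.null(path)) data.table::fwrite(out, path)
  out
}
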