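# ---- small neural-network engine -------------------------------------------
#
# Plain-matrix multilayer perceptrons with analytic backpropagation and Adam.
# Shapes: inputs are n x d matrices (rows = samples). A net is a list of
# layers, each with weight W (d_in x d_out) and bias b (length d_out), an
# activation per hidden layer and a linear output layer. Caches from the
# forward pass carry the per-layer inputs and pre-activations needed for the
# backward pass; the backward pass additionally exposes per-layer delta and
# activation matrices so DP-SGD can compute per-sample gradient norms without
# materialising per-sample gradients.

act_fun <- function(x, act, leak = 0.2) {
  switch(act,
    linear = x,
    relu = pmax(x, 0),
    lrelu = ifelse(x > 0, x, leak * x),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)),
    stop("unknown activation: ", act)
  )
}

act_grad <- function(x, act, leak = 0.2) {
  switch(act,
    linear = array(1, dim = dim(x)),
    relu = (x > 0) * 1,
    lrelu = ifelse(x > 0, 1, leak),
    tanh = 1 - tanh(x)^2,
    sigmoid = { s <- 1 / (1 + exp(-x)); s * (1 - s) },
    stop("unknown activation: ", act)
  )
}

#' Initialise a multilayer perceptron
#'
#' He-style initialisation, biases at zero. The final layer is linear; all
#' hidden layers use `act`.
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param act hidden activation: one of `"relu"`, `"lrelu"`, `"tanh"`.
#' @param out_scale multiplier on the output layer's initial weights; small
#'   values keep an untrained generator's output near zero.
#' @return an object of class `mmsynth_mlp`.
#' @keywords internal
mlp_init <- function(sizes, act = "lrelu", out_scale = 1) {
  stopifnot(length(sizes) >= 2)
  L <- length(sizes) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    sc <- sqrt(2 / fan_in) * if (l == L) out_scale else 1
    layers[[l]] <- list(
      W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sc),
                 sizes[l], sizes[l + 1]),
      b = numeric(sizes[l + 1])
    )
  }
  structure(list(layers = layers, act = act, sizes = sizes),
            class = "mmsynth_mlp")
}

#' Forward pass through an MLP
#'
#' @param net `mmsynth_mlp`.
#' @param X n x d input matrix.
#' @param dropout hidden-unit dropout probability; applied only when
#'   `training = TRUE` (inverted dropout, so eval mode needs no rescaling).
#' @return list with `out` (n x d_out) and `cache` for [mlp_backward()].
#' @keywords internal
mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  X <- as.matrix(X)
  L <- length(net$layers)
  acts <- vector("list", L)   # input to each layer
  pres <- vector("list", L)   # pre-activation of each layer
  masks <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    acts[[l]] <- A
    Z <- A %*% net$layers[[l]]$W
    Z <- sweep(Z, 2, net$layers[[l]]$b, "+")
    pres[[l]] <- Z
    A <- if (l < L) act_fun(Z, net$act) else Z
    if (l < L && training && dropout > 0) {
      m <- matrix(stats::rbinom(length(A), 1, 1 - dropout), nrow(A)) / (1 - dropout)
      masks[[l]] <- m
      A <- A * m
    }
  }
  list(out = A, cache = list(acts = acts, pres = pres, masks = masks))
}

#' Backward pass through an MLP
#'
#' @param dOut gradient of the loss w.r.t. the network output (n x d_out).
#' @return list with `grads` (per-layer `W`/`b` summed over samples), `dX`
#'   (gradient w.r.t. the input), and `per_layer` delta/activation pairs for
#'   per-sample gradient-norm computation.
#' @keywords internal
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  per_layer <- vector("list", L)
  D <- as.matrix(dOut)
  for (l in rev(seq_len(L))) {
    if (l < L) {
      if (!is.null(cache$masks[[l]])) D <- D * cache$masks[[l]]
      D <- D * act_grad(cache$pres[[l]], net$act)
    }
    A <- cache$acts[[l]]
    grads[[l]] <- list(W = crossprod(A, D), b = colSums(D))
    per_layer[[l]] <- list(delta = D, act = A)
    D <- D %*% t(net$layers[[l]]$W)
  }
  list(grads = grads, dX = D, per_layer = per_layer)
}

adam_init <- function(net) {
  lapply(net$layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, opt, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    o <- opt[[l]]
    o$mW <- beta1 * o$mW + (1 - beta1) * g$W
    o$vW <- beta2 * o$vW + (1 - beta2) * g$W^2
    o$mb <- beta1 * o$mb + (1 - beta1) * g$b
    o$vb <- beta2 * o$vb + (1 - beta2) * g$b^2
    mW <- o$mW / (1 - beta1^t); vW <- o$vW / (1 - beta2^t)
    mb <- o$mb / (1 - beta1^t); vb <- o$vb / (1 - beta2^t)
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * mW / (sqrt(vW) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * mb / (sqrt(vb) + eps)
    opt[[l]] <- o
  }
  list(net = net, opt = opt)
}

# plain SGD step on summed gradients divided by n
sgd_step <- function(net, grads, lr, n = 1) {
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * grads[[l]]$W / n
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * grads[[l]]$b / n
  }
  net
}

# flatten per-sample gradients of an MLP backward pass into an n x P matrix
# (used by tests and by the DP path when an explicit matrix is requested)
per_sample_grad_matrix <- function(per_layer) {
  n <- nrow(per_layer[[1]]$delta)
  blocks <- lapply(per_layer, function(pl) {
    din <- ncol(pl$act); dout <- ncol(pl$delta)
    Wg <- matrix(0, n, din * dout)
    for (i in seq_len(n)) {
      Wg[i, ] <- as.vector(outer(pl$act[i, ], pl$delta[i, ]))
    }
    cbind(Wg, pl$delta)
  })
  do.call(cbind, blocks)
}

# per-sample gradient euclidean norms without materialising the gradients:
# ||outer(a, d)||_F^2 = ||a||^2 ||d||^2, bias contributes ||d||^2
per_sample_grad_norms <- function(per_layer) {
  n <- nrow(per_layer[[1]]$delta)
  s <- numeric(n)
  for (pl in per_layer) {
    dn <- rowSums(pl$delta^2)
    s <- s + dn * rowSums(pl$act^2) + dn
  }
  sqrt(s)
}

# clipped, noised, averaged gradients in per-layer form (DP-SGD on an MLP)
dp_layer_grads <- function(per_layer, clip_norm, noise_multiplier) {
  norms <- per_sample_grad_norms(per_layer)
  scale <- 1 / pmax(1, norms / clip_norm)
  B <- length(scale)
  lapply(per_layer, function(pl) {
    Ds <- pl$delta * scale
    W <- crossprod(pl$act, Ds)
    b <- colSums(Ds)
    if (noise_multiplier > 0) {
      W <- W + matrix(stats::rnorm(length(W), sd = noise_multiplier * clip_norm),
                      nrow(W))
      b <- b + stats::rnorm(length(b), sd = noise_multiplier * clip_norm)
    }
    list(W = W / B, b = b / B)
  })
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
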