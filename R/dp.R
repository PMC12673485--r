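# ---- DP-SGD mechanics and Renyi-DP accounting ------------------------------

#' Differential-privacy configuration for DP-SGD
#'
#' @param clip_norm per-sample gradient clipping norm C (> 0).
#' @param noise_multiplier ratio sigma of Gaussian noise SD to C (>= 0).
#' @param sampling_rate Poisson/mini-batch sampling rate q = B/N in (0, 1].
#' @param delta target delta of the (epsilon, delta) guarantee.
#' @param epsilon_budget maximum admissible epsilon.
#' @param orders Renyi orders alpha > 1 used by the accountant. The default
#'   grid (quarter-steps up to 64 plus all integers) is dense enough for
#'   budgets near 1.
#' @return an object of class `dp_config`.
#' @export
dp_config <- function(clip_norm = 1.0, noise_multiplier = 1.2,
                      sampling_rate = 0.002, delta = 1e-5,
                      epsilon_budget = 1.0,
                      orders = default_rdp_orders()) {
  if (!is.numeric(clip_norm) || length(clip_norm) != 1 || clip_norm <= 0)
    stop("dp_config: 'clip_norm' must be a positive number")
  if (!is.numeric(noise_multiplier) || noise_multiplier < 0)
    stop("dp_config: 'noise_multiplier' must be >= 0")
  if (sampling_rate <= 0 || sampling_rate > 1)
    stop("dp_config: 'sampling_rate' must be in (0, 1]")
  if (delta <= 0 || delta >= 1)
    stop("dp_config: 'delta' must be in (0, 1)")
  if (any(orders <= 1))
    stop("dp_config: 'orders' must all exceed 1")
  structure(list(clip_norm = clip_norm, noise_multiplier = noise_multiplier,
                 sampling_rate = sampling_rate, delta = delta,
                 epsilon_budget = epsilon_budget, orders = sort(orders)),
            class = "dp_config")
}

#' @rdname dp_config
#' @export
default_rdp_orders <- function() {
  # quarter-steps where the optimum usually lies, plus high integer orders so
  # that small-epsilon targets (down to ~0.05) remain expressible: the
  # conversion can never go below log(1/delta)/(max(alpha) - 1)
  sort(unique(c(seq(1.25, 63.75, by = 0.25), 2:256)))
}

#' Clip per-sample gradients and add Gaussian noise
#'
#' Each row of `grads` (one per-sample gradient) is scaled by
#' `1 / max(1, ||g_i|| / C)` so its norm never exceeds C. Gaussian noise with
#' per-coordinate SD `sigma * C` is added to the clipped sum, and the result
#' is divided by the batch size B, so the output noise has per-coordinate SD
#' `sigma * C / B`. Setting `literal_eq = TRUE` instead noises the average
#' directly with SD `sigma * C` (a strictly noisier variant kept for
#' reproduction of the averaged-form update some descriptions print; the
#' accountant's guarantees assume the default).
#'
#' @param grads B x P matrix of per-sample gradients.
#' @param clip_norm clipping norm C (> 0).
#' @param noise_multiplier noise multiplier sigma (>= 0).
#' @param literal_eq add noise after averaging rather than to the sum.
#' @return length-P privatised averaged gradient.
#' @export
clip_and_noise <- function(grads, clip_norm, noise_multiplier,
                           literal_eq = FALSE) {
  if (clip_norm <= 0) stop("clip_and_noise: 'clip_norm' must be > 0")
  grads <- as.matrix(grads)
  B <- nrow(grads)
  norms <- sqrt(rowSums(grads^2))
  clipped <- grads / pmax(1, norms / clip_norm)
  total <- colSums(clipped)
  sd_noise <- noise_multiplier * clip_norm
  if (literal_eq) {
    total / B + stats::rnorm(ncol(grads), sd = sd_noise)
  } else {
    (total + stats::rnorm(ncol(grads), sd = sd_noise)) / B
  }
}

# log(choose(n, k)) for possibly large n
log_choose <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# integer-order subsampled-Gaussian RDP via the stable binomial expansion:
# (1/(alpha-1)) * log sum_k C(alpha,k) (1-q)^(alpha-k) q^k exp(k(k-1)/(2 sigma^2))
rdp_subsampled_int <- function(q, sigma, alpha) {
  ks <- 0:alpha
  terms <- log_choose(alpha, ks) + ks * log(q) + (alpha - ks) * log1p(-q) +
    ks * (ks - 1) / (2 * sigma^2)
  # k = 0 term: q^0 -> log term 0 * log(q) is fine (0 * -Inf avoided since q>0)
  log_sum_exp(terms) / (alpha - 1)
}

#' Per-step Renyi-DP value of the (subsampled) Gaussian mechanism
#'
#' For `q = 1` this is the Gaussian-mechanism closed form
#' `alpha / (2 sigma^2)`. For `q < 1` it is the subsampled-Gaussian upper
#' bound, computed with a log-domain binomial expansion at integer orders and
#' by linear interpolation between the neighbouring integer orders at
#' fractional ones. `q = 0` touches no data and costs nothing.
#'
#' @param q sampling rate in \[0, 1\].
#' @param sigma noise multiplier (> 0; `sigma = 0` signals infinite loss).
#' @param alpha Renyi order (> 1); may be a vector.
#' @return per-step RDP value(s), same length as `alpha`.
#' @export
rdp_step <- function(q, sigma, alpha) {
  if (any(alpha <= 1)) stop("rdp_step: 'alpha' must exceed 1")
  if (q < 0 || q > 1) stop("rdp_step: 'q' must be in [0, 1]")
  if (q == 0) return(rep(0, length(alpha)))
  if (sigma == 0) {
    warning("rdp_step: sigma = 0 gives infinite privacy loss")
    return(rep(Inf, length(alpha)))
  }
  if (q == 1) return(alpha / (2 * sigma^2))
  vapply(alpha, function(a) {
    if (a == floor(a)) {
      rdp_subsampled_int(q, sigma, as.integer(a))
    } else {
      lo <- floor(a); hi <- ceiling(a)
      if (lo < 2) lo <- 2  # expansion needs an integer order >= 2
      rlo <- rdp_subsampled_int(q, sigma, as.integer(lo))
      rhi <- rdp_subsampled_int(q, sigma, as.integer(hi))
      w <- (a - lo) / max(hi - lo, 1)
      (1 - w) * rlo + w * rhi
    }
  }, numeric(1))
}

#' Create an empty privacy ledger
#'
#' A ledger accumulates per-order RDP totals across composed DP-SGD steps and
#' converts them to an (epsilon, delta) guarantee on demand.
#'
#' @param config a [dp_config()].
#' @return object of class `privacy_ledger`.
#' @export
privacy_ledger <- function(config = dp_config()) {
  structure(list(config = config,
                 rdp = stats::setNames(rep(0, length(config$orders)),
                                       config$orders),
                 steps = 0L),
            class = "privacy_ledger")
}

#' Compose DP-SGD steps onto a ledger
#'
#' RDP composes additively: `steps` homogeneous steps at the given `(q,
#' sigma)` add `steps` times the per-step value at every order. Heterogeneous
#' schedules are composed by successive calls.
#'
#' @param ledger a [privacy_ledger()].
#' @param steps number of steps to append (>= 0).
#' @param q,sigma per-step sampling rate and noise multiplier; default from
#'   the ledger's config.
#' @return the updated ledger (with `epsilon` recomputed).
#' @export
ledger_compose <- function(ledger, steps = 1,
                           q = ledger$config$sampling_rate,
                           sigma = ledger$config$noise_multiplier) {
  stopifnot(inherits(ledger, "privacy_ledger"), steps >= 0)
  if (steps > 0) {
    ledger$rdp <- ledger$rdp + steps * rdp_step(q, sigma, ledger$config$orders)
    ledger$steps <- ledger$steps + as.integer(steps)
  }
  ledger$epsilon <- to_epsilon(ledger, ledger$config$delta)$epsilon
  ledger
}

#' Convert accumulated RDP to an (epsilon, delta) guarantee
#'
#' `epsilon = min_alpha [ RDP(alpha) + log(1/delta) / (alpha - 1) ]`.
#'
#' @param ledger a [privacy_ledger()] (possibly empty).
#' @param delta target delta.
#' @return list with `epsilon` and the achieving `order`.
#' @export
to_epsilon <- function(ledger, delta = ledger$config$delta) {
  if (all(ledger$rdp == 0))  # no mechanism invoked: perfect privacy
    return(list(epsilon = 0, order = NA_real_))
  orders <- ledger$config$orders
  eps <- ledger$rdp + log(1 / delta) / (orders - 1)
  i <- which.min(eps)
  list(epsilon = unname(eps[i]), order = orders[i])
}

#' Check a ledger against an epsilon budget
#'
#' @param ledger a [privacy_ledger()].
#' @param epsilon_budget maximum admissible epsilon.
#' @param delta target delta.
#' @return list with `pass`, certified `epsilon`, `margin`
#'   (budget - epsilon), achieving `order`, `steps`.
#' @export
assert_budget <- function(ledger, epsilon_budget = ledger$config$epsilon_budget,
                          delta = ledger$config$delta) {
  e <- to_epsilon(ledger, delta)
  list(pass = e$epsilon <= epsilon_budget, epsilon = e$epsilon,
       margin = epsilon_budget - e$epsilon, order = e$order,
       steps = ledger$steps, delta = delta)
}

#' Solve for the noise multiplier meeting an epsilon target
#'
#' Bisection on sigma so that `T` steps at sampling rate `q` certify at most
#' `epsilon_target` at `delta`. epsilon is monotone decreasing in sigma, so
#' the root is unique.
#'
#' @param epsilon_target desired certified epsilon.
#' @param q sampling rate; @param steps number of composed steps.
#' @param delta target delta.
#' @param interval search interval for sigma.
#' @return the smallest sigma (to tolerance) certifying the target.
#' @export
sigma_for_epsilon <- function(epsilon_target, q, steps, delta = 1e-5,
                              interval = c(0.3, 200)) {
  eps_at <- function(s) {
    led <- ledger_compose(privacy_ledger(dp_config(
      noise_multiplier = s, sampling_rate = q, delta = delta)), steps = steps)
    led$epsilon - epsilon_target
  }
  if (eps_at(interval[2]) > 0)
    stop("sigma_for_epsilon: target unattainable within sigma interval")
  stats::uniroot(eps_at, interval, tol = 1e-4)$root
}

#' Serialise / restore a privacy ledger as JSON
#' @param ledger a [privacy_ledger()]; @param path file path.
#' @export
write_ledger <- function(ledger, path) {
  out <- list(config = unclass(ledger$config), rdp = unname(ledger$rdp),
              orders = ledger$config$orders, steps = ledger$steps,
              epsilon = to_epsilon(ledger)$epsilon)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- dp_config(clip_norm = x$config$clip_norm,
                   noise_multiplier = x$config$noise_multiplier,
                   sampling_rate = x$config$sampling_rate,
                   delta = x$config$delta,
                   epsilon_budget = x$config$epsilon_budget,
                   orders = x$orders)
  led <- privacy_ledger(cfg)
  led$rdp <- stats::setNames(x$rdp, x$orders)
  led$steps <- as.integer(x$steps)
  led$epsilon <- to_epsilon(led)$epsilon
  led
}
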