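# shared fixtures: all built in code, seeded

# small multimodal cohort config used across test files
small_cohort_config <- function(n = 120, seed = 42, effect_size = 1, ...) {
  args <- utils::modifyList(
    list(n_subjects = n, effect_size = effect_size, eeg_channels = 4,
         eeg_epoch_sec = 1, image_patch_edge = 4, embed_dim = 32,
         vocab_size = 16, n_sites = 5, seed = seed),
    list(...))
  do.call(cohort_config, args)
}

# two-modality Gaussian toy with coherent class gaps (the planted synthesis
# task): embedding-like block shifts +gap1 for class 2, tabular-like block
# shifts -gap2
gaussian_toy <- function(seed, n = 200, gap1 = 0.75, gap2 = 0.5) {
  set.seed(seed)
  y <- rep(1:2, each = n / 2)
  list(X = list(embedding = matrix(rnorm(n * 8), n) +
                  outer(ifelse(y == 2, gap1, -gap1), rep(1, 8)),
                tabular = matrix(rnorm(n * 6), n) +
                  outer(ifelse(y == 2, -gap2, gap2), rep(1, 6))),
       y = y)
}

# tiny run configuration for pipeline-level tests
tiny_run_config <- function(seeds = 42, n = 120) {
  run_config(n_subjects = n, seeds = seeds, effect_size = 1,
             madsn_epochs = 3, amel_epochs = 40, n_synth = 60)
}

expect_simplex <- function(alpha, tol = 1e-10) {
  expect_true(all(alpha >= -tol))
  expect_equal(unname(rowSums(as.matrix(alpha))),
               rep(1, nrow(as.matrix(alpha))), tolerance = 1e-8)
}
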