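# ---- synthetic multimodal cohort generator ---------------------------------

GENERATOR_VERSION <- "mmsynth-cohort-1"

#' Configuration for the synthetic multimodal cohort generator
#'
#' The generator emulates the structure of multi-site autism repositories:
#' a small 3D imaging patch per subject, a multi-channel EEG epoch, a
#' behavioural token sequence with a fixed-width embedding, mixed
#' demographics with site effects and missingness, severity item scores, a
#' binary diagnosis label and an ordinal severity class.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param class_balance fraction of subjects with label 1, in \[0, 1\].
#' @param n_sites number of acquisition sites.
#' @param eeg_channels EEG channel count.
#' @param eeg_sfreq EEG sampling frequency in Hz; must exceed twice the
#'   highest generated frequency (50 Hz mains).
#' @param eeg_epoch_sec epoch length in seconds.
#' @param image_patch_edge edge length of the cubic imaging patch (voxels).
#' @param embed_dim width of the behavioural embedding.
#' @param vocab_size behavioural token vocabulary size.
#' @param effect_size class-separation knob (>= 0); 0 plants no class signal
#'   in any modality.
#' @param missing_rate fraction of demographic/severity entries set missing.
#' @param artifact_rate fraction of EEG epochs given a +-100 uV-exceeding
#'   artifact sample.
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, class_balance = 0.5, n_sites = 17,
                          eeg_channels = 8, eeg_sfreq = 250,
                          eeg_epoch_sec = 2, image_patch_edge = 8,
                          embed_dim = 128, vocab_size = 32,
                          effect_size = 1, missing_rate = 0.05,
                          artifact_rate = 0.02, seed = 42) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x < 1 || x != round(x))
      stop("cohort_config: '", nm, "' must be a count >= 1")
  }
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1)
      stop("cohort_config: '", nm, "' must be a fraction in [0, 1]")
  }
  for (nm in c("n_subjects", "n_sites", "eeg_channels", "eeg_sfreq",
               "image_patch_edge", "embed_dim", "vocab_size"))
    chk_count(get(nm), nm)
  for (nm in c("class_balance", "missing_rate", "artifact_rate"))
    chk_frac(get(nm), nm)
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("cohort_config: 'effect_size' must be >= 0")
  if (!is.numeric(eeg_epoch_sec) || eeg_epoch_sec <= 0)
    stop("cohort_config: 'eeg_epoch_sec' must be > 0")
  if (eeg_sfreq <= 2 * 50)
    stop("cohort_config: 'eeg_sfreq' must exceed twice the highest generated frequency (50 Hz)")
  structure(list(n_subjects = as.integer(n_subjects),
                 class_balance = class_balance, n_sites = as.integer(n_sites),
                 eeg_channels = as.integer(eeg_channels),
                 eeg_sfreq = eeg_sfreq, eeg_epoch_sec = eeg_epoch_sec,
                 image_patch_edge = as.integer(image_patch_edge),
                 embed_dim = as.integer(embed_dim),
                 vocab_size = as.integer(vocab_size),
                 effect_size = effect_size, missing_rate = missing_rate,
                 artifact_rate = artifact_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

# fixed random codebook shared by generation and nearest-codebook decoding;
# depends only on (vocab_size, embed_dim), not on the cohort seed, so real
# and synthetic text live in the same embedding space
behavior_codebook <- function(vocab_size, embed_dim) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(20260101L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  matrix(stats::rnorm(vocab_size * embed_dim), vocab_size, embed_dim)
}

# 1/f-shaped noise via FFT shaping of white noise
pink_noise <- function(n, sd = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x) * sd
}

# row-stochastic Markov transition matrix with a mild diagonal preference
random_markov <- function(v) {
  M <- matrix(stats::rexp(v * v), v, v) + diag(v) * 2
  M / rowSums(M)
}

markov_sample <- function(trans, len) {
  v <- nrow(trans)
  s <- integer(len)
  s[1] <- sample.int(v, 1)
  for (i in seq_len(len - 1))
    s[i + 1] <- sample.int(v, 1, prob = trans[s[i], ])
  s - 1L  # tokens over [0, v)
}

# per-class amplitude of the 10 Hz alpha component: a + effect * label * b
ALPHA_BASE_AMP <- 4      # uV, class-0 alpha amplitude
ALPHA_EFFECT_AMP <- 3    # uV per unit effect_size for class 1
MAINS_AMP <- 1.5         # uV, 50 Hz mains leakage (exercises the notch)
EEG_NOISE_SD <- 10       # uV, 1/f background
IMAGE_EFFECT <- 0.15     # central sub-block mean offset per unit effect_size
SEVERITY_EFFECT <- 0.25  # per-item mean shift per unit effect_size
TOKEN_LEN <- 20L         # behavioural sequence length

#' Generate a synthetic multimodal cohort
#'
#' Deterministic given the config (including its seed). Planted class
#' structure, strongest to weakest: EEG alpha-band (10 Hz) amplitude shift
#' scaled by `effect_size` on top of 1/f noise (plus a small 50 Hz mains
#' tone); behavioural tokens from two class-conditional Markov chains
#' interpolated by `effect_size`; severity item mean shifts; a mean offset in
#' the central sub-block of the imaging patch. Sites add additive offsets to
#' continuous features. `missing_rate` of demographic/severity entries are
#' set to `NA`; `artifact_rate` of EEG epochs receive a sample exceeding
#' +-100 uV.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort`: list with `records`, `config`,
#'   `provenance`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  v <- config$vocab_size
  n_samp <- round(config$eeg_sfreq * config$eeg_epoch_sec)
  edge <- config$image_patch_edge
  eff <- config$effect_size

  # labels: forced balance within +-1 subject, order shuffled
  n1 <- round(n * config$class_balance)
  labels <- sample(c(rep(1L, n1), rep(0L, n - n1)))
  sites <- sample.int(config$n_sites, n, replace = TRUE)
  site_offset <- stats::rnorm(config$n_sites, sd = 0.3)

  # class-conditional Markov chains, identical at effect_size = 0
  T0 <- random_markov(v)
  T_alt <- random_markov(v)
  w <- min(1, 0.5 * eff)
  T1 <- (1 - w) * T0 + w * T_alt
  codebook <- behavior_codebook(v, config$embed_dim)

  t_idx <- seq_len(n_samp) / config$eeg_sfreq
  alpha_wave <- sin(2 * pi * 10 * t_idx)
  mains_wave <- sin(2 * pi * 50 * t_idx)
  mid <- (edge %/% 4 + 1):(edge - edge %/% 4)

  records <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    so <- site_offset[sites[i]]

    amp <- ALPHA_BASE_AMP + eff * lab * ALPHA_EFFECT_AMP
    eeg <- matrix(0, config$eeg_channels, n_samp)
    for (ch in seq_len(config$eeg_channels)) {
      phase <- stats::runif(1, 0, 2 * pi)
      eeg[ch, ] <- pink_noise(n_samp, sd = EEG_NOISE_SD) +
        amp * sin(2 * pi * 10 * t_idx + phase) +
        MAINS_AMP * mains_wave + so
    }
    if (stats::runif(1) < config$artifact_rate) {
      ch <- sample.int(config$eeg_channels, 1)
      pos <- sample.int(n_samp, 1)
      eeg[ch, pos] <- sample(c(-1, 1), 1) * stats::runif(1, 120, 200)
    }

    img <- array(stats::rnorm(edge^3) + so * 0.5, dim = c(edge, edge, edge))
    img[mid, mid, mid] <- img[mid, mid, mid] + IMAGE_EFFECT * eff * lab

    trans <- if (lab == 1L) T1 else T0
    tokens <- markov_sample(trans, TOKEN_LEN)
    embedding <- colMeans(codebook[tokens + 1L, , drop = FALSE])

    sev <- pmax(0, stats::rnorm(8, mean = 1.5 + SEVERITY_EFFECT * eff * lab,
                                sd = 0.8))
    sev_sum <- sum(sev)
    # fixed cut-points (tertiles of the null sum distribution ~ N(12, 2.26))
    sev_class <- if (sev_sum < 11) "mild" else if (sev_sum < 13.5)
      "moderate" else "severe"

    age <- max(4, stats::rnorm(1, mean = 12, sd = 5) + so)
    demo <- list(age = age,
                 sex = sample(c("M", "F"), 1, prob = c(0.8, 0.2)),
                 site = paste0("site", sites[i]),
                 relationship = sample(c("proband", "sibling", "parent"), 1,
                                       prob = c(0.7, 0.2, 0.1)))

    # missingness: eligible fields are age, sex, relationship, severity items
    if (config$missing_rate > 0) {
      if (stats::runif(1) < config$missing_rate) demo$age <- NA_real_
      if (stats::runif(1) < config$missing_rate) demo$sex <- NA_character_
      if (stats::runif(1) < config$missing_rate)
        demo$relationship <- NA_character_
      miss <- stats::runif(8) < config$missing_rate
      sev[miss] <- NA_real_
    }

    records[[i]] <- list(
      subject_id = sprintf("S%05d", i),
      image_patch = img, eeg = eeg,
      behavior_tokens = tokens, behavior_embedding = embedding,
      demographics = demo, severity_items = sev,
      label = lab, severity_class = sev_class)
  }
  structure(list(records = records, config = config,
                 provenance = list(seed = config$seed,
                                   generator = GENERATOR_VERSION)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cfg <- x$config
  cat("mmsynth cohort:", length(x$records), "subjects,",
      cfg$n_sites, "sites, effect_size", cfg$effect_size,
      "| seed", x$provenance$seed, "\n")
  invisible(x)
}

#' Extract the tabular phenotype table of a cohort
#'
#' One row per subject with columns `subject_id`, `age`, `sex`, `site`,
#' `relationship`, `A1`..`A8`, `label`, `severity_class`.
#'
#' @param cohort a [generate_cohort()] result.
#' @export
cohort_table <- function(cohort) {
  rows <- lapply(cohort$records, function(r) {
    sev <- as.list(r$severity_items)
    names(sev) <- paste0("A", 1:8)
    c(list(subject_id = r$subject_id, age = r$demographics$age,
           sex = r$demographics$sex, site = r$demographics$site,
           relationship = r$demographics$relationship),
      sev, list(label = r$label, severity_class = r$severity_class))
  })
  do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
}

#' Write a cohort to a directory
#'
#' Tabular fields go to `phenotype.csv`, behavioural token sequences to
#' `tokens.csv`, arrays (EEG, imaging patches, behavioural embeddings) to RDS
#' containers keyed by subject order, and `manifest.json` records files,
#' shapes and the generator seed.
#'
#' @param cohort a `cohort`; @param directory output directory (created).
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cohort"))
  if (!length(cohort$records)) stop("write_cohort: empty cohort")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("write_cohort: cannot create ", directory)
  tab <- cohort_table(cohort)
  data.table::fwrite(tab, file.path(directory, "phenotype.csv"), na = "NA")
  toks <- data.frame(
    subject_id = vapply(cohort$records, `[[`, "", "subject_id"),
    tokens = vapply(cohort$records, function(r)
      paste(r$behavior_tokens, collapse = " "), ""))
  data.table::fwrite(toks, file.path(directory, "tokens.csv"))
  arrays <- list(
    eeg = lapply(cohort$records, `[[`, "eeg"),
    image_patch = lapply(cohort$records, `[[`, "image_patch"),
    behavior_embedding = lapply(cohort$records, `[[`, "behavior_embedding"))
  for (nm in names(arrays))
    saveRDS(arrays[[nm]], file.path(directory, paste0(nm, ".rds")))
  cfg <- cohort$config
  manifest <- list(
    generator = cohort$provenance$generator, seed = cohort$provenance$seed,
    n_subjects = length(cohort$records),
    files = c("phenotype.csv", "tokens.csv", "eeg.rds", "image_patch.rds",
              "behavior_embedding.rds"),
    shapes = list(
      eeg = c(cfg$eeg_channels, round(cfg$eeg_sfreq * cfg$eeg_epoch_sec)),
      image_patch = rep(cfg$image_patch_edge, 3),
      behavior_embedding = cfg$embed_dim),
    config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory containing `manifest.json` and the files it
#'   lists. Missing files or shape mismatches raise an error naming the file.
#' @export
read_cohort <- function(directory) {
  man_path <- file.path(directory, "manifest.json")
  if (!file.exists(man_path)) stop("read_cohort: missing file manifest.json")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  for (f in man$files)
    if (!file.exists(file.path(directory, f)))
      stop("read_cohort: missing file ", f)
  tab <- data.table::fread(file.path(directory, "phenotype.csv"),
                           data.table = FALSE, na.strings = "NA")
  need <- c("subject_id", "age", "sex", "site", "relationship",
            paste0("A", 1:8), "label", "severity_class")
  if (!all(need %in% names(tab)) || nrow(tab) != man$n_subjects)
    stop("read_cohort: malformed or truncated phenotype.csv")
  toks <- data.table::fread(file.path(directory, "tokens.csv"),
                            data.table = FALSE)
  if (nrow(toks) != man$n_subjects)
    stop("read_cohort: malformed or truncated tokens.csv")
  arrays <- lapply(c(eeg = "eeg", image_patch = "image_patch",
                     behavior_embedding = "behavior_embedding"),
                   function(nm) readRDS(file.path(directory,
                                                  paste0(nm, ".rds"))))
  for (nm in names(arrays)) {
    if (length(arrays[[nm]]) != man$n_subjects)
      stop("read_cohort: wrong subject count in ", nm, ".rds")
  }
  if (!all(dim(arrays$eeg[[1]]) == man$shapes$eeg))
    stop("read_cohort: shape mismatch in eeg.rds")
  if (!all(dim(arrays$image_patch[[1]]) == man$shapes$image_patch))
    stop("read_cohort: shape mismatch in image_patch.rds")
  if (length(arrays$behavior_embedding[[1]]) != man$shapes$behavior_embedding)
    stop("read_cohort: shape mismatch in behavior_embedding.rds")
  cfgl <- man$config
  config <- cohort_config(
    n_subjects = cfgl$n_subjects, class_balance = cfgl$class_balance,
    n_sites = cfgl$n_sites, eeg_channels = cfgl$eeg_channels,
    eeg_sfreq = cfgl$eeg_sfreq, eeg_epoch_sec = cfgl$eeg_epoch_sec,
    image_patch_edge = cfgl$image_patch_edge, embed_dim = cfgl$embed_dim,
    vocab_size = cfgl$vocab_size, effect_size = cfgl$effect_size,
    missing_rate = cfgl$missing_rate, artifact_rate = cfgl$artifact_rate,
    seed = cfgl$seed)
  records <- lapply(seq_len(man$n_subjects), function(i) {
    sev <- as.numeric(tab[i, paste0("A", 1:8)])
    list(subject_id = tab$subject_id[i],
         image_patch = arrays$image_patch[[i]], eeg = arrays$eeg[[i]],
         behavior_tokens = as.integer(strsplit(toks$tokens[i], " ")[[1]]),
         behavior_embedding = arrays$behavior_embedding[[i]],
         demographics = list(age = tab$age[i], sex = tab$sex[i],
                             site = tab$site[i],
                             relationship = tab$relationship[i]),
         severity_items = sev, label = as.integer(tab$label[i]),
         severity_class = tab$severity_class[i])
  })
  structure(list(records = records, config = config,
                 provenance = list(seed = man$seed, generator = man$generator)),
            class = "cohort")
}
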