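# ---- fitted, replayable preprocessing --------------------------------------

#' Fit a z-score transform
#'
#' Population (1/n) standard deviation over the observed (non-missing)
#' values, so that transformed training values have mean 0 and variance 1.
#'
#' @param values numeric vector, possibly with `NA`.
#' @return list with `mu` and `sigma`.
#' @export
fit_zscore <- function(values) {
  x <- values[!is.na(values)]
  if (!length(x)) stop("fit_zscore: all values missing")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  list(mu = mu, sigma = sigma)
}

#' Apply a fitted z-score transform
#'
#' `x' = (x - mu) / sigma`; constant features (`sigma = 0`) map to 0 after
#' centering rather than dividing by zero.
#'
#' @param values numeric vector; @param mu,sigma fitted parameters.
#' @export
apply_zscore <- function(values, mu, sigma) {
  if (sigma == 0) return(ifelse(is.na(values), NA_real_, 0))
  (values - mu) / sigma
}

#' Fit preprocessing state on training rows
#'
#' Means/SDs for every numeric column and ordered category vocabularies
#' (always ending in `"unknown"`) for every categorical column, computed from
#' the training rows only.
#'
#' @param table data.frame of phenotype rows (training subset).
#' @param numeric_cols,categorical_cols column names.
#' @param eeg_filter_params EEG filter settings stored with the state.
#' @param reject_threshold artifact rejection threshold in uV.
#' @return object of class `preprocess_state`.
#' @export
fit_preprocess <- function(table,
                           numeric_cols = c("age", paste0("A", 1:8)),
                           categorical_cols = c("sex", "site", "relationship"),
                           eeg_filter_params = list(band_low = 1,
                                                    band_high = 40,
                                                    notch = 50, order = 4),
                           reject_threshold = 100) {
  miss <- setdiff(c(numeric_cols, categorical_cols), names(table))
  if (length(miss)) stop("fit_preprocess: columns absent: ",
                         paste(miss, collapse = ", "))
  zs <- lapply(numeric_cols, function(cl) fit_zscore(table[[cl]]))
  names(zs) <- numeric_cols
  vocab <- lapply(categorical_cols, function(cl) {
    v <- sort(unique(stats::na.omit(as.character(table[[cl]]))))
    c(v, "unknown")
  })
  names(vocab) <- categorical_cols
  structure(list(
    feature_means = vapply(zs, `[[`, 0, "mu"),
    feature_sds = vapply(zs, `[[`, 0, "sigma"),
    category_vocab = vocab,
    eeg_filter_params = eeg_filter_params,
    reject_threshold = reject_threshold),
    class = "preprocess_state")
}

#' Impute missing values from fitted state
#'
#' Numeric missing entries get the training mean; categorical missing entries
#' get the `"unknown"` category. Observed values pass through unchanged.
#'
#' @param values vector with possible `NA`.
#' @param feature feature name, looked up in `state`.
#' @param state a [fit_preprocess()] result.
#' @export
impute <- function(values, feature, state) {
  if (feature %in% names(state$feature_means)) {
    values[is.na(values)] <- state$feature_means[[feature]]
    values
  } else if (feature %in% names(state$category_vocab)) {
    values <- as.character(values)
    values[is.na(values)] <- "unknown"
    values
  } else {
    stop("impute: feature '", feature, "' absent from preprocessing state")
  }
}

#' One-hot encode a categorical value
#'
#' @param value a category value (length 1); `NA` or values unseen at fit
#'   time map to the `"unknown"` slot.
#' @param vocab ordered category vector containing `"unknown"`.
#' @return binary vector of length `length(vocab)` summing to 1.
#' @export
one_hot <- function(value, vocab) {
  h <- numeric(length(vocab))
  value <- as.character(value)
  j <- if (is.na(value) || !(value %in% vocab)) match("unknown", vocab)
       else match(value, vocab)
  h[j] <- 1
  stats::setNames(h, vocab)
}

# RBJ biquad notch filter coefficients
notch_coefs <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter an EEG epoch
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass between
#' `band_low` and `band_high`, followed by a zero-phase 2nd-order IIR notch
#' (Q = 30) at `notch`. Applied per channel; output shape unchanged.
#'
#' @param eeg channels x samples matrix (uV).
#' @param sfreq sampling frequency in Hz; must exceed `2 * band_high`.
#' @param band_low,band_high band edges in Hz.
#' @param notch notch frequency in Hz (`NULL` to skip).
#' @export
filter_eeg <- function(eeg, sfreq, band_low = 1, band_high = 40, notch = 50) {
  if (sfreq <= 2 * band_high)
    stop("filter_eeg: sfreq must exceed twice band_high")
  eeg <- as.matrix(eeg)
  bp <- signal::butter(2, c(band_low, band_high) / (sfreq / 2), type = "pass")
  nc <- if (!is.null(notch)) notch_coefs(notch, sfreq) else NULL
  out <- t(apply(eeg, 1, function(ch) {
    y <- signal::filtfilt(bp, ch)
    if (!is.null(nc)) y <- signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), y)
    y
  }))
  dimnames(out) <- dimnames(eeg)
  out
}

#' Reject high-amplitude EEG epochs and z-score the rest
#'
#' An epoch is rejected iff any sample exceeds the threshold in absolute
#' value. Kept epochs are z-scored epoch-wise (all samples of the epoch
#' jointly, population SD).
#'
#' @param epochs list of channels x samples matrices.
#' @param threshold rejection threshold in uV.
#' @return list with `kept` (z-scored epochs), `mask` (TRUE = rejected).
#' @export
reject_epochs <- function(epochs, threshold = 100) {
  mask <- vapply(epochs, function(e) any(abs(e) > threshold), logical(1))
  kept <- lapply(epochs[!mask], function(e) {
    mu <- mean(e)
    s <- sqrt(mean((e - mu)^2))
    if (s == 0) e - mu else (e - mu) / s
  })
  if (all(mask) && length(epochs))
    warning("reject_epochs: all epochs rejected")
  list(kept = kept, mask = mask)
}

age_bin <- function(age) {
  cut(age, breaks = c(-Inf, 10, 18, Inf), labels = c("<10", "10-18", ">18"),
      right = FALSE)
}

# largest-remainder apportionment of n into shares proportional to ratios;
# ties broken by seeded order
largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- exact - base
  left <- n - sum(base)
  if (left > 0) {
    # ties in the remainders are broken by seeded shuffle
    ord <- order(rem, stats::runif(length(rem)), decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  base
}

#' Stratified train/validation/test split
#'
#' Subjects are stratified by (label, age bin, site) with age bins
#' \{<10, 10-18, >18\}; within each stratum the ratios are honoured with
#' largest-remainder rounding over a seeded shuffle. Strata smaller than 3
#' subjects are merged across age bins (keeping label and site), with a
#' message.
#'
#' @param cohort a `cohort` or a phenotype data.frame with `subject_id`,
#'   `age`, `site`, `label`.
#' @param ratios train/val/test proportions summing to 1.
#' @param seed RNG seed for the within-stratum shuffle.
#' @return data.frame with `subject_id`, `split`, `stratum`.
#' @export
stratified_split <- function(cohort, ratios = c(0.70, 0.15, 0.15), seed = 42) {
  tab <- if (inherits(cohort, "cohort")) cohort_table(cohort) else cohort
  if (!nrow(tab)) stop("stratified_split: empty cohort")
  stopifnot(abs(sum(ratios) - 1) < 1e-8, length(ratios) == 3)
  set.seed(seed)
  ab <- as.character(age_bin(ifelse(is.na(tab$age), 12, tab$age)))
  strata <- paste(tab$label, ab, tab$site, sep = "|")
  # merge strata smaller than 3 into the same (label, site) pool
  cnt <- table(strata)
  small <- names(cnt)[cnt < 3]
  if (length(small)) {
    message("stratified_split: merging ", length(small),
            " strata smaller than 3 across age bins")
    is_small <- strata %in% small
    strata[is_small] <- paste(tab$label[is_small], "merged",
                              tab$site[is_small], sep = "|")
  }
  split <- character(nrow(tab))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    sizes <- largest_remainder(length(idx), ratios)
    split[idx] <- rep(c("train", "val", "test"), times = sizes)
  }
  data.frame(subject_id = tab$subject_id, split = split, stratum = strata,
             stringsAsFactors = FALSE)
}

#' Serialise / restore preprocessing state as JSON
#' @param state a `preprocess_state`; @param path file path.
#' @export
write_preprocess_state <- function(state, path) {
  out <- unclass(state)
  out$feature_means <- as.list(out$feature_means)
  out$feature_sds <- as.list(out$feature_sds)
  # 17 significant digits round-trips doubles losslessly
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_preprocess_state
#' @export
read_preprocess_state <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$feature_means <- unlist(x$feature_means)
  x$feature_sds <- unlist(x$feature_sds)
  x$category_vocab <- lapply(x$category_vocab, unlist)
  structure(x, class = "preprocess_state")
}

#' Apply fitted preprocessing to a cohort
#'
#' Produces per-modality numeric matrices ready for the synthesis network
#' and the ensemble: z-scored/imputed/one-hot tabular features, filtered and
#' artifact-checked epoch-z-scored EEG (flattened), flattened imaging
#' patches, behavioural embeddings, plus a modality availability mask (EEG is
#' unavailable for subjects whose epoch was rejected).
#'
#' @param cohort a `cohort`; @param state a [fit_preprocess()] result.
#' @return list with matrices `tabular`, `eeg`, `image`, `embedding`,
#'   integer `labels`, `tokens` (list), `availability` (n x 4 logical:
#'   image, eeg, embedding, tabular), `subject_id`.
#' @export
apply_preprocess <- function(cohort, state) {
  stopifnot(inherits(cohort, "cohort"), inherits(state, "preprocess_state"))
  tab <- cohort_table(cohort)
  num_cols <- names(state$feature_means)
  cat_cols <- names(state$category_vocab)
  num_mat <- sapply(num_cols, function(cl) {
    x <- impute(tab[[cl]], cl, state)
    apply_zscore(x, state$feature_means[[cl]], state$feature_sds[[cl]])
  })
  cat_mat <- do.call(cbind, lapply(cat_cols, function(cl) {
    vals <- impute(tab[[cl]], cl, state)
    t(vapply(vals, one_hot, numeric(length(state$category_vocab[[cl]])),
             vocab = state$category_vocab[[cl]]))
  }))
  tabular <- cbind(num_mat, cat_mat)
  rownames(tabular) <- NULL

  fp <- state$eeg_filter_params
  sf <- cohort$config$eeg_sfreq
  filtered <- lapply(cohort$records, function(r)
    filter_eeg(r$eeg, sf, fp$band_low, fp$band_high, fp$notch))
  rej <- vapply(cohort$records, function(r)
    any(abs(r$eeg) > state$reject_threshold), logical(1))
  eeg <- t(vapply(filtered, function(e) {
    mu <- mean(e); s <- sqrt(mean((e - mu)^2))
    as.vector(if (s == 0) e - mu else (e - mu) / s)
  }, numeric(length(filtered[[1]]))))

  image <- t(vapply(cohort$records, function(r) as.vector(r$image_patch),
                    numeric(length(cohort$records[[1]]$image_patch))))
  embedding <- t(vapply(cohort$records, function(r) r$behavior_embedding,
                        numeric(cohort$config$embed_dim)))
  avail <- cbind(image = TRUE, eeg = !rej, embedding = TRUE, tabular = TRUE)
  list(tabular = tabular, eeg = eeg, image = image, embedding = embedding,
       labels = vapply(cohort$records, `[[`, 0L, "label"),
       tokens = lapply(cohort$records, `[[`, "behavior_tokens"),
       availability = avail,
       subject_id = vapply(cohort$records, `[[`, "", "subject_id"))
}
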