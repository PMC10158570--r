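#' Segment a recording into triplet-aligned epochs
#'
#' Cuts consecutive, non-overlapping windows of `duration` seconds (default
#' 4.5 s = 6 triplets at 1.333 Hz), each starting exactly at a triplet
#' onset. The first epoch is anchored at the first triplet onset at or after
#' the onset amplitude ramp (`exclude_ramp = TRUE`); the trailing partial
#' window is dropped.
#'
#' @param recording an `ft_recording`.
#' @param duration epoch length (s); `duration * sample_rate` must be an
#'   integer.
#' @param exclude_ramp anchor after the onset ramp (default) or at the first
#'   triplet onset.
#' @return object of class `ft_epochs`: list with `data` (channels x epochs
#'   x samples array), `sample_rate`, `duration`, `channels`, `condition`,
#'   `block`, `subject_id`.
#' @export
epoch_recording <- function(recording, duration = 4.5, exclude_ramp = TRUE) {
  stopifnot(inherits(recording, "ft_recording"))
  fs <- recording$sample_rate
  ns <- duration * fs
  if (abs(ns - round(ns)) > 1e-9) {
    abort("`duration * sample_rate` must be an integer number of samples.")
  }
  ns <- as.integer(round(ns))
  onsets <- recording$triplet_onsets
  t0 <- if (exclude_ramp) onsets[onsets >= recording$ramp_duration][1] else onsets[1]
  if (is.na(t0)) abort("No triplet onset after the ramp.")
  total_t <- ncol(recording$data) / fs
  starts <- seq(t0, total_t, by = duration)
  starts <- starts[starts + duration <= total_t + 1e-9]
  if (length(starts) == 0) abort("Recording is shorter than one epoch.")
  dat <- array(0, dim = c(nrow(recording$data), length(starts), ns))
  for (k in seq_along(starts)) {
    i0 <- round(starts[k] * fs)
    dat[, k, ] <- recording$data[, i0 + seq_len(ns)]
  }
  structure(list(
    data = dat, sample_rate = fs, duration = duration,
    channels = recording$channels, condition = recording$condition,
    block = recording$block, subject_id = recording$subject_id,
    epoch_onsets = starts
  ), class = "ft_epochs")
}

#' @export
print.ft_epochs <- function(x, ...) {
  cat(sprintf("<ft_epochs> %d epochs x %d ch x %d samples (%.2f s each)\n",
              dim(x$data)[2], dim(x$data)[1], dim(x$data)[3], x$duration))
  invisible(x)
}

#' Pool epoch sets
#'
#' Concatenates epoch sets (e.g. the three exposure blocks of one condition)
#' along the epoch dimension. Channel count, sample rate and duration must
#' match.
#'
#' @param epoch_list list of `ft_epochs`.
#' @return a single `ft_epochs` with `block = NA`.
#' @export
combine_epochs <- function(epoch_list) {
  stopifnot(length(epoch_list) >= 1,
            all(vapply(epoch_list, inherits, TRUE, "ft_epochs")))
  ref <- epoch_list[[1]]
  for (e in epoch_list[-1]) {
    if (e$sample_rate != ref$sample_rate || e$duration != ref$duration ||
        dim(e$data)[1] != dim(ref$data)[1]) {
      abort("Epoch sets to combine must share channels, sample rate and duration.")
    }
  }
  dats <- lapply(epoch_list, `[[`, "data")
  total <- sum(vapply(dats, function(d) dim(d)[2], 0L))
  out <- array(0, dim = c(dim(ref$data)[1], total, dim(ref$data)[3]))
  at <- 0L
  for (d in dats) {
    out[, at + seq_len(dim(d)[2]), ] <- d
    at <- at + dim(d)[2]
  }
  ref$data <- out
  ref$block <- NA_integer_
  ref$epoch_onsets <- NULL
  ref
}

# Hann-tapered DFT of every epoch at all bins: returns complex array
# channels x epochs x bins (only bins `keep`)
epoch_spectra <- function(epochs, keep) {
  d <- epochs$data
  nc <- dim(d)[1]; ne <- dim(d)[2]; ns <- dim(d)[3]
  w <- hann_taper(ns)
  # mvfft works column-wise: reshape to samples x (channels*epochs)
  flat <- matrix(aperm(d, c(3, 1, 2)), nrow = ns) * w
  sp <- mvfft(flat)[keep, , drop = FALSE]
  array(t(sp), dim = c(nc, ne, length(keep)))
}

#' Inter-trial phase coherence spectrum
#'
#' For each channel and DFT bin in `[fmin, fmax]`: Hann-taper each epoch,
#' take the DFT, extract the phase `phi_k`, and return
#' `|1/N sum_k exp(i phi_k)|` (the resultant length of the unit phase
#' vectors). Values lie in `[0, 1]`: 0 for uniformly random phase, 1 for
#' perfect phase locking. If a bin's amplitude is exactly zero in some epoch
#' the phase is undefined; that epoch is excluded from that bin (with a
#' warning) and N adjusted.
#'
#' @param epochs an `ft_epochs` with at least 2 epochs.
#' @param fmin,fmax analysis band (Hz), default 0.3-6 Hz.
#' @return object of class `ft_itpc`: list with `values` (channels x
#'   frequencies matrix in `[0, 1]`), `freqs` (exact DFT bins), `n_epochs`,
#'   `channels`, `condition`, `block`, `subject_id`.
#' @export
compute_itpc <- function(epochs, fmin = 0.3, fmax = 6) {
  stopifnot(inherits(epochs, "ft_epochs"))
  ne <- dim(epochs$data)[2]
  if (ne < 2) abort("ITPC needs at least 2 epochs.")
  if (!all(is.finite(epochs$data))) abort("Epoch data must be finite.")
  ns <- dim(epochs$data)[3]
  freqs <- dft_freqs(ns, epochs$sample_rate)
  keep <- which(freqs >= fmin - 1e-9 & freqs <= fmax + 1e-9)
  sp <- epoch_spectra(epochs, keep)
  amp <- Mod(sp)
  zero <- amp == 0
  if (any(zero)) {
    warn(sprintf("%d epoch x bin cells had exactly zero amplitude; excluded from ITPC.",
                 sum(zero)))
  }
  unit <- sp / ifelse(zero, 1, amp)
  unit[zero] <- 0
  n_eff <- ne - apply(zero, c(1, 3), sum)
  # clamp away floating-point overshoot at perfect phase locking
  values <- pmin(Mod(apply(unit, c(1, 3), sum)) / pmax(n_eff, 1), 1)
  values[n_eff == 0] <- NA_real_
  dimnames(values) <- list(epochs$channels$label, NULL)
  structure(list(
    values = values, freqs = freqs[keep], n_epochs = ne,
    channels = epochs$channels, condition = epochs$condition,
    block = epochs$block, subject_id = epochs$subject_id
  ), class = "ft_itpc")
}

#' @export
print.ft_itpc <- function(x, ...) {
  cat(sprintf("<ft_itpc> %d ch x %d bins (%.3f-%.3f Hz), N = %d epochs\n",
              nrow(x$values), ncol(x$values), min(x$freqs), max(x$freqs),
              x$n_epochs))
  invisible(x)
}

#' The four frequencies of interest
#'
#' Word rate 1.333 Hz, first harmonic 2.667 Hz, syllable rate 4 Hz, third
#' harmonic 5.333 Hz — all integer multiples of the 4.5 s epoch's bin
#' spacing (1/4.5 Hz; bin indices 6, 12, 18, 24). `direction` is the a
#' priori sign of the language-minus-baseline effect (+ at word-related
#' frequencies, - at the syllable rate).
#'
#' @return tibble with columns `foi`, `freq`, `direction`, `word_related`.
#' @export
foi_set <- function() {
  tibble::tibble(
    foi = c("word_rate", "first_harmonic", "syllable_rate", "third_harmonic"),
    freq = c(6, 12, 18, 24) / 4.5,
    direction = c(1, 1, -1, 1),
    word_related = c(TRUE, TRUE, FALSE, TRUE)
  )
}

match_foi_bins <- function(freqs, foi_freqs, tol = 1e-6) {
  idx <- vapply(foi_freqs, function(f) {
    i <- which.min(abs(freqs - f))
    if (abs(freqs[i] - f) > tol) {
      abort(sprintf(
        "FOI %.4f Hz is not an exact DFT bin of this epoch length (nearest bin %.4f Hz).",
        f, freqs[i]))
    }
    i
  }, 0L)
  idx
}

#' Electrode-averaged ITPC at the frequencies of interest
#'
#' @param itpc an `ft_itpc`.
#' @param fois tibble from [foi_set()] (or a subset of it).
#' @param electrodes `NULL` for all electrodes, or a character vector of
#'   labels (e.g. the significant-cluster subset).
#' @return tibble with columns `foi`, `freq`, `itpc` (mean over the
#'   requested electrodes at the exact FOI bin), plus the itpc metadata
#'   columns `subject_id`, `condition`, `block`, `n_epochs`.
#' @export
foi_summary <- function(itpc, fois = foi_set(), electrodes = NULL) {
  stopifnot(inherits(itpc, "ft_itpc"))
  idx <- match_foi_bins(itpc$freqs, fois$freq)
  rows <- if (is.null(electrodes)) seq_len(nrow(itpc$values)) else {
    m <- match(electrodes, itpc$channels$label)
    if (anyNA(m)) abort("Unknown electrode label in `electrodes`.")
    m
  }
  vals <- colMeans(itpc$values[rows, idx, drop = FALSE])
  meta <- itpc[c("subject_id", "condition", "block", "n_epochs")]
  tibble::tibble(
    foi = fois$foi, freq = fois$freq, itpc = vals,
    subject_id = meta$subject_id %||% NA_character_,
    condition = meta$condition %||% NA_character_,
    block = meta$block %||% NA_integer_,
    n_epochs = meta$n_epochs
  )
}
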