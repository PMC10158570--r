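#' Evoked-response kernels
#'
#' The syllable kernel is a single-cycle damped sinusoid of 80 ms; the word
#' kernel is a slower biphasic deflection of 300 ms. These produce clean
#' spectral peaks at the tagged frequencies (4 Hz and 1.333 Hz plus
#' harmonics) without claiming physiological realism.
#'
#' @param sample_rate sampling rate (Hz).
#' @return numeric vector of kernel samples.
#' @keywords internal
#' @name evoked_kernels
syllable_kernel <- function(sample_rate) {
  t <- seq(0, 0.08, by = 1 / sample_rate)
  sin(2 * pi * t / 0.08) * exp(-t / 0.03)
}

#' @rdname evoked_kernels
#' @keywords internal
word_kernel <- function(sample_rate) {
  t <- seq(0, 0.3, by = 1 / sample_rate)
  sin(2 * pi * t / 0.3) * sin(pi * t / 0.3)
}

#' Spectrally shaped (1/f) Gaussian noise
#'
#' White Gaussian noise shaped in the frequency domain so that power falls as
#' `1/f^exponent`, rescaled to unit standard deviation.
#'
#' @param n number of samples.
#' @param exponent spectral slope (power); 0 gives white noise.
#' @param sample_rate sampling rate (Hz), used only for the frequency axis.
#' @return numeric vector of length `n` with sd 1.
#' @export
pink_noise <- function(n, exponent = 1, sample_rate = 1) {
  w <- rnorm(n)
  if (exponent == 0) return(w)
  f <- dft_freqs(n, sample_rate)
  # two-sided amplitude shaping, DC removed
  f_fold <- pmin(f, sample_rate - f)
  amp <- c(0, f_fold[-1]^(-exponent / 2))
  x <- Re(fft(fft(w) * amp, inverse = TRUE)) / n
  x / sd(x)
}

#' Simulate a multi-channel EEG recording for one stream
#'
#' Signal model: a 4 Hz syllable-locked evoked component (syllable-onset
#' impulse train, weighted by each syllable's envelope amplitude, convolved
#' with the syllable kernel), plus a word-rate component at triplet onsets
#' (amplitude `kappa + lambda` in the language condition, `kappa` in the
#' baseline) convolved with the word kernel, plus `1/f` noise of scale
#' `noise_sigma` with a shared across-channel component. Components are
#' scaled per channel by fixed Gaussian topographies (word-rate mid-central,
#' syllable-rate mid-frontal). The stimulus amplitude ramp multiplies the
#' evoked impulse weights.
#'
#' @param stream an [ft_stream].
#' @param profile one-row tibble (or list) of subject parameters as produced
#'   by [sample_cohort()].
#' @param montage electrode layout tibble ([make_montage()]).
#' @param sample_rate sampling rate (Hz); 0.25 s and 0.75 s must be integer
#'   sample counts (default 256).
#' @param seed integer seed for the noise.
#' @param block block number stored in the recording metadata.
#' @param topography `"default"` for the Gaussian maps, `"uniform"` for equal
#'   weights on all channels.
#' @param shared_noise_fraction variance fraction of the noise shared across
#'   channels.
#' @return object of class `ft_recording`: list with `data` (channels x
#'   samples matrix, arbitrary units), `sample_rate`, `channels` (montage
#'   tibble), `triplet_onsets`, `ramp_duration`, `subject_id`, `condition`,
#'   `block`.
#' @export
simulate_eeg <- function(stream, profile, montage = make_montage(),
                         sample_rate = 256, seed = 1L, block = 1L,
                         topography = c("default", "uniform"),
                         shared_noise_fraction = 0.3) {
  stopifnot(inherits(stream, "ft_stream"))
  topography <- match.arg(topography)
  if (nrow(stream) == 0) abort("Empty stream.")
  if (abs(0.25 * sample_rate - round(0.25 * sample_rate)) > 1e-9 ||
      abs(0.75 * sample_rate - round(0.75 * sample_rate)) > 1e-9) {
    abort("`sample_rate` must make 0.25 s and 0.75 s integer sample counts.")
  }
  profile <- as.list(profile)
  n_ch <- nrow(montage)
  n_samp <- round(0.75 * n_triplets(stream) * sample_rate)
  lex <- attr(stream, "lexicon")
  ramp <- attr(stream, "ramp_duration")

  ramp_gain <- rep(1, n_samp)
  if (ramp > 0) {
    nr <- min(round(ramp * sample_rate), n_samp)
    ramp_gain[seq_len(nr)] <- seq(0, 1, length.out = nr)
    ramp_gain[n_samp - nr + seq_len(nr)] <- seq(1, 0, length.out = nr)
  }

  # impulse trains (ramp-scaled)
  syl_amp <- lex$syllables$amplitude[match(stream$syllable, lex$syllables$id)]
  syl_idx <- round(stream$onset * sample_rate) + 1L
  imp_syl <- numeric(n_samp)
  imp_syl[syl_idx] <- syl_amp * ramp_gain[syl_idx]
  trip_idx <- round(triplet_onsets(stream) * sample_rate) + 1L
  imp_word <- numeric(n_samp)
  word_gain <- profile$kappa +
    profile$lambda * (stream$condition[1] == "language")
  imp_word[trip_idx] <- word_gain * ramp_gain[trip_idx]

  conv_trunc <- function(imp, kern) {
    convolve(imp, rev(kern), type = "open")[seq_len(n_samp)]
  }
  sig_syl <- profile$syllable_gain * conv_trunc(imp_syl, syllable_kernel(sample_rate))
  sig_word <- conv_trunc(imp_word, word_kernel(sample_rate))

  topo <- if (topography == "uniform") {
    list(word = rep(1, n_ch), syllable = rep(1, n_ch))
  } else {
    default_topographies(montage)
  }

  data <- outer(topo$syllable, sig_syl) + outer(topo$word, sig_word)
  if (profile$noise_sigma > 0) {
    noise <- withr::with_seed(as.integer(seed), {
      shared <- pink_noise(n_samp, profile$noise_exponent, sample_rate)
      indep <- vapply(seq_len(n_ch), function(i) {
        pink_noise(n_samp, profile$noise_exponent, sample_rate)
      }, numeric(n_samp))
      sqrt(shared_noise_fraction) * matrix(shared, n_ch, n_samp, byrow = TRUE) +
        sqrt(1 - shared_noise_fraction) * t(indep)
    })
    data <- data + profile$noise_sigma * noise
  }
  rownames(data) <- montage$label

  structure(list(
    data = data,
    sample_rate = sample_rate,
    channels = montage,
    triplet_onsets = triplet_onsets(stream),
    ramp_duration = ramp,
    subject_id = profile$subject_id %||% "sub-01",
    condition = stream$condition[1],
    block = as.integer(block)
  ), class = "ft_recording")
}

#' @export
print.ft_recording <- function(x, ...) {
  cat(sprintf("<ft_recording> %s / %s block %d: %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$condition, x$block, nrow(x$data),
              ncol(x$data), x$sample_rate))
  invisible(x)
}
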