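#' Syllable envelope kernel
#'
#' Gamma-shaped attack-decay curve: rises as a power law with exponent
#' `attack / decay`, peaks at `amplitude` exactly `attack` seconds after
#' syllable onset, then decays exponentially with time constant `decay`.
#' Each syllable contributes only within its own 250 ms slot.
#'
#' @param t time since syllable onset (s), vector.
#' @param attack,decay,amplitude kernel parameters (s, s, dimensionless).
#' @keywords internal
envelope_kernel <- function(t, attack, decay, amplitude) {
  k <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  k[pos] <- amplitude * (tp / attack)^(attack / decay) * exp(-(tp - attack) / decay)
  k
}

#' Synthesize the amplitude envelope of a stream
#'
#' Each syllable contributes its envelope kernel in its 250 ms slot; a linear
#' amplitude ramp of the stream's `ramp_duration` is applied multiplicatively
#' at the start and end. Total length is `n_triplets * 0.75 s`.
#'
#' @param stream an [ft_stream].
#' @param sample_rate sampling rate (Hz), `>= 100`.
#' @return numeric vector of class `ft_envelope` with attributes
#'   `sample_rate` and `ramp_duration`.
#' @export
synthesize_envelope <- function(stream, sample_rate = 1000) {
  stopifnot(inherits(stream, "ft_stream"))
  check_scalar_number(sample_rate, "sample_rate", lower = 100)
  lex <- attr(stream, "lexicon")
  if (any(lex$syllables$attack >= 0.25)) {
    abort("Envelope kernel attack time must be shorter than the 250 ms syllable slot.")
  }
  n_slot <- round(0.25 * sample_rate)
  n_total <- round(0.75 * n_triplets(stream) * sample_rate)
  env <- numeric(n_total)
  t_slot <- (seq_len(n_slot) - 1) / sample_rate
  # all 18 kernels precomputed once, then placed per syllable slot
  kern <- lapply(seq_len(18), function(i) {
    envelope_kernel(t_slot, lex$syllables$attack[i], lex$syllables$decay[i],
                    lex$syllables$amplitude[i])
  })
  names(kern) <- lex$syllables$id
  for (i in seq_len(nrow(stream))) {
    i0 <- round(stream$onset[i] * sample_rate)
    env[i0 + seq_len(n_slot)] <- kern[[stream$syllable[i]]]
  }
  ramp <- attr(stream, "ramp_duration")
  if (ramp > 0) {
    nr <- min(round(ramp * sample_rate), n_total)
    up <- seq(0, 1, length.out = nr)
    env[seq_len(nr)] <- env[seq_len(nr)] * up
    env[n_total - nr + seq_len(nr)] <- env[n_total - nr + seq_len(nr)] * rev(up)
  }
  structure(env, class = "ft_envelope", sample_rate = sample_rate,
            ramp_duration = ramp)
}

#' Modulation spectrum of an amplitude envelope
#'
#' Welch-style average of Hann-windowed magnitude spectra over segments with
#' 50% overlap, per-segment DC removal, power normalised to unit sum over
#' 0-10 Hz. With the default 15 s segments the word-rate frequencies 1.333,
#' 2.667, 4 and 5.333 Hz fall on exact bins (k/15 Hz, k = 20, 40, 60, 80).
#' Segment placement starts after the onset ramp and stops before the
#' closing ramp.
#'
#' @param envelope an `ft_envelope` (or plain numeric vector).
#' @param sample_rate sampling rate (Hz); taken from the envelope attribute
#'   when present.
#' @param segment_length Welch segment length (s).
#' @return tibble of class `ft_modspec` with columns `freq` (Hz) and `power`,
#'   plus attributes `segment_length` and `n_segments`.
#' @export
modulation_spectrum <- function(envelope, sample_rate = NULL, segment_length = 15) {
  sample_rate <- sample_rate %||% attr(envelope, "sample_rate")
  check_scalar_number(sample_rate, "sample_rate", lower = 1)
  check_scalar_number(segment_length, "segment_length", lower = 1e-3)
  ramp <- attr(envelope, "ramp_duration") %||% 0
  x <- as.numeric(envelope)
  nseg <- round(segment_length * sample_rate)
  i0 <- round(ramp * sample_rate)             # first usable sample (0-based)
  i1 <- length(x) - round(ramp * sample_rate) # last usable sample
  if (i1 - i0 < nseg) abort("Envelope is shorter than one segment (after ramp exclusion).")
  step <- floor(nseg / 2)
  starts <- seq(i0, i1 - nseg, by = step)
  w <- hann_taper(nseg)
  mag <- matrix(0, nseg, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j] + seq_len(nseg)]
    seg <- (seg - mean(seg)) * w
    mag[, j] <- Mod(fft(seg))
  }
  freq <- dft_freqs(nseg, sample_rate)
  keep <- freq <= 10 & seq_along(freq) <= nseg / 2
  power <- rowMeans(mag)[keep]
  if (sum(power) > 0) power <- power / sum(power)
  structure(tibble::tibble(freq = freq[keep], power = power),
            class = c("ft_modspec", class(tibble::tibble())),
            segment_length = segment_length, n_segments = length(starts))
}

#' Screen candidate lexica by word-rate acoustic power
#'
#' For each candidate lexicon, generates a language stream, synthesizes its
#' envelope and sums modulation-spectrum power at the word-rate bins (1.333,
#' 2.667 and 5.333 Hz). Candidates are ranked ascending (smallest word-rate
#' acoustic confound first); ties are broken by candidate index.
#'
#' @param candidates list of `ft_lexicon` objects (at least 2).
#' @param n_triplets stream length used for the audit.
#' @param seed integer seed (one stream per candidate, common seed).
#' @param sample_rate envelope sampling rate (Hz).
#' @return tibble with columns `candidate`, `word_rate_power`, `rank`,
#'   ordered by rank.
#' @export
screen_lexicon_candidates <- function(candidates, n_triplets = 512, seed = 1L,
                                      sample_rate = 600) {
  if (length(candidates) < 2) abort("Need at least 2 candidate lexica.")
  stopifnot(all(vapply(candidates, inherits, TRUE, "ft_lexicon")))
  word_bins <- c(4 / 3, 8 / 3, 16 / 3)
  pow <- vapply(seq_along(candidates), function(i) {
    stream <- generate_language_stream(candidates[[i]], n_triplets, seed = seed)
    ms <- modulation_spectrum(synthesize_envelope(stream, sample_rate))
    idx <- vapply(word_bins, function(f) which.min(abs(ms$freq - f)), 0L)
    sum(ms$power[idx])
  }, 0)
  ord <- order(pow, seq_along(pow))
  tibble::tibble(candidate = ord, word_rate_power = pow[ord],
                 rank = seq_along(ord))
}
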