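# Shared fixtures, all built in code.

# small ring montage for fast simulation tests
tiny_montage <- function(n = 8) {
  theta <- pi / 2 + 2 * pi * (seq_len(n - 1) - 1) / (n - 1)
  tibble::tibble(
    label = paste0("T", seq_len(n)),
    x = c(0, 0.8 * cos(theta)),
    y = c(0, 0.8 * sin(theta)))
}

quick_profile <- function(lambda = 0, kappa = 0, noise_sigma = 0,
                          syllable_gain = 1, subject_id = "sub-01") {
  tibble::tibble(subject_id = subject_id, lambda = lambda, kappa = kappa,
                 syllable_gain = syllable_gain, noise_sigma = noise_sigma,
                 noise_exponent = 1, p2afc = 0.5, rt_effect = 0,
                 hit_effect = 0)
}

# an ft_epochs built directly from a channels x epochs x samples array
make_epochs <- function(data, sample_rate, duration = dim(data)[3] / sample_rate,
                        labels = paste0("ch", seq_len(dim(data)[1]))) {
  structure(list(
    data = data, sample_rate = sample_rate, duration = duration,
    channels = tibble::tibble(label = labels,
                              x = seq(0, 1, length.out = dim(data)[1]),
                              y = 0),
    condition = "language", block = 1L, subject_id = "sub-01"
  ), class = "ft_epochs")
}

# white-noise epoch set at an epoch length whose DFT grid contains the FOIs
noise_epochs <- function(n_ch = 1, n_ep = 20, fs = 64, duration = 4.5,
                         seed = 1) {
  withr::with_seed(seed, {
    make_epochs(array(rnorm(n_ch * n_ep * fs * duration),
                      dim = c(n_ch, n_ep, fs * duration)), fs, duration)
  })
}

# condition pair of simulated multi-block epoch sets for one subject
simulate_subject_epochs <- function(profile, lexicon = build_lexicon(),
                                    montage = tiny_montage(),
                                    n_triplets = 64, n_blocks = 2,
                                    sample_rate = 64, seed = 1) {
  seeds <- child_seeds(seed, 2 * n_blocks + 2)
  lang <- lapply(seq_len(n_blocks), function(b) {
    st <- generate_language_stream(lexicon, n_triplets, seed = seeds[b])
    epoch_recording(simulate_eeg(st, profile, montage, sample_rate,
                                 seed = seeds[n_blocks + b], block = b))
  })
  base <- lapply(seq_len(n_blocks), function(b) {
    bs <- generate_baseline_stream(lexicon, n_triplets,
                                   seed = seeds[2 * n_blocks + 1] + b)
    epoch_recording(simulate_eeg(bs, profile, montage, sample_rate,
                                 seed = seeds[2 * n_blocks + 2] + b, block = b))
  })
  list(language = combine_epochs(lang), baseline = combine_epochs(base))
}
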