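lex <- build_lexicon()

test_that("epoching count follows the post-ramp direct count and boundary rules", {
  # 256 triplets, 5 s ramps: first post-ramp triplet onset is 5.25 s
  # (index 7, 0-based), leaving 249 triplets -> floor(249 / 6) = 41 epochs
  st <- generate_language_stream(lex, 256, seed = 1)
  rec <- simulate_eeg(st, quick_profile(), tiny_montage(), 64, seed = 1)
  ep <- epoch_recording(rec)
  onsets <- rec$triplet_onsets
  usable <- sum(onsets >= 5)
  expect_equal(dim(ep$data)[2], floor(usable / 6))
  expect_equal(dim(ep$data)[2], 41)
  expect_equal(ep$epoch_onsets[1], 5.25)
  expect_equal(diff(ep$epoch_onsets), rep(4.5, 40))
  # without ramp exclusion: floor(256 / 6) = 42
  expect_equal(dim(epoch_recording(rec, exclude_ramp = FALSE)$data)[2], 42)

  # one-epoch boundary: a 4.5 s ramp-free recording gives exactly 1 epoch
  st6 <- generate_language_stream(lex, 6, seed = 1, ramp_duration = 0)
  rec6 <- simulate_eeg(st6, quick_profile(), tiny_montage(), 64, seed = 1)
  expect_equal(dim(epoch_recording(rec6)$data)[2], 1)
  # 4.0 s (< one epoch) errors
  st5 <- generate_language_stream(lex, 5, seed = 1, ramp_duration = 0)
  rec5 <- simulate_eeg(st5, quick_profile(), tiny_montage(), 64, seed = 1)
  expect_error(epoch_recording(rec5), "shorter than one epoch")
  expect_error(epoch_recording(rec6, duration = 4.51), "integer")
})

test_that("ITPC is 1 for identical epochs and 0 for antipodal phases", {
  fs <- 64
  n <- 4.5 * fs
  sig <- withr::with_seed(13, sin(2 * pi * 2 * (0:(n - 1)) / fs) + 0.5 * rnorm(n))
  # dim (channel, epoch, sample): epoch index varies fastest within a sample
  same <- make_epochs(array(rep(sig, each = 12), dim = c(1, 12, n)), fs)
  # identical epochs share phases exactly at every bin
  it <- compute_itpc(same)
  expect_true(all(it$values >= 0 & it$values <= 1))
  expect_equal(as.vector(it$values), rep(1, ncol(it$values)), tolerance = 1e-9)

  # two epochs with opposite sign have antipodal phases at every bin
  anti <- make_epochs(array(as.vector(rbind(sig, -sig)), dim = c(1, 2, n)), fs)
  it2 <- compute_itpc(anti)
  expect_lt(max(it2$values), 1e-9)
})

test_that("uniform-phase ITPC matches the sqrt(pi) / (2 sqrt(N)) expectation", {
  ep <- noise_epochs(n_ch = 1, n_ep = 1000, fs = 64, seed = 33)
  it <- compute_itpc(ep)
  nbins <- ncol(it$values)
  expected <- sqrt(pi) / (2 * sqrt(1000))
  # sd of the resultant length of N uniform phasors is sqrt((4 - pi) / (4 N))
  se <- sqrt((4 - pi) / (4 * 1000) / nbins)
  expect_lt(abs(mean(it$values) - expected), 3 * se)
})

test_that("ITPC is invariant to epoch order and pools by complex-sum conservation", {
  ep <- noise_epochs(n_ch = 2, n_ep = 16, fs = 64, seed = 5)
  perm <- withr::with_seed(7, sample(16))
  shuf <- ep
  shuf$data <- ep$data[, perm, , drop = FALSE]
  expect_equal(compute_itpc(shuf)$values, compute_itpc(ep)$values,
               tolerance = 1e-12)

  # N * R(full) resultant vector equals the sum of the two half resultants
  fois <- foi_set()
  P <- freqtagsl:::foi_phasors(ep, fois)     # epochs x ch x foi
  full <- apply(P, c(2, 3), sum)
  halves <- apply(P[1:8, , , drop = FALSE], c(2, 3), sum) +
    apply(P[9:16, , , drop = FALSE], c(2, 3), sum)
  expect_equal(full, halves, tolerance = 1e-12)
})

test_that("FOI summary uses exact bins and errors on a bin mismatch", {
  fois <- foi_set()
  expect_equal(fois$freq * 4.5, c(6, 12, 18, 24), tolerance = 1e-12)
  ep <- noise_epochs(n_ch = 3, n_ep = 6, fs = 64, seed = 2)
  it <- compute_itpc(ep)
  s <- foi_summary(it)
  idx <- vapply(fois$freq, function(f) which.min(abs(it$freqs - f)), 0L)
  expect_equal(s$itpc, colMeans(it$values[, idx]))
  s1 <- foi_summary(it, electrodes = "ch2")
  expect_equal(s1$itpc, unname(it$values[2, idx]))
  # a 4 s epoch cannot represent 1.333 Hz exactly
  ep4 <- noise_epochs(n_ch = 1, n_ep = 4, fs = 64, duration = 4, seed = 3)
  expect_error(foi_summary(compute_itpc(ep4)), "not an exact DFT bin")
  expect_error(foi_summary(it, electrodes = "nope"), "Unknown electrode")
})

test_that("compute_itpc enforces its preconditions and flags zero-amplitude bins", {
  ep1 <- noise_epochs(n_ep = 1)
  expect_error(compute_itpc(ep1), "at least 2")
  bad <- noise_epochs(n_ep = 4)
  bad$data[1, 2, 3] <- NA
  expect_error(compute_itpc(bad), "finite")
  # an all-zero epoch has zero amplitude at every bin -> excluded with warning
  zeroed <- noise_epochs(n_ch = 1, n_ep = 4, seed = 9)
  zeroed$data[1, 2, ] <- 0
  expect_warning(itz <- compute_itpc(zeroed), "zero amplitude")
  manual <- compute_itpc(make_epochs(zeroed$data[, -2, , drop = FALSE], 64))
  expect_equal(itz$values, manual$values, tolerance = 1e-12)
})

test_that("a learning gain raises word-rate ITPC in language over baseline across seeds", {
  fois <- foi_set()
  word <- which(fois$word_related)
  diffs_lambda <- c(); diffs_null <- c()
  for (s in 1:20) {
    prof <- quick_profile(lambda = 2.5, kappa = 0.4, noise_sigma = 4)
    eps <- simulate_subject_epochs(prof, lex, n_triplets = 48, n_blocks = 1,
                                   seed = s)
    sl <- foi_summary(compute_itpc(eps$language), fois)
    sb <- foi_summary(compute_itpc(eps$baseline), fois)
    diffs_lambda[s] <- mean(sl$itpc[word] - sb$itpc[word])
    prof0 <- quick_profile(lambda = 0, kappa = 0.4, noise_sigma = 4)
    eps0 <- simulate_subject_epochs(prof0, lex, n_triplets = 48, n_blocks = 1,
                                    seed = 100 + s)
    sl0 <- foi_summary(compute_itpc(eps0$language), fois)
    sb0 <- foi_summary(compute_itpc(eps0$baseline), fois)
    diffs_null[s] <- mean(sl0$itpc[word] - sb0$itpc[word])
  }
  # language > baseline at the word-related frequencies when lambda > 0
  # (one-sided Mann-Whitney over independent simulated subjects)
  expect_lt(wilcox.test(diffs_lambda, diffs_null, alternative = "greater")$p.value,
            0.01)
  # and the kappa-only confound is condition-balanced
  expect_gt(t.test(diffs_null)$p.value, 0.01)
})

test_that("ITPC spectra roundtrip through TSV + sidecar", {
  ep <- noise_epochs(n_ch = 3, n_ep = 5, seed = 11)
  it <- compute_itpc(ep)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_itpc(it, path)
  back <- read_itpc(path)
  expect_equal(back$values, it$values, tolerance = 1e-12)
  expect_equal(back$freqs, it$freqs, tolerance = 1e-12)
  expect_equal(back$n_epochs, it$n_epochs)
})
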