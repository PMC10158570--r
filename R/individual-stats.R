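# unit phasors of each epoch at the FOI bins: complex array
# epochs x channels x FOIs (the sufficient statistic for all
# epoch-exchange permutation tests, far smaller than the epochs themselves)
foi_phasors <- function(epochs, fois) {
  ns <- dim(epochs$data)[3]
  freqs <- dft_freqs(ns, epochs$sample_rate)
  bins <- match_foi_bins(freqs, fois$freq)
  sp <- epoch_spectra(epochs, bins)  # ch x ep x foi
  amp <- Mod(sp)
  unit <- sp / ifelse(amp == 0, 1, amp)
  aperm(unit, c(2, 1, 3))
}

# electrode-averaged ITPC per FOI from an (epochs x ch*foi) phasor matrix
itpc_from_phasors <- function(P, idx, n_ch, n_foi) {
  r <- Mod(colMeans(P[idx, , drop = FALSE]))
  colMeans(matrix(r, n_ch, n_foi))
}

# core permutation engine on phasor arrays (epochs x ch x foi)
individual_permutation_phasors <- function(A1, A2, fois, n_perm, seed,
                                           subject_id = NA_character_,
                                           electrodes = NULL,
                                           channel_labels = NULL) {
  if (!is.null(electrodes)) {
    m <- match(electrodes, channel_labels)
    if (anyNA(m)) abort("Unknown electrode label in `electrodes`.")
    A1 <- A1[, m, , drop = FALSE]
    A2 <- A2[, m, , drop = FALSE]
  }
  n1 <- dim(A1)[1]; n2 <- dim(A2)[1]
  if (n1 < 4 || n2 < 4) abort("Need at least 4 epochs per condition.")
  n_ch <- dim(A1)[2]
  n_foi <- nrow(fois)
  P <- rbind(matrix(A1, n1), matrix(A2, n2))  # epochs x (ch*foi)
  idx1 <- seq_len(n1)
  idx2 <- n1 + seq_len(n2)

  obs_lang <- itpc_from_phasors(P, idx1, n_ch, n_foi)
  obs_base <- itpc_from_phasors(P, idx2, n_ch, n_foi)
  observed <- fois$direction * (obs_lang - obs_base)

  m_swap <- floor(min(n1, n2) / 2)
  null <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(n_perm), function(k) {
      sw1 <- sample(idx1, m_swap)
      sw2 <- sample(idx2, m_swap)
      new1 <- c(setdiff(idx1, sw1), sw2)
      new2 <- c(setdiff(idx2, sw2), sw1)
      fois$direction * (itpc_from_phasors(P, new1, n_ch, n_foi) -
                          itpc_from_phasors(P, new2, n_ch, n_foi))
    }, numeric(n_foi)))
  })
  p <- vapply(seq_len(n_foi), function(j) {
    (1 + sum(null[, j] >= observed[j])) / (1 + n_perm)
  }, 0)

  res <- tibble::tibble(
    foi = fois$foi, freq = fois$freq, direction = fois$direction,
    itpc_language = obs_lang, itpc_baseline = obs_base,
    observed = observed, p = p
  )
  structure(res, class = c("ft_indiv_perm", class(res)),
            null = null, subject_id = subject_id,
            electrode_set = if (is.null(electrodes)) "all" else "subset",
            n_perm = n_perm)
}

#' Per-participant condition permutation test
#'
#' Tests, within one participant, whether electrode-averaged ITPC differs
#' between the language and baseline conditions at each frequency of
#' interest. The null is built by exchanging a random half of the epochs
#' between the two conditions (an equal-sized swap of
#' `floor(min(N1, N2) / 2)` epochs each way, preserving each condition's
#' epoch count, on which ITPC depends) and recomputing the difference. One
#' tailed, with the a priori direction per FOI (+ at word-related
#' frequencies, - at the syllable rate) and the add-one p correction.
#'
#' @param lang_epochs,base_epochs `ft_epochs` for the two conditions (same
#'   channels and sample rate, >= 4 epochs each).
#' @param fois tibble from [foi_set()].
#' @param electrodes `NULL` for all electrodes or a label subset (e.g. the
#'   significant-cluster electrodes from the group analysis).
#' @param n_perm number of label exchanges.
#' @param seed integer seed.
#' @return object of class `ft_indiv_perm`: tibble with one row per FOI
#'   (`foi`, `freq`, `direction`, `itpc_language`, `itpc_baseline`,
#'   `observed` — the directed difference — and `p`), with attributes
#'   `null` (n_perm x FOI matrix of directed null differences),
#'   `subject_id`, `electrode_set`, `n_perm`.
#' @export
individual_permutation <- function(lang_epochs, base_epochs, fois = foi_set(),
                                   electrodes = NULL, n_perm = 1000,
                                   seed = 1L) {
  stopifnot(inherits(lang_epochs, "ft_epochs"), inherits(base_epochs, "ft_epochs"))
  if (dim(lang_epochs$data)[1] != dim(base_epochs$data)[1] ||
      lang_epochs$sample_rate != base_epochs$sample_rate) {
    abort("Epoch sets must share channels and sample rate.")
  }
  individual_permutation_phasors(
    foi_phasors(lang_epochs, fois), foi_phasors(base_epochs, fois),
    fois, n_perm, seed, subject_id = lang_epochs$subject_id,
    electrodes = electrodes, channel_labels = lang_epochs$channels$label)
}

#' Classify learners from individual permutation results
#'
#' A subject is flagged as showing a neural learning effect if their
#' permutation p value is at or below `alpha` at any word-related frequency
#' (1.333, 2.667 or 5.333 Hz). The reversed 4 Hz syllable-rate effect is
#' flagged separately.
#'
#' @param results list of `ft_indiv_perm` (one per subject).
#' @param alpha significance level.
#' @return object of class `ft_learner_class`: list with `subjects` tibble
#'   (`subject_id`, per-FOI p values, `n_word_fois_significant`,
#'   `learner_flag`, `syllable_flag`), `foi_counts` tibble, `n_flagged`,
#'   `n_total`, `alpha`.
#' @export
classify_learners <- function(results, alpha = 0.05) {
  stopifnot(all(vapply(results, inherits, TRUE, "ft_indiv_perm")))
  fois <- results[[1]]$foi
  word_fois <- results[[1]]$foi[results[[1]]$direction > 0]
  subjects <- purrr::map_dfr(results, function(r) {
    p <- setNames(r$p, r$foi)
    tibble::tibble(
      subject_id = attr(r, "subject_id") %||% NA_character_,
      !!!as.list(p),
      n_word_fois_significant = sum(p[word_fois] <= alpha),
      learner_flag = any(p[word_fois] <= alpha),
      syllable_flag = any(p[setdiff(fois, word_fois)] <= alpha)
    )
  })
  foi_counts <- tibble::tibble(
    foi = fois,
    n_significant = vapply(fois, function(f) {
      sum(vapply(results, function(r) r$p[r$foi == f] <= alpha, TRUE))
    }, 0L)
  )
  structure(list(subjects = subjects, foi_counts = foi_counts,
                 n_flagged = sum(subjects$learner_flag),
                 n_total = nrow(subjects), alpha = alpha),
            class = "ft_learner_class")
}

#' @export
print.ft_learner_class <- function(x, ...) {
  cat(sprintf("<ft_learner_class> %d/%d subjects significant at any word-related FOI (alpha=%.2f)\n",
              x$n_flagged, x$n_total, x$alpha))
  print(x$foi_counts)
  invisible(x)
}
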