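#' Stimulus streams
#'
#' A stimulus stream is a BIDS-events-shaped tibble (one row per syllable)
#' with columns `onset` (s), `duration` (s), `syllable`, `triplet_index`,
#' `position` (1-3) and `condition`, carrying the generating lexicon and
#' timing constants as attributes. Syllables are presented at a constant
#' 4 Hz (250 ms each), so triplets occur at 1.333 Hz (750 ms).
#'
#' @name ft_stream
NULL

new_stream <- function(triplets, lexicon, condition, ramp_duration, seed,
                       variant = NA_character_) {
  # triplets: character matrix n x 3 of syllable ids
  n <- nrow(triplets)
  syl <- as.vector(t(triplets))
  pos_of <- setNames(lexicon$syllables$position, lexicon$syllables$id)
  out <- tibble::tibble(
    onset = 0.25 * (seq_along(syl) - 1),
    duration = 0.25,
    syllable = syl,
    triplet_index = rep(seq_len(n), each = 3),
    position = unname(pos_of[syl]),
    condition = condition
  )
  structure(out,
            class = c("ft_stream", class(out)),
            lexicon = lexicon,
            syllable_duration = 0.25,
            ramp_duration = ramp_duration,
            variant = variant,
            seed = as.integer(seed))
}

#' @export
print.ft_stream <- function(x, ...) {
  cat(sprintf("<ft_stream> condition=%s, %d triplets (%.2f s), ramp %.1f s\n",
              x$condition[1], max(x$triplet_index), n_triplets(x) * 0.75,
              attr(x, "ramp_duration")))
  NextMethod()
}

n_triplets <- function(stream) max(stream$triplet_index)

#' Triplet onset times of a stream
#' @param stream an `ft_stream`.
#' @return numeric vector of onsets (s), one per triplet.
#' @export
triplet_onsets <- function(stream) {
  stream$onset[!duplicated(stream$triplet_index)]
}

stream_triplet_matrix <- function(stream) {
  matrix(stream$syllable, ncol = 3, byrow = TRUE)
}

#' Generate an artificial-language stream
#'
#' Concatenates the six pseudowords into a 4 Hz syllable stream with
#' within-word transitional probability 1 and between-word transitional
#' probability 0.2 (next word drawn among the 5 other words). Words are
#' scheduled in shuffled blocks of six so counts stay balanced to within
#' +/- 1 over the stream, immediate repetition of the same word is forbidden,
#' and the distribution over time is even.
#'
#' @param lexicon an `ft_lexicon`.
#' @param n_triplets number of triplets (words) to emit, `>= 1`.
#' @param seed integer seed.
#' @param ramp_duration linear amplitude ramp applied at stream start and end
#'   during envelope synthesis (s); also marks the region excluded from
#'   epoching and empirical transition counts.
#' @return an [ft_stream] tibble.
#' @export
generate_language_stream <- function(lexicon, n_triplets, seed = 1L,
                                     ramp_duration = 5) {
  stopifnot(inherits(lexicon, "ft_lexicon"))
  check_scalar_number(n_triplets, "n_triplets", lower = 1)
  n_triplets <- as.integer(n_triplets)
  pw <- lexicon$pseudowords
  idx <- withr::with_seed(as.integer(seed), {
    n_blocks <- ceiling(n_triplets / 6)
    out <- integer(0)
    for (b in seq_len(n_blocks)) {
      repeat {
        blk <- sample.int(6)
        if (length(out) == 0 || blk[1] != out[length(out)]) break
      }
      out <- c(out, blk)
    }
    out[seq_len(n_triplets)]
  })
  trip <- as.matrix(pw[idx, c("s1", "s2", "s3")])
  new_stream(trip, lexicon, "language", ramp_duration, seed)
}

#' Generate a position-controlled baseline stream
#'
#' Every triplet uses one position-1, one position-2 and one position-3
#' syllable in order, matching the language stream's positional acoustics
#' while destroying the word structure. Two variants:
#' \describe{
#'   \item{`tp02`}{each transition is drawn uniformly from exactly 5 of the 6
#'     position-legal successors (transitional probability 0.2): within a
#'     triplet the successor that would reproduce the original pseudoword
#'     bigram is excluded; across a triplet boundary the initial syllable of
#'     the triplet just completed is excluded, which also forbids immediate
#'     triplet repetition.}
#'   \item{`all_combinations`}{uniform over all 6 successors (design TP 1/6);
#'     a triplet identical to its predecessor is redrawn.}
#' }
#'
#' @inheritParams generate_language_stream
#' @param variant `"tp02"` (default) or `"all_combinations"`.
#' @return an [ft_stream] tibble.
#' @export
generate_baseline_stream <- function(lexicon, n_triplets, seed = 1L,
                                     variant = c("tp02", "all_combinations"),
                                     ramp_duration = 5) {
  stopifnot(inherits(lexicon, "ft_lexicon"))
  check_scalar_number(n_triplets, "n_triplets", lower = 1)
  n_triplets <- as.integer(n_triplets)
  variant <- match.arg(variant)
  syl <- lexicon$syllables
  by_pos <- split(syl$id, syl$position)
  # word successor of each pos-1/pos-2 syllable (the bigram to exclude)
  pw <- lexicon$pseudowords
  word_next <- c(setNames(pw$s2, pw$s1), setNames(pw$s3, pw$s2))

  trip <- withr::with_seed(as.integer(seed), {
    out <- matrix(NA_character_, n_triplets, 3)
    if (variant == "tp02") {
      prev_first <- NULL
      for (k in seq_len(n_triplets)) {
        s1 <- if (is.null(prev_first)) sample(by_pos[[1]], 1) else
          sample(setdiff(by_pos[[1]], prev_first), 1)
        s2 <- sample(setdiff(by_pos[[2]], word_next[[s1]]), 1)
        s3 <- sample(setdiff(by_pos[[3]], word_next[[s2]]), 1)
        out[k, ] <- c(s1, s2, s3)
        prev_first <- s1
      }
    } else {
      for (k in seq_len(n_triplets)) {
        repeat {
          cand <- c(sample(by_pos[[1]], 1), sample(by_pos[[2]], 1),
                    sample(by_pos[[3]], 1))
          if (k == 1 || any(cand != out[k - 1, ])) break
        }
        out[k, ] <- cand
      }
    }
    out
  })
  new_stream(trip, lexicon, "baseline", ramp_duration, seed, variant = variant)
}

#' Transition matrix of a stream
#'
#' @param stream an [ft_stream].
#' @param mode `"empirical"`: bigram counts normalised per row, or
#'   `"design"`: the exact conditional probabilities implied by the
#'   generator. For the baseline `tp02` variant the between-triplet exclusion
#'   depends on the previous triplet's first syllable, so the design entries
#'   for position-3 to position-1 transitions are the probability conditional
#'   on the successor being available (exactly 5 of the 6 are, each 0.2);
#'   this is flagged in the `context_dependent` attribute.
#' @param exclude_ramp drop syllables inside the start/end amplitude ramps
#'   before counting (empirical mode).
#' @return an 18 x 18 row-stochastic matrix with syllable-id dimnames, class
#'   `ft_tpm`.
#' @export
transition_matrix <- function(stream, mode = c("empirical", "design"),
                              exclude_ramp = TRUE) {
  stopifnot(inherits(stream, "ft_stream"))
  mode <- match.arg(mode)
  lex <- attr(stream, "lexicon")
  ids <- lex$syllables$id
  P <- matrix(0, 18, 18, dimnames = list(ids, ids))
  context_dependent <- FALSE

  if (mode == "empirical") {
    s <- stream
    if (exclude_ramp) {
      ramp <- attr(stream, "ramp_duration")
      total <- 0.75 * n_triplets(stream)
      s <- stream[stream$onset >= ramp & stream$onset + 0.25 <= total - ramp, ]
    }
    if (nrow(s) < 2) abort("Empirical mode needs at least 2 syllables in the stream.")
    from <- s$syllable[-nrow(s)]
    to <- s$syllable[-1]
    tab <- table(factor(from, ids), factor(to, ids))
    n <- rowSums(tab)
    P[n > 0, ] <- tab[n > 0, ] / n[n > 0]
  } else {
    pw <- lex$pseudowords
    if (stream$condition[1] == "language") {
      for (i in seq_len(6)) {
        P[pw$s1[i], pw$s2[i]] <- 1
        P[pw$s2[i], pw$s3[i]] <- 1
        P[pw$s3[i], pw$s1[-i]] <- 0.2
      }
    } else if (identical(attr(stream, "variant"), "tp02")) {
      word_next <- c(setNames(pw$s2, pw$s1), setNames(pw$s3, pw$s2))
      for (i in seq_len(6)) {
        P[pw$s1[i], setdiff(pw$s2, word_next[[pw$s1[i]]])] <- 0.2
        P[pw$s2[i], setdiff(pw$s3, word_next[[pw$s2[i]]])] <- 0.2
        P[pw$s3[i], pw$s1] <- 0.2   # 5 of these 6 available at any step
      }
      context_dependent <- TRUE
    } else {
      for (i in seq_len(6)) {
        P[pw$s1[i], pw$s2] <- 1 / 6
        P[pw$s2[i], pw$s3] <- 1 / 6
        P[pw$s3[i], pw$s1] <- 1 / 6
      }
    }
  }
  structure(P, class = c("ft_tpm", "matrix", "array"),
            mode = mode, context_dependent = context_dependent)
}
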