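#' The default artificial-language lexicon
#'
#' Six tri-syllabic pseudowords over 18 CV syllables, each syllable occurring
#' in exactly one pseudoword and at a fixed within-word position. This is the
#' standard word set for the 4 Hz syllable / 1.333 Hz word frequency-tagging
#' design.
#' @keywords internal
default_words <- function() {
  list(
    PaShuDi = c("Pa", "Shu", "Di"),
    SoGuMa  = c("So", "Gu", "Ma"),
    NoMuBe  = c("No", "Mu", "Be"),
    TuBiPo  = c("Tu", "Bi", "Po"),
    GeRoVa  = c("Ge", "Ro", "Va"),
    KaLeVi  = c("Ka", "Le", "Vi")
  )
}

# Fixed per-syllable envelope kernel parameters (attack s, decay s, peak
# amplitude). Authored once as the package's stand-in for the acoustic
# differences between natural CV syllables: attack 20-70 ms, decay 40-150 ms,
# amplitude within +/-15% of unity. Ordered to match the 18 syllables of the
# default lexicon read word by word.
default_kernel_table <- function() {
  tibble::tribble(
    ~attack, ~decay, ~amplitude,
    0.030, 0.110, 1.10,   # Pa
    0.065, 0.060, 0.90,   # Shu
    0.025, 0.140, 1.05,   # Di
    0.055, 0.080, 0.95,   # So
    0.040, 0.120, 1.15,   # Gu
    0.060, 0.050, 0.85,   # Ma
    0.035, 0.090, 1.00,   # No
    0.050, 0.130, 1.10,   # Mu
    0.020, 0.070, 0.90,   # Be
    0.045, 0.100, 1.05,   # Tu
    0.070, 0.040, 0.95,   # Bi
    0.030, 0.150, 1.12,   # Po
    0.055, 0.065, 0.88,   # Ge
    0.025, 0.105, 1.08,   # Ro
    0.060, 0.085, 0.92,   # Va
    0.040, 0.135, 1.02,   # Ka
    0.065, 0.055, 0.98,   # Le
    0.035, 0.115, 1.06    # Vi
  )
}

#' Build a syllable lexicon
#'
#' Constructs the lexicon used throughout the pipeline: 18 syllables
#' partitioned into 6 ordered tri-syllabic pseudowords (6 syllables per
#' within-word position), together with per-syllable envelope-kernel
#' parameters and the 6 part-word foils used by the 2AFC test.
#'
#' @param words named list of 6 character vectors of length 3 (the
#'   pseudowords), or `NULL` for the default lexicon.
#' @param kernel_heterogeneity scalar `>= 0` scaling how strongly envelope
#'   kernels differ across syllables; `0` collapses all kernels onto the mean
#'   kernel (an acoustically flat control), `1` uses the packaged table as is.
#' @param seed integer seed for part-word construction.
#' @return an object of class `ft_lexicon`: a list with tibbles `syllables`
#'   (id, position, attack, decay, amplitude), `pseudowords` (word, s1, s2,
#'   s3) and `part_words` (part_word, s1, s2, s3, template).
#' @examples
#' lex <- build_lexicon()
#' lex$pseudowords
#' @export
build_lexicon <- function(words = NULL, kernel_heterogeneity = 1, seed = 1L) {
  words <- words %||% default_words()
  check_scalar_number(kernel_heterogeneity, "kernel_heterogeneity", lower = 0)
  if (length(words) != 6 || !all(lengths(words) == 3)) {
    abort("A lexicon needs exactly 6 pseudowords of 3 syllables each.")
  }
  ids <- unlist(words, use.names = FALSE)
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "Each syllable must appear in exactly one pseudoword; duplicated: %s.",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(ids) != 18) abort("A lexicon must contain exactly 18 syllables.")
  if (is.null(names(words))) {
    names(words) <- vapply(words, paste0, "", collapse = "")
  }

  kern <- default_kernel_table()
  flat <- dplyr::summarise(kern, dplyr::across(dplyr::everything(), mean))
  h <- kernel_heterogeneity
  kern <- tibble::as_tibble(purrr::map2(kern, flat, ~ .y + h * (.x - .y)))

  syllables <- tibble::tibble(
    id = ids,
    position = rep(1:3, times = 6),
    attack = kern$attack, decay = kern$decay, amplitude = kern$amplitude
  )
  pseudowords <- tibble::tibble(
    word = names(words),
    s1 = unname(vapply(words, `[`, "", 1)),
    s2 = unname(vapply(words, `[`, "", 2)),
    s3 = unname(vapply(words, `[`, "", 3))
  )
  lex <- structure(
    list(syllables = syllables, pseudowords = pseudowords, part_words = NULL),
    class = "ft_lexicon"
  )
  lex$part_words <- generate_part_words(lex, seed = seed)
  lex
}

#' @export
print.ft_lexicon <- function(x, ...) {
  cat("<ft_lexicon> 18 syllables, 6 pseudowords:",
      paste(x$pseudowords$word, collapse = ", "), "\n")
  invisible(x)
}

#' Construct part-word foils
#'
#' Part-words span a word boundary: either the last two syllables of one
#' pseudoword followed by the first syllable of another (2+1), or the last
#' syllable of one followed by the first two of another (1+2). Three of each
#' template are produced, no part-word equals a pseudoword, and every
#' pseudoword contributes syllables to at least one part-word.
#'
#' @param lexicon an `ft_lexicon` (its `part_words` slot is ignored).
#' @param seed integer seed for the word pairing.
#' @return tibble with columns part_word, s1, s2, s3, template.
#' @export
generate_part_words <- function(lexicon, seed = 1L) {
  stopifnot(inherits(lexicon, "ft_lexicon"))
  pw <- lexicon$pseudowords
  withr::with_seed(as.integer(seed), {
    # random cyclic pairing: word i donates to part-word i, word sigma(i)
    # completes it; a cycle guarantees A != B and full coverage
    ord <- sample.int(6)
    a <- ord
    b <- ord[c(2:6, 1)]
  })
  template <- rep(c("2+1", "1+2"), each = 3)
  rows <- purrr::map2(seq_along(a), template, function(i, tpl) {
    A <- pw[a[i], ]; B <- pw[b[i], ]
    if (tpl == "2+1") c(A$s2, A$s3, B$s1) else c(A$s3, B$s1, B$s2)
  })
  tibble::tibble(
    part_word = vapply(rows, paste0, "", collapse = ""),
    s1 = vapply(rows, `[`, "", 1),
    s2 = vapply(rows, `[`, "", 2),
    s3 = vapply(rows, `[`, "", 3),
    template = template
  )
}
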