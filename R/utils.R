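#' Derive reproducible child seeds from a master seed
#'
#' All stochastic stages draw their own integer seed from the master seed so
#' that stages can be re-run in isolation and runs are reproducible end to
#' end.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Hann taper of length n (signal's periodic-symmetric "hanning" convention).
hann_taper <- function(n) {
  if (n == 1) return(1)
  as.numeric(signal::hanning(n))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# frequencies of the DFT grid for an epoch of `n` samples at `fs` Hz
dft_freqs <- function(n, fs) (seq_len(n) - 1) * fs / n
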