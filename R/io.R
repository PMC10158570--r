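#' Stream serialization (events table + JSON sidecar)
#'
#' Streams are written as BIDS-style events TSV (columns `onset`,
#' `duration`, `trial_type`, `triplet_index`, `position`, `condition`) with
#' a JSON sidecar holding the generator metadata and the lexicon, so that
#' write-then-read is the identity.
#'
#' @param stream an [ft_stream].
#' @param path TSV path; the sidecar goes to `sub(".tsv", ".json", path)`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "ft_stream"))
  ev <- tibble::tibble(
    onset = stream$onset, duration = stream$duration,
    trial_type = stream$syllable, triplet_index = stream$triplet_index,
    position = stream$position, condition = stream$condition)
  readr::write_tsv(ev, path)
  side <- list(
    syllable_duration = attr(stream, "syllable_duration"),
    ramp_duration = attr(stream, "ramp_duration"),
    variant = attr(stream, "variant"),
    seed = attr(stream, "seed"),
    lexicon = lexicon_to_list(attr(stream, "lexicon")))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  ev <- read_tsv_checked(path, c("onset", "duration", "trial_type",
                                 "triplet_index", "position", "condition"))
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  lex <- lexicon_from_list(side$lexicon)
  trip <- matrix(ev$trial_type, ncol = 3, byrow = TRUE)
  out <- new_stream(trip, lex, ev$condition[1], side$ramp_duration, side$seed,
                    variant = side$variant %||% NA_character_)
  if (max(abs(out$onset - ev$onset)) > 1e-9) {
    abort(sprintf("Onsets in %s are not on the 4 Hz grid.", path))
  }
  out
}

# strict TSV reader with located parse errors
read_tsv_checked <- function(path, expected_cols) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  out <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  pb <- readr::problems(out)
  if (nrow(pb) > 0) {
    abort(sprintf("Parse error in %s at line %d, column %d: expected %s, got %s.",
                  path, pb$row[1] + 1L, pb$col[1], pb$expected[1], pb$actual[1]))
  }
  missing <- setdiff(expected_cols, names(out))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing columns: %s.", path,
                  paste(missing, collapse = ", ")))
  }
  out
}

lexicon_to_list <- function(lexicon) {
  list(syllables = lexicon$syllables, pseudowords = lexicon$pseudowords,
       part_words = lexicon$part_words)
}

lexicon_from_list <- function(x) {
  lex <- structure(list(
    syllables = tibble::as_tibble(x$syllables),
    pseudowords = tibble::as_tibble(x$pseudowords),
    part_words = tibble::as_tibble(x$part_words)), class = "ft_lexicon")
  lex
}

#' Lexicon serialization (JSON)
#' @param lexicon an `ft_lexicon`.
#' @param path JSON path.
#' @return `path` invisibly (write) / the lexicon (read).
#' @export
write_lexicon <- function(lexicon, path) {
  jsonlite::write_json(lexicon_to_list(lexicon), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  lexicon_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Recording container (raw float64 + JSON sidecar)
#'
#' Continuous multi-channel data are stored as little-endian float64 in a
#' `.bin` file (channels fastest) with a JSON sidecar carrying dimensions,
#' sample rate, channel labels/positions and triplet onsets. Roundtrip is
#' bit-identical.
#'
#' @param recording an `ft_recording`.
#' @param prefix path prefix; writes `<prefix>.bin` and `<prefix>.json`.
#' @return `prefix` invisibly (write) / the recording (read).
#' @export
write_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "ft_recording"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$data), con, size = 8, endian = "little")
  meta <- recording[setdiff(names(recording), "data")]
  meta$dim <- dim(recording$data)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(x) != n) {
    abort(sprintf("%s.bin is truncated: expected %d doubles, got %d.",
                  prefix, n, length(x)))
  }
  data <- matrix(x, meta$dim[1], meta$dim[2])
  rownames(data) <- meta$channels$label
  structure(list(
    data = data, sample_rate = meta$sample_rate,
    channels = tibble::as_tibble(meta$channels),
    triplet_onsets = meta$triplet_onsets,
    ramp_duration = meta$ramp_duration,
    subject_id = meta$subject_id, condition = meta$condition,
    block = as.integer(meta$block)
  ), class = "ft_recording")
}

#' ITPC spectrum serialization (TSV + JSON sidecar)
#' @param itpc an `ft_itpc`.
#' @param path TSV path (rows: channels; columns: frequency bins).
#' @return `path` invisibly (write) / the spectrum (read).
#' @export
write_itpc <- function(itpc, path) {
  stopifnot(inherits(itpc, "ft_itpc"))
  tab <- tibble::as_tibble(itpc$values, .name_repair = "minimal")
  names(tab) <- sprintf("%.10g", itpc$freqs)
  tab <- dplyr::bind_cols(tibble::tibble(channel = itpc$channels$label), tab)
  readr::write_tsv(tab, path)
  meta <- itpc[c("freqs", "n_epochs", "condition", "block", "subject_id")]
  meta$channels <- itpc$channels
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_itpc
#' @export
read_itpc <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  tab <- read_tsv_checked(path, "channel")
  values <- as.matrix(tab[, -1])
  dimnames(values) <- list(tab$channel, NULL)
  structure(list(
    values = values, freqs = meta$freqs, n_epochs = meta$n_epochs,
    channels = tibble::as_tibble(meta$channels),
    condition = meta$condition, block = meta$block,
    subject_id = meta$subject_id
  ), class = "ft_itpc")
}

#' Write an amplitude envelope as a plain-text sample array
#'
#' One sample per line, full double precision, with a `# sample_rate=` header
#' comment line.
#'
#' @param envelope `ft_envelope` (or numeric vector).
#' @param path output text path.
#' @param sample_rate sampling rate (Hz); defaults to the envelope attribute.
#' @return `path` invisibly (write) / an `ft_envelope` (read).
#' @export
write_envelope_txt <- function(envelope, path, sample_rate = NULL) {
  sample_rate <- sample_rate %||% attr(envelope, "sample_rate") %||% 1000
  writeLines(c(sprintf("# sample_rate=%.10g", sample_rate),
               sprintf("%.17g", as.numeric(envelope))), path)
  invisible(path)
}

#' @rdname write_envelope_txt
#' @export
read_envelope_txt <- function(path) {
  lines <- readLines(path)
  sr <- as.numeric(sub("# sample_rate=", "", lines[1], fixed = TRUE))
  if (!is.finite(sr)) abort(sprintf("%s: malformed sample_rate header.", path))
  structure(as.numeric(lines[-1]), class = "ft_envelope", sample_rate = sr,
            ramp_duration = 0)
}

#' Write an amplitude envelope as a mono WAV file
#'
#' Minimal 16-bit PCM mono writer. Samples are rescaled to the +/-1 range
#' by the envelope maximum before quantization.
#'
#' @param envelope `ft_envelope` (or numeric vector).
#' @param path output `.wav` path.
#' @param sample_rate sampling rate (Hz); defaults to the envelope
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_wav <- function(envelope, path, sample_rate = NULL) {
  sample_rate <- as.integer(sample_rate %||% attr(envelope, "sample_rate") %||% 1000)
  x <- as.numeric(envelope)
  peak <- max(abs(x), 1e-12)
  pcm <- as.integer(round(x / peak * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(sample_rate, con, size = 4, endian = "little")
  writeBin(sample_rate * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
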