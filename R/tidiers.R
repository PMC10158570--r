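#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ITPC spectrum into a long tibble
#'
#' @param x an `ft_itpc`.
#' @param ... unused.
#' @return tibble with one row per channel x frequency bin: `channel`,
#'   `freq`, `itpc`, plus `subject_id`, `condition`, `block`.
#' @exportS3Method generics::tidy
tidy.ft_itpc <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channels$label, times = length(x$freqs)),
    freq = rep(x$freqs, each = nrow(x$values)),
    itpc = as.vector(x$values),
    subject_id = x$subject_id, condition = x$condition, block = x$block)
}

#' @rdname tidy.ft_itpc
#' @exportS3Method generics::glance
glance.ft_itpc <- function(x, ...) {
  tibble::tibble(n_channels = nrow(x$values), n_bins = ncol(x$values),
                 n_epochs = x$n_epochs, fmin = min(x$freqs),
                 fmax = max(x$freqs), mean_itpc = mean(x$values, na.rm = TRUE))
}

#' Tidy the by-block mixed-model fit
#'
#' @param x an `ft_block_fit`.
#' @param ... unused.
#' @return the coefficient tibble (`term`, `estimate`, `std.error`,
#'   `statistic`, `df`, `p.value`).
#' @exportS3Method generics::tidy
tidy.ft_block_fit <- function(x, ...) x$coefficients

#' @rdname tidy.ft_block_fit
#' @exportS3Method generics::glance
glance.ft_block_fit <- function(x, ...) {
  tibble::tibble(engine = x$engine, ranef_sd = x$ranef_sd, sigma = x$sigma)
}

#' Tidy cluster permutation results
#'
#' @param x an `ft_clusters`.
#' @param ... unused.
#' @return tibble with one row per cluster (electrodes collapsed to a
#'   comma-separated string).
#' @exportS3Method generics::tidy
tidy.ft_clusters <- function(x, ...) {
  tibble::tibble(
    cluster = x$cluster, n_electrodes = x$n_electrodes,
    electrodes = vapply(x$electrodes, paste, "", collapse = ","),
    stat = x$stat, p = x$p)
}

#' @rdname tidy.ft_clusters
#' @exportS3Method generics::glance
glance.ft_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x), n_significant = sum(x$p <= 0.05),
                 n_perm = attr(x, "n_perm"), direction = attr(x, "direction"))
}

#' Tidy an individual permutation result
#'
#' @param x an `ft_indiv_perm`.
#' @param ... unused.
#' @return the per-FOI result tibble with `subject_id` and `electrode_set`
#'   columns added.
#' @exportS3Method generics::tidy
tidy.ft_indiv_perm <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                subject_id = attr(x, "subject_id"),
                electrode_set = attr(x, "electrode_set"))
}

#' Tidy the neural-behavioral comparison
#'
#' @param x an `ft_nbc`.
#' @param ... unused.
#' @return tibble stacking the correlation and Welch-test rows with an
#'   `analysis` column.
#' @exportS3Method generics::tidy
tidy.ft_nbc <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$correlations, analysis = "correlation", .before = 1),
    dplyr::mutate(x$group_tests, analysis = "group_split", .before = 1))
}

#' Tidy a full experiment run
#'
#' @param x an `ft_experiment`.
#' @param ... unused.
#' @return the group FOI test table.
#' @exportS3Method generics::tidy
tidy.ft_experiment <- function(x, ...) x$group_foi

#' @rdname tidy.ft_experiment
#' @exportS3Method generics::glance
glance.ft_experiment <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$cohort),
    n_learners_true = sum(x$cohort$lambda > 0),
    n_neural_significant = x$individual$n_flagged,
    n_implicit_significant = sum(x$behavior$implicit_significant),
    n_explicit_above_cutoff = sum(x$behavior$explicit_above_cutoff),
    mean_2afc_accuracy = mean(x$behavior$accuracy),
    chance_cutoff = x$chance_cutoff)
}
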