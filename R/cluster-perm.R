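# per-electrode paired t statistics for many sign-flip permutations at once.
# D is the n x E difference matrix; S is an n x P matrix of +/-1 flips.
# Because s_i^2 = 1, sum_i (s_i d_ie)^2 = sum_i d_ie^2, so only the mean
# changes under a flip and all P x E t values follow from one crossproduct.
signflip_t <- function(D, S) {
  n <- nrow(D)
  M <- crossprod(S, D) / n                     # P x E means
  SS <- matrix(colSums(D^2), nrow(M), ncol(M), byrow = TRUE)
  t <- M / sqrt(pmax(SS - n * M^2, 0) / (n * (n - 1)))
  t[!is.finite(t)] <- 0  # zero-variance electrodes carry no evidence
  t
}

#' Cluster-based electrode permutation test
#'
#' Nonparametric correction for testing a condition difference at every
#' electrode: one-tailed paired t per electrode, supra-threshold electrodes
#' (p < `cluster_alpha`) grouped into spatially connected clusters, cluster
#' mass = summed t, and a max-cluster-statistic null built from random
#' within-subject condition-label sign flips. Cluster p values use the
#' add-one correction `(1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param language,baseline subjects x electrodes matrices of ITPC at one
#'   frequency (matching shapes).
#' @param adjacency logical electrode adjacency matrix
#'   ([electrode_adjacency()]).
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param cluster_alpha one-tailed cluster-forming threshold.
#' @param direction `"greater"` (language > baseline) or `"less"`.
#' @param seed integer seed.
#' @return object of class `ft_clusters`: tibble with one row per cluster
#'   (`cluster`, `n_electrodes`, `electrodes` list-column, `stat`, `p`),
#'   with attributes `null` (max-cluster null distribution), `t_obs`,
#'   `n_perm`, `direction`. Zero rows when nothing is supra-threshold.
#' @export
cluster_permutation <- function(language, baseline, adjacency,
                                n_perm = 1000, cluster_alpha = 0.05,
                                direction = c("greater", "less"), seed = 1L) {
  direction <- match.arg(direction)
  if (!all(dim(language) == dim(baseline))) abort("Shapes must match.")
  if (ncol(language) != nrow(adjacency)) abort("Adjacency must cover all electrodes.")
  if (n_perm < 100) abort("Use at least 100 permutations.")
  n <- nrow(language)
  E <- ncol(language)
  labels <- colnames(adjacency) %||% paste0("E", seq_len(E))
  sgn <- if (direction == "greater") 1 else -1
  D <- sgn * (language - baseline)
  t_crit <- qt(1 - cluster_alpha, df = n - 1)

  max_mass <- function(tvec) {
    supra <- which(tvec > t_crit)
    comps <- connected_components(adjacency, supra)
    if (length(comps) == 0) 0 else max(vapply(comps, function(cc) sum(tvec[cc]), 0))
  }

  t_obs <- as.vector(signflip_t(D, matrix(1, n, 1)))
  supra <- which(t_obs > t_crit)
  comps <- connected_components(adjacency, supra)

  null <- withr::with_seed(as.integer(seed), {
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    Tm <- signflip_t(D, S)
    vapply(seq_len(n_perm), function(p) max_mass(Tm[p, ]), 0)
  })

  res <- if (length(comps) == 0) {
    tibble::tibble(cluster = integer(), n_electrodes = integer(),
                   electrodes = list(), stat = numeric(), p = numeric())
  } else {
    stats_ <- vapply(comps, function(cc) sum(t_obs[cc]), 0)
    ord <- order(stats_, decreasing = TRUE)
    tibble::tibble(
      cluster = seq_along(ord),
      n_electrodes = lengths(comps)[ord],
      electrodes = lapply(comps[ord], function(cc) labels[cc]),
      stat = stats_[ord],
      p = vapply(stats_[ord], function(s) (1 + sum(null >= s)) / (1 + n_perm), 0)
    )
  }
  structure(res, class = c("ft_clusters", class(res)),
            null = null, t_obs = setNames(t_obs, labels),
            n_perm = n_perm, direction = direction,
            cluster_alpha = cluster_alpha)
}
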