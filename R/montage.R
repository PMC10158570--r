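#' Synthetic 64-channel montage
#'
#' A synthetic 2-D head layout: 64 electrodes on concentric rings (1, 6, 12,
#' 20, 25 electrodes at normalised radii 0, 0.25, 0.5, 0.75, 1), labelled
#' A1..A32, B1..B32 in the BioSemi naming style. Positive y is anterior.
#' These are generated coordinates for simulation, not digitized 10-20
#' positions.
#'
#' @param n_channels currently only 64 is supported.
#' @return tibble with columns `label`, `x`, `y` (head radius normalised
#'   to 1).
#' @export
make_montage <- function(n_channels = 64) {
  if (n_channels != 64) abort("Only the 64-channel layout is provided.")
  counts <- c(1, 6, 12, 20, 25)
  radii <- c(0, 0.25, 0.5, 0.75, 1)
  xy <- purrr::map2_dfr(counts, radii, function(k, r) {
    theta <- pi / 2 + 2 * pi * (seq_len(k) - 1) / k  # start anterior
    tibble::tibble(x = r * cos(theta), y = r * sin(theta))
  })
  xy$label <- paste0(rep(c("A", "B"), each = 32), rep(1:32, 2))
  xy[, c("label", "x", "y")]
}

#' Electrode adjacency from a 2-D montage
#'
#' Electrodes are adjacent if their distance is below `threshold` times the
#' head radius (the maximal electrode distance from the origin).
#'
#' @param montage tibble with `label`, `x`, `y`.
#' @param threshold adjacency distance threshold (fraction of head radius).
#' @return logical adjacency matrix with zero diagonal and label dimnames.
#' @export
electrode_adjacency <- function(montage, threshold = 0.35) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  head_r <- max(sqrt(montage$x^2 + montage$y^2))
  adj <- d < threshold * head_r
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$label, montage$label)
  isolated <- rowSums(adj) == 0
  if (any(isolated)) {
    warn(sprintf("Disconnected electrodes in adjacency: %s",
                 paste(montage$label[isolated], collapse = ", ")))
  }
  adj
}

#' Gaussian scalp topography weights
#'
#' @param montage tibble with `x`, `y`.
#' @param center length-2 numeric, map center in head coordinates.
#' @param width Gaussian width (head-radius units).
#' @return numeric weight vector (max 1), one per electrode.
#' @export
gaussian_topography <- function(montage, center, width = 0.6) {
  d2 <- (montage$x - center[1])^2 + (montage$y - center[2])^2
  exp(-d2 / (2 * width^2))
}

# default component topographies: word-rate response mid-central, syllable
# response mid-frontal
default_topographies <- function(montage) {
  list(word = gaussian_topography(montage, c(0, 0.1)),
       syllable = gaussian_topography(montage, c(0, 0.55)))
}

# connected components of the subgraph induced by `nodes` (integer ids) in a
# logical adjacency matrix; plain BFS kept dependency-free because it sits in
# the permutation hot loop
connected_components <- function(adj, nodes) {
  if (length(nodes) == 0) return(list())
  remaining <- nodes
  comps <- list()
  while (length(remaining) > 0) {
    queue <- remaining[1]
    comp <- queue
    remaining <- remaining[-1]
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- remaining[adj[v, remaining]]
      if (length(nb) > 0) {
        comp <- c(comp, nb)
        queue <- c(queue, nb)
        remaining <- setdiff(remaining, nb)
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}
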