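#' Synthetic benchmark landscapes with known peak structure
#'
#' Closed-form and randomised probability landscapes used to validate the
#' persistence machinery against ground truth that is independent of the
#' master-equation solver.
#'
#' `poisson_landscape()` is a truncated-and-renormalised Poisson profile
#' (unimodal; with integer rate `lambda` the maximum is a two-point plateau
#' at `lambda - 1` and `lambda`, which must still count as one peak).
#' `mixture_landscape()` is a normalised mixture of Poisson components with
#' chosen weights. `random_landscape()` draws i.i.d. heights on a 1-d or
#' 2-d grid from a seeded RNG, for fuzzing against the brute-force oracle.
#'
#' @param lambda Poisson rate (scalar, or vector for the mixture).
#' @param cap Support is `0..cap`.
#' @return Numeric probability vector over `0..cap`.
#' @export
poisson_landscape <- function(lambda, cap) {
  p <- stats::dpois(0:cap, lambda)
  p / sum(p)
}

#' @rdname poisson_landscape
#' @param weights Mixture weights (normalised internally).
#' @export
mixture_landscape <- function(lambda, weights, cap) {
  stopifnot(length(lambda) == length(weights), all(weights > 0))
  w <- weights / sum(weights)
  p <- drop(vapply(lambda, function(l) stats::dpois(0:cap, l),
                   numeric(cap + 1)) %*% w)
  p / sum(p)
}

#' @rdname poisson_landscape
#' @param dims Grid dimensions (length 1 or 2).
#' @param seed Seed for reproducible draws.
#' @return For `random_landscape()`: list with `heights` (normalised) and
#'   `adjacency` (nearest-neighbour lattice).
#' @export
random_landscape <- function(dims, seed) {
  set.seed(seed)
  n <- prod(dims)
  h <- stats::runif(n)
  h <- h / sum(h)
  list(heights = h, adjacency = lattice_adjacency(dims), dims = dims)
}

#' Brute-force superlevel component counts (oracle)
#'
#' Reference implementation used only for testing the persistence code: for
#' a threshold `r`, counts the connected components of the subgraph induced
#' by nodes with height `>= r` via [igraph::components()]. The number of
#' persistence classes alive at level `r` (born at or above, dying below)
#' must match this count exactly for every threshold.
#'
#' @param heights Non-negative heights.
#' @param adjacency Sparse adjacency pattern ([lattice_adjacency()] etc.);
#'   default 1-d path.
#' @param r Threshold.
#' @return Integer component count.
#' @export
brute_force_components <- function(heights, r, adjacency = NULL) {
  h <- as.numeric(heights)
  if (is.null(adjacency)) adjacency <- path_adjacency(length(h))
  keep <- which(h >= r)
  if (!length(keep)) return(0L)
  A <- as(adjacency, "CsparseMatrix")[keep, keep, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  as.integer(igraph::components(g)$no)
}
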