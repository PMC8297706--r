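#' 0-dimensional persistent homology of a probability landscape
#'
#' Computes the superlevel-set persistence diagram of a non-negative height
#' function on a graph. Sweeping a threshold downward from the global
#' maximum, each strict local maximum births a connected component at its
#' height; when two components merge, the younger one (the elder rule: the
#' component with the lower birth survives, ties broken towards the smaller
#' node index) dies at the merge height. Zero-persistence pairs arising from
#' plateaus are discarded, so a flat-topped peak counts once. Components
#' that never merge are *essential*: one per connected component of the
#' graph, recorded with death 0.
#'
#' @param heights Non-negative numeric vector (e.g. steady-state
#'   probabilities), or an `ffl_landscape` (its `p` is used and, unless
#'   `adjacency` is given, the generator support graph is the connectivity).
#' @param adjacency Sparse pattern (structurally symmetric) giving the
#'   neighbourhood graph, e.g. [generator_adjacency()] or
#'   [lattice_adjacency()]. For a plain vector with `adjacency = NULL`, a
#'   1-d path graph over consecutive entries is used.
#' @param generator Optional `ffl_generator` from which to take the
#'   adjacency when `heights` is an `ffl_landscape`.
#' @return Object of class `ffl_persistence`: data frame with columns
#'   `birth`, `death`, `persistence`, `representative` (node index of the
#'   peak maximum) and `essential`, sorted by persistence descending
#'   (essential classes first, by birth descending).
#' @examples
#' d <- superlevel_persistence(c(0.1, 0.3, 0.1, 0.4, 0.1))
#' d[, c("birth", "death")]  # peaks born at 0.4 (essential) and 0.3
#' @export
superlevel_persistence <- function(heights, adjacency = NULL, generator = NULL) {
  if (inherits(heights, "ffl_landscape")) {
    if (is.null(adjacency)) {
      if (is.null(generator))
        stop("supply 'generator' (or an explicit adjacency) for a landscape",
             call. = FALSE)
      adjacency <- generator_adjacency(generator)
    }
    heights <- heights$p
  }
  h <- as.numeric(heights)
  if (length(h) == 0L) stop("empty height vector", call. = FALSE)
  if (any(!is.finite(h)) || any(h < 0))
    stop("heights must be finite and non-negative", call. = FALSE)
  if (is.null(adjacency)) adjacency <- path_adjacency(length(h))
  A <- as(as(adjacency, "CsparseMatrix"), "generalMatrix")
  if (nrow(A) != length(h) || ncol(A) != length(h))
    stop("adjacency dimension does not match heights", call. = FALSE)
  ord <- order(-h, seq_along(h)) - 1L
  res <- persistence_cpp(h, A@i, A@p, ord)
  d <- data.frame(birth = res$birth, death = res$death,
                  persistence = res$birth - res$death,
                  representative = res$representative,
                  essential = res$essential)
  d <- d[order(-d$essential, -d$persistence, -d$birth), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("ffl_persistence", "data.frame")
  d
}

#' @export
print.ffl_persistence <- function(x, ...) {
  cat(sprintf("Persistence diagram: %d classes (%d essential)\n",
              nrow(x), sum(x$essential)))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Count probability peaks above a persistence threshold
#'
#' A peak is a persistence class whose persistence exceeds the threshold;
#' essential classes (the global maximum of each component) always count.
#' The default threshold is 1% of the largest birth value, which separates
#' genuine probability maxima from numerical ripple over a wide range
#' (roughly 0.5% to 5%) on the landscapes this package produces.
#'
#' @param diagram An `ffl_persistence` (or the arguments of
#'   [superlevel_persistence()], which is then called first).
#' @param threshold Absolute persistence cutoff; default
#'   `rel_threshold * max(birth)`.
#' @param rel_threshold Relative cutoff used when `threshold` is `NULL`.
#' @inheritParams superlevel_persistence
#' @return Integer peak count.
#' @export
count_peaks <- function(diagram, threshold = NULL, rel_threshold = 0.01,
                        adjacency = NULL, generator = NULL) {
  if (!inherits(diagram, "ffl_persistence"))
    diagram <- superlevel_persistence(diagram, adjacency = adjacency,
                                      generator = generator)
  if (is.null(threshold)) threshold <- rel_threshold * max(diagram$birth)
  sum(diagram$essential | diagram$persistence > threshold)
}

#' Modality of a marginal distribution
#'
#' Persistence-based count of the modes of a one- or two-dimensional
#' marginal, with the mode locations (copy numbers of the peak
#' representatives; ties resolved toward the smaller copy number by the
#' processing order). Uses unit-lattice adjacency on the marginal grid.
#'
#' @param marginal An `ffl_marginal` from [marginalize()], a numeric
#'   probability vector over `0, 1, ...`, or a matrix over a copy-number
#'   grid.
#' @inheritParams count_peaks
#' @return List with `n_modes`, `modes` (copy numbers, sorted; a matrix
#'   with one row per mode in the 2-d case), and the `diagram`.
#' @export
marginal_modality <- function(marginal, threshold = NULL, rel_threshold = 0.01) {
  if (inherits(marginal, "ffl_marginal")) marginal <- marginal$prob
  if (length(marginal) == 0L) stop("empty marginal", call. = FALSE)
  if (is.matrix(marginal)) {
    dims <- dim(marginal)
    d <- superlevel_persistence(as.numeric(marginal),
                                adjacency = lattice_adjacency(dims))
  } else {
    dims <- NULL
    d <- superlevel_persistence(as.numeric(marginal))
  }
  if (is.null(threshold)) threshold <- rel_threshold * max(d$birth)
  keep <- d$essential | d$persistence > threshold
  modes <- if (is.null(dims)) {
    sort(d$representative[keep] - 1L)
  } else {
    m <- arrayInd(d$representative[keep], .dim = dims) - 1L
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  list(n_modes = sum(keep), modes = modes, diagram = d)
}

# ---- adjacency constructors -----------------------------------------------

#' Connectivity graphs for persistence computations
#'
#' `generator_adjacency()` connects two microstates when a single reaction
#' converts one into the other (the off-diagonal support of the dCME
#' generator, symmetrised). `lattice_adjacency()` gives the axis-aligned
#' nearest-neighbour graph of a full grid, for persistence on marginal
#' arrays; `path_adjacency()` is its one-dimensional case.
#'
#' @param generator An `ffl_generator`.
#' @return A sparse pattern matrix (`CsparseMatrix`).
#' @export
generator_adjacency <- function(generator) {
  stopifnot(inherits(generator, "ffl_generator"))
  M <- generator$M
  A <- M
  diag(A) <- 0
  A <- Matrix::drop0(A)
  as(abs(A) + Matrix::t(abs(A)) > 0, "CsparseMatrix")
}

#' @rdname generator_adjacency
#' @param dims Integer grid dimensions (first dimension varies fastest,
#'   matching R array linearisation).
#' @export
lattice_adjacency <- function(dims) {
  dims <- as.integer(dims)
  stopifnot(all(dims >= 1))
  n <- prod(dims)
  idx <- seq_len(n)
  coords <- arrayInd(idx, .dim = dims)
  ii <- integer(0); jj <- integer(0)
  stride <- cumprod(c(1L, dims[-length(dims)]))
  for (k in seq_along(dims)) {
    src <- idx[coords[, k] < dims[k]]
    ii <- c(ii, src, src + stride[k])
    jj <- c(jj, src + stride[k], src)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)), dims = c(n, n))
}

#' @rdname generator_adjacency
#' @param n Number of path nodes.
#' @export
path_adjacency <- function(n) lattice_adjacency(n)
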