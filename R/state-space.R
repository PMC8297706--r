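#' Promoter occupancy configurations of an FFL
#'
#' Enumerates the joint occupancy states of genes `b` and `c`. For gene `b`
#' with `Nb` copies these are the pairs `(xb, xbA)` summing to `Nb`; for gene
#' `c` with `Nc` copies the triplets `(xc, xcA, xcB)` summing to `Nc` (each
#' copy free, A-bound or B-bound). The joint configurations are the Cartesian
#' product, `b`-states major; within each gene the bound counts increase
#' lexicographically. The ordering is pinned so that state indices, generator
#' matrices and output files are reproducible.
#'
#' @param Nb,Nc Gene copy numbers (1 or 2).
#' @return Integer matrix with columns `xb, xbA, xc, xcA, xcB`, one row per
#'   configuration.
#' @examples
#' nrow(gene_configs(1, 2))  # 2 x 6 = 12
#' @export
gene_configs <- function(Nb, Nc) {
  Nb <- as.integer(Nb); Nc <- as.integer(Nc)
  stopifnot(Nb >= 1L, Nc >= 1L)
  bocc <- cbind(xb = Nb - (0:Nb), xbA = 0:Nb)
  cocc <- do.call(rbind, unlist(lapply(0:Nc, function(nA) {
    lapply(0:(Nc - nA), function(nB) c(xc = Nc - nA - nB, xcA = nA, xcB = nB))
  }), recursive = FALSE))
  out <- cbind(bocc[rep(seq_len(nrow(bocc)), each = nrow(cocc)), , drop = FALSE],
               cocc[rep(seq_len(nrow(cocc)), times = nrow(bocc)), , drop = FALSE])
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Default free-protein truncation caps
#'
#' The cap for each protein is set from the largest conditional Poisson mean
#' it can attain across promoter states: `lam_A = sA/dA`,
#' `lam_B = Nb * sB * max(1, k1)/dB`, `lam_C = Nc * sC * max(1, k2, k3)/dC`,
#' with cap = `ceiling(lam + 8*sqrt(lam) + 10)`. With duplicated genes the
#' fully bound configurations synthesise from every copy, hence the `Nb`,
#' `Nc` factors. The 8-sigma-plus-offset margin puts the
#' truncated conditional tail mass far below the landscape tolerances; the
#' [boundary_mass()] diagnostic certifies adequacy after each solve.
#'
#' @param params An [ffl_params()] object.
#' @return Integer vector `c(A=, B=, C=)` of caps (maximum free copy number).
#' @export
truncation_caps <- function(params) {
  stopifnot(inherits(params, "ffl_params"))
  p <- params
  lam <- c(A = p$sA / p$dA,
           B = p$Nb * p$sB * max(1, p$k1) / p$dB,
           C = p$Nc * p$sC * max(1, p$k2, p$k3) / p$dC)
  caps <- ceiling(lam + 8 * sqrt(lam) + 10)
  storage.mode(caps) <- "integer"
  caps
}

#' Enumerate the truncated microstate space
#'
#' The state space is the product of the promoter occupancy configurations
#' ([gene_configs()]) with the free-protein boxes `0..capA` x `0..capB` x
#' `0..capC`. States are ordered with the occupancy configuration index
#' varying slowest, then `xA`, then `xB`, then `xC` (fastest); the linear
#' index of a state is therefore
#' `((g-1)*(capA+1) + xA) * (capB+1) * (capC+1) + xB*(capC+1) + xC + 1`.
#' Bound protein (in `bA`, `cA`, `cB` complexes) does not count against the
#' caps; gene copy numbers bound it at 2 or less anyway.
#'
#' @param network An [build_ffl_network()] result.
#' @param caps Integer vector of three caps `(A, B, C)`; defaults to
#'   [truncation_caps()] of the network's parameters.
#' @param max_states Guard against runaway enumerations (default 5e6).
#' @return Object of class `ffl_state_space` with fields `configs`, `caps`,
#'   `dims` (states per protein axis), `G`, `n_block`, `n`, and `network`.
#' @examples
#' net <- build_ffl_network(ffl_params())
#' enumerate_states(net, caps = c(1, 1, 1))$n  # 6 * 8 = 48
#' @export
enumerate_states <- function(network, caps = NULL, max_states = 5e6) {
  stopifnot(inherits(network, "ffl_network"))
  if (is.null(caps)) caps <- truncation_caps(network$params)
  caps <- as.integer(caps)
  if (length(caps) != 3L || any(caps < 0L))
    stop("'caps' must be three non-negative integers", call. = FALSE)
  configs <- gene_configs(network$params$Nb, network$params$Nc)
  G <- nrow(configs)
  dims <- caps + 1L
  n_block <- prod(as.double(dims))
  n <- G * n_block
  if (n > max_states)
    stop(sprintf("state space too large: %g states exceeds max_states = %g",
                 n, max_states), call. = FALSE)
  space <- list(configs = configs, caps = structure(caps, names = c("A", "B", "C")),
                dims = dims, G = G, n_block = as.integer(n_block),
                n = as.integer(n), network = network)
  class(space) <- "ffl_state_space"
  space
}

#' @export
print.ffl_state_space <- function(x, ...) {
  cat(sprintf("FFL state space: %d states (%d occupancy configs x %d x %d x %d protein box), caps (%d, %d, %d)\n",
              x$n, x$G, x$dims[1], x$dims[2], x$dims[3],
              x$caps[1], x$caps[2], x$caps[3]))
  invisible(x)
}

#' Linear index of microstates
#'
#' Maps microstates (rows over [ffl_species()]) to their 1-based linear index
#' in the pinned state ordering, and back.
#'
#' @param space An `ffl_state_space`.
#' @param x Named copy-number vector, or a matrix with one microstate per row.
#' @return Integer index/indices; `NA` for states outside the space.
#' @export
state_index <- function(space, x) {
  stopifnot(inherits(space, "ffl_state_space"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  cfg <- space$configs
  gk <- apply(cfg, 1, paste, collapse = ",")
  xs <- cbind(xb = x[, "b"], xbA = x[, "bA"], xc = x[, "c"],
              xcA = x[, "cA"], xcB = x[, "cB"])
  g <- match(apply(xs, 1, paste, collapse = ","), gk)
  dA <- space$dims[1]; dB <- space$dims[2]; dC <- space$dims[3]
  inside <- !is.na(g) & x[, "A"] >= 0 & x[, "A"] < dA &
    x[, "B"] >= 0 & x[, "B"] < dB & x[, "C"] >= 0 & x[, "C"] < dC &
    x[, "a"] == 1
  idx <- ((g - 1L) * dA + x[, "A"]) * (dB * dC) + x[, "B"] * dC + x[, "C"] + 1L
  idx[!inside] <- NA_integer_
  as.integer(idx)
}

#' @rdname state_index
#' @param idx Integer linear indices.
#' @export
index_state <- function(space, idx) {
  stopifnot(inherits(space, "ffl_state_space"))
  dA <- space$dims[1]; dB <- space$dims[2]; dC <- space$dims[3]
  i0 <- as.integer(idx) - 1L
  xC <- i0 %% dC; i0 <- i0 %/% dC
  xB <- i0 %% dB; i0 <- i0 %/% dB
  xA <- i0 %% dA; g <- i0 %/% dA + 1L
  cfg <- space$configs[g, , drop = FALSE]
  out <- cbind(A = xA, B = xB, C = xC, a = 1L,
               b = cfg[, "xb"], c = cfg[, "xc"],
               bA = cfg[, "xbA"], cA = cfg[, "xcA"], cB = cfg[, "xcB"])
  storage.mode(out) <- "integer"
  out
}

#' Strong-connectivity report of the truncated transition graph
#'
#' Checks (ignoring rates) whether every state communicates with every other
#' in the truncated chain, starting from the unbound zero-protein state. With
#' degenerate caps (e.g. `capA = 0`) promoter binding can never fire and the
#' bound configurations are unreachable; such states are listed.
#'
#' @param space An `ffl_state_space`.
#' @param matrix The generator from [build_generator()] (its sparsity pattern
#'   is the transition graph).
#' @return List with `connected` (logical), `n_components`, and
#'   `unreachable` (integer state indices not in the component of the initial
#'   state).
#' @export
reachable_check <- function(space, matrix) {
  M <- if (inherits(matrix, "ffl_generator")) matrix$M else matrix
  g <- igraph::graph_from_adjacency_matrix(abs(M) > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  start <- state_index(space, initial_state(space$network))
  main <- comp$membership[start]
  unreachable <- which(comp$membership != main)
  list(connected = comp$no == 1L, n_components = comp$no,
       unreachable = unreachable)
}
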