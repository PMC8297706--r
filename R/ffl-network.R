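#' Species order used throughout the package
#'
#' Copy-number vectors (microstates, stoichiometries, SSA states) are indexed
#' in this fixed order: the three free proteins, the input gene, the two free
#' regulated genes, and the three promoter-bound complexes.
#'
#' @return Character vector of the nine species names.
#' @export
ffl_species <- function() c("A", "B", "C", "a", "b", "c", "bA", "cA", "cB")

#' Construct the stochastic reaction network of a feed-forward loop
#'
#' Builds the mass-action reaction list of the FFL motif: reversible promoter
#' binding of A to gene `b`, of A to gene `c` and of B to gene `c`;
#' constitutive synthesis of A from gene `a` and of B and C from free genes;
#' regulated synthesis of B from the `bA` complex (fold `k1`) and of C from the
#' `cB` (fold `k2`) and `cA` (fold `k3`) complexes; and first-order degradation
#' of the three proteins. Gene duplication changes only the initial gene copy
#' numbers (`Nb`, `Nc`), never the reaction set.
#'
#' Each reaction's propensity at a microstate `x` is the rate constant times
#' the product of copy numbers of its reactants (all reactions are at most
#' bimolecular with unit stoichiometries).
#'
#' @param params An [ffl_params()] object.
#' @return An object of class `ffl_network`: list with `species`, `params`,
#'   and `reactions` (each reaction has `label`, `rate`, named `reactants` and
#'   `products` stoichiometries and the net stoichiometry vector `s`).
#' @examples
#' net <- build_ffl_network(ffl_params(1.2, 1.2, 1.2))
#' length(net$reactions)  # 15
#' @export
build_ffl_network <- function(params) {
  stopifnot(inherits(params, "ffl_params"))
  validate_ffl_params(params)
  p <- params
  sp <- ffl_species()
  rxn <- function(label, rate, reactants, products) {
    re <- structure(rep(0L, 9L), names = sp)
    pr <- re
    re[names(reactants)] <- as.integer(reactants)
    pr[names(products)] <- as.integer(products)
    list(label = label, rate = rate, reactants = re, products = pr,
         s = pr - re)
  }
  reactions <- list(
    rxn("bind_bA",   p$rbA,       c(b = 1, A = 1), c(bA = 1)),
    rxn("unbind_bA", p$fbA,       c(bA = 1),       c(b = 1, A = 1)),
    rxn("bind_cA",   p$rcA,       c(c = 1, A = 1), c(cA = 1)),
    rxn("unbind_cA", p$fcA,       c(cA = 1),       c(c = 1, A = 1)),
    rxn("bind_cB",   p$rcB,       c(c = 1, B = 1), c(cB = 1)),
    rxn("unbind_cB", p$fcB,       c(cB = 1),       c(c = 1, B = 1)),
    rxn("syn_A",     p$sA,        c(a = 1),        c(a = 1, A = 1)),
    rxn("deg_A",     p$dA,        c(A = 1),        c()),
    rxn("syn_B",     p$sB,        c(b = 1),        c(b = 1, B = 1)),
    rxn("syn_B_bA",  p$sB * p$k1, c(bA = 1),       c(bA = 1, B = 1)),
    rxn("deg_B",     p$dB,        c(B = 1),        c()),
    rxn("syn_C",     p$sC,        c(c = 1),        c(c = 1, C = 1)),
    rxn("syn_C_cB",  p$sC * p$k2, c(cB = 1),       c(cB = 1, C = 1)),
    rxn("syn_C_cA",  p$sC * p$k3, c(cA = 1),       c(cA = 1, C = 1)),
    rxn("deg_C",     p$dC,        c(C = 1),        c())
  )
  net <- list(species = sp, params = p, reactions = reactions)
  class(net) <- "ffl_network"
  # conservation of gene totals must hold reaction by reaction
  for (r in reactions) {
    if (r$s["b"] + r$s["bA"] != 0L || r$s["c"] + r$s["cA"] + r$s["cB"] != 0L ||
        r$s["a"] != 0L)
      stop("reaction '", r$label, "' violates gene conservation", call. = FALSE)
  }
  net
}

#' @export
print.ffl_network <- function(x, ...) {
  cat(sprintf("FFL reaction network [%s]: %d species, %d reactions, Nb = %d, Nc = %d\n",
              classify_ffl_type(x$params$k1, x$params$k2, x$params$k3)$label,
              length(x$species), length(x$reactions), x$params$Nb, x$params$Nc))
  invisible(x)
}

#' Initial microstate of an FFL network
#'
#' All free proteins at zero, all genes unbound: the conventional starting
#' point for trajectories and for reachability checks.
#'
#' @param network An `ffl_network`.
#' @return Named integer vector over [ffl_species()].
#' @export
initial_state <- function(network) {
  stopifnot(inherits(network, "ffl_network"))
  x <- structure(rep(0L, 9L), names = ffl_species())
  x["a"] <- 1L
  x["b"] <- network$params$Nb
  x["c"] <- network$params$Nc
  x
}

#' Propensity of one reaction at a microstate
#'
#' Mass-action combinatorial form: the rate constant times `choose(x_l, c_l)`
#' over reactant species (all stoichiometries here are 0 or 1, so this is a
#' plain product of reactant copy numbers).
#'
#' @param reaction One element of `network$reactions`.
#' @param x Named copy-number vector over [ffl_species()].
#' @return Numeric propensity.
#' @export
propensity <- function(reaction, x) {
  need <- reaction$reactants
  reaction$rate * prod(choose(x[need > 0L], need[need > 0L]))
}
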