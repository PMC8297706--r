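# network -> flat reaction tables consumed by the C++ simulator
ssa_tables <- function(network) {
  stopifnot(inherits(network, "ffl_network"))
  species <- ffl_species()
  m <- length(network$reactions)
  rate <- numeric(m)
  reactants <- matrix(-1L, m, 2)
  stoich <- matrix(0L, m, length(species))
  colnames(stoich) <- species
  for (k in seq_len(m)) {
    r <- network$reactions[[k]]
    rate[k] <- r$rate
    idx <- rep(match(names(r$reactants), species), times = r$reactants)
    if (any(r$reactants > 1))
      stop("unit reactant stoichiometries assumed", call. = FALSE)
    if (length(idx) > 2) stop("at most bimolecular reactions", call. = FALSE)
    if (length(idx) >= 1) reactants[k, 1] <- idx[1] - 1L
    if (length(idx) >= 2) reactants[k, 2] <- idx[2] - 1L
    stoich[k, ] <- r$s
  }
  list(rate = rate, reactants = reactants, stoich = stoich,
       labels = vapply(network$reactions, `[[`, "", "label"))
}

#' Stochastic simulation (direct-method Gillespie) of an FFL network
#'
#' Simulates one exact trajectory of the (untruncated) reaction network.
#' Uses R's random number generator, so results are reproducible with
#' `set.seed()`.
#'
#' @param network A [build_ffl_network()] object.
#' @param t_end Simulated time horizon.
#' @param x0 Optional named initial state; defaults to
#'   [initial_state()] (promoters unbound, no protein).
#' @param max_events Guard on the number of recorded events (default 1e7).
#' @return Object of class `ffl_trajectory`: `times` (event times, starting
#'   with 0), `states` (matrix of copy numbers after each event, first row
#'   the initial state), `reactions` (reaction labels per event), and
#'   `absorbed`.
#' @examples
#' net <- build_ffl_network(ffl_params(1.2, 1.2, 1.2))
#' set.seed(1)
#' tr <- simulate_ssa(net, t_end = 50)
#' tail(tr$states[, c("A", "B", "C")], 1)
#' @export
simulate_ssa <- function(network, t_end, x0 = NULL, max_events = 1e7) {
  tab <- ssa_tables(network)
  species <- ffl_species()
  if (is.null(x0)) x0 <- initial_state(network)
  x0 <- as.integer(x0[species])
  out <- ssa_simulate_cpp(tab$rate, tab$reactants, tab$stoich, x0,
                          as.numeric(t_end), as.integer(max_events))
  ne <- length(out$times)
  states <- matrix(rep(x0, each = ne + 1L), ne + 1L, length(species),
                   dimnames = list(NULL, species))
  if (ne > 0) {
    inc <- apply(tab$stoich[out$reaction, , drop = FALSE], 2, cumsum)
    states[-1L, ] <- states[-1L, ] + inc
  }
  structure(list(times = c(0, out$times), states = states,
                 reactions = tab$labels[out$reaction],
                 absorbed = out$absorbed, t_end = t_end),
            class = "ffl_trajectory")
}

#' @export
print.ffl_trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory: %d events over t = [0, %g]%s\n",
              length(x$times) - 1L, x$t_end,
              if (x$absorbed) " (absorbed)" else ""))
  invisible(x)
}

#' Time-weighted empirical distribution of a trajectory
#'
#' The exact occupancy measure of a simulated trajectory: each visited copy
#' number of `species` is weighted by the time the trajectory spends there
#' after the burn-in, normalised to a probability vector. As simulated time
#' grows this converges to the stationary marginal (up to truncation
#' differences with the dCME).
#'
#' @param trajectory An [simulate_ssa()] result.
#' @param species One species name.
#' @param burn_in Time discarded from the start (default 500).
#' @return Named probability vector over `0..max` observed copy number.
#' @export
empirical_distribution <- function(trajectory, species, burn_in = 500) {
  stopifnot(inherits(trajectory, "ffl_trajectory"))
  if (burn_in >= trajectory$t_end)
    stop("burn_in must be smaller than the simulated horizon", call. = FALSE)
  t <- trajectory$times
  x <- trajectory$states[, species]
  dt <- pmax(pmin(c(t[-1], trajectory$t_end), trajectory$t_end) -
               pmax(t, burn_in), 0)
  w <- tapply(dt, factor(x, levels = 0:max(x)), sum, default = 0)
  p <- as.vector(w) / sum(dt)
  stats::setNames(p, 0:max(x))
}

#' Streaming occupancy histogram over many SSA trajectories
#'
#' Accumulates the time-weighted histogram of one or two species over
#' `n_traj` independent trajectories without storing the trajectories,
#' which keeps long comparisons against the exact landscape cheap in
#' memory.
#'
#' @inheritParams simulate_ssa
#' @param species One or two species names.
#' @param caps Histogram caps per species (counts beyond are clamped into
#'   the top bin); defaults to the [truncation_caps()] of the network.
#' @param n_traj Number of independent trajectories (default 1).
#' @param burn_in Time discarded from the start of each trajectory.
#' @return Named probability vector (one species) or matrix (two species,
#'   first on rows).
#' @export
ssa_histogram <- function(network, t_end, species, burn_in = 500,
                          caps = NULL, n_traj = 1, x0 = NULL) {
  tab <- ssa_tables(network)
  sp <- ffl_species()
  stopifnot(all(species %in% sp), length(species) %in% 1:2)
  if (is.null(x0)) x0 <- initial_state(network)
  if (is.null(caps)) {
    full <- truncation_caps(network$params)
    caps <- full[match(species, c("A", "B", "C"))]
    caps[is.na(caps)] <- 2L  # gene species
  }
  if (burn_in >= t_end)
    stop("burn_in must be smaller than the simulated horizon", call. = FALSE)
  out <- ssa_occupancy_cpp(tab$rate, tab$reactants, tab$stoich,
                           as.integer(x0[sp]), as.numeric(t_end),
                           as.numeric(burn_in),
                           match(species, sp) - 1L, as.integer(caps),
                           as.integer(n_traj))
  p <- out$weights / out$total_time
  if (length(species) == 1L) {
    stats::setNames(p, 0:caps[1])
  } else {
    matrix(p, caps[1] + 1L, caps[2] + 1L,
           dimnames = list(0:caps[1], 0:caps[2]))
  }
}
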