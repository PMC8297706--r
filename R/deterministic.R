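#' Occupancy-conditioned deterministic equilibria
#'
#' In the slow promoter-switching regime each promoter occupancy
#' configuration persists long enough for the proteins to relax to the
#' deterministic fixed point of that configuration: each protein is a
#' linear birth-death process with equilibrium synthesis/degradation. The
#' candidate expression levels are therefore
#' `B* in {sB/dB, k1 sB/dB}` (per bound/unbound B promoter copy) and
#' `C* in {sC/dC, k2 sC/dC, k3 sC/dC}`, one per occupancy configuration.
#' These are the deterministic predictions against which the probability
#' landscape's peak structure is compared.
#'
#' @param params An [ffl_params()] object.
#' @param merge_tol Relative tolerance below which two equilibria are
#'   considered the same level (default 1e-9).
#' @return List with `A` (scalar), `B` and `C` (sorted unique levels), and
#'   `by_config`: a data frame with one row per promoter occupancy
#'   configuration giving its `(A*, B*, C*)`.
#' @examples
#' occupancy_equilibria(ffl_params(2.4, 4.5, 1.8))$C  # 10, 18, 45
#' @export
occupancy_equilibria <- function(params, merge_tol = 1e-9) {
  stopifnot(inherits(params, "ffl_params"))
  p <- params
  cfg <- gene_configs(p$Nb, p$Nc)
  Astar <- p$sA / p$dA
  Bstar <- (p$sB * cfg[, "xb"] + p$sB * p$k1 * cfg[, "xbA"]) / p$dB
  Cstar <- (p$sC * cfg[, "xc"] + p$sC * p$k2 * cfg[, "xcB"] +
              p$sC * p$k3 * cfg[, "xcA"]) / p$dC
  merge_levels <- function(v) {
    v <- sort(unique(v))
    if (length(v) <= 1L) return(v)
    keep <- c(TRUE, diff(v) > merge_tol * pmax(abs(v[-length(v)]), 1))
    v[keep]
  }
  list(A = Astar,
       B = merge_levels(Bstar),
       C = merge_levels(Cstar),
       by_config = data.frame(cfg, A = Astar, B = Bstar, C = Cstar))
}

# mass-action right-hand side over the nine species; promoter occupancies
# are treated as continuous variables conserved per gene copy
mean_field_rhs <- function(x, p) {
  x <- unname(x)
  A <- x[1]; B <- x[2]; C <- x[3]
  a <- x[4]; b <- x[5]; c_ <- x[6]
  bA <- x[7]; cA <- x[8]; cB <- x[9]
  v_bA_on <- p$rbA * b * A;  v_bA_off <- p$fbA * bA
  v_cA_on <- p$rcA * c_ * A; v_cA_off <- p$fcA * cA
  v_cB_on <- p$rcB * c_ * B; v_cB_off <- p$fcB * cB
  synA <- p$sA * a
  synB <- p$sB * b + p$sB * p$k1 * bA
  synC <- p$sC * c_ + p$sC * p$k2 * cB + p$sC * p$k3 * cA
  c(A = synA - p$dA * A - v_bA_on + v_bA_off - v_cA_on + v_cA_off,
    B = synB - p$dB * B - v_cB_on + v_cB_off,
    C = synC - p$dC * C,
    a = 0,
    b = -v_bA_on + v_bA_off,
    c = -v_cA_on + v_cA_off - v_cB_on + v_cB_off,
    bA = v_bA_on - v_bA_off,
    cA = v_cA_on - v_cA_off,
    cB = v_cB_on - v_cB_off)
}

#' Mean-field (mass-action) steady state of the full network
#'
#' Deterministic counterpart of the stochastic model: ordinary differential
#' equations with mass-action kinetics over all nine species, promoter
#' occupancies included as continuous variables (conserved per gene:
#' `b + bA = Nb`, `c + cA + cB = Nc`). The system is integrated to
#' stationarity with `deSolve::lsoda` and the fixed point polished by
#' Newton iteration to residual below `1e-10`. Because the averaged
#' promoter state washes out the slow-switching multistability, this
#' mean-field model has a single fixed point where the exact landscape can
#' have several peaks.
#'
#' @param params An [ffl_params()] object.
#' @param x0 Optional initial state (named as [ffl_species()]); default all
#'   proteins at zero, promoters unbound.
#' @param t_relax Integration horizon before polishing (default 2000).
#' @param check_uniqueness If `TRUE` (default), re-solve from several
#'   dispersed initial conditions and report whether all converge to the
#'   same point.
#' @return List with `state` (named fixed point), `residual`, and
#'   `unique` (`NA` when the check is skipped).
#' @export
mean_field_steady_state <- function(params, x0 = NULL, t_relax = 2000,
                                    check_uniqueness = TRUE) {
  stopifnot(inherits(params, "ffl_params"))
  p <- params
  species <- ffl_species()
  if (is.null(x0)) {
    x0 <- stats::setNames(numeric(9), species)
    x0["a"] <- 1; x0["b"] <- p$Nb; x0["c"] <- p$Nc
  } else {
    stopifnot(setequal(names(x0), species))
    x0 <- x0[species]
  }
  relax <- function(x0) {
    sol <- deSolve::lsoda(y = x0, times = c(0, t_relax),
                          func = function(t, y, parms) list(mean_field_rhs(y, p)),
                          rtol = 1e-10, atol = 1e-12)
    x <- sol[nrow(sol), species]
    # Newton polish on the reduced coordinates (A, B, C, bA, cA, cB);
    # b, c follow from the per-gene conservation laws, a is constant
    red <- c("A", "B", "C", "bA", "cA", "cB")
    full <- function(z) {
      y <- stats::setNames(numeric(9), species)
      y[red] <- z
      y["a"] <- 1
      y["b"] <- p$Nb - z["bA"]
      y["c"] <- p$Nc - z["cA"] - z["cB"]
      y
    }
    g <- function(z) mean_field_rhs(full(z), p)[red]
    fd_jacobian <- function(z, gz) {
      J <- matrix(0, length(z), length(z))
      for (j in seq_along(z)) {
        hj <- 1e-7 * max(abs(z[j]), 1)
        zj <- z; zj[j] <- zj[j] + hj
        J[, j] <- (g(zj) - gz) / hj
      }
      J
    }
    z <- x[red]
    for (it in 1:50) {
      gz <- g(z)
      if (max(abs(gz)) < 1e-12) break
      J <- fd_jacobian(z, gz)
      step <- tryCatch(solve(J, gz), error = function(e) NULL)
      if (is.null(step)) break
      z <- z - stats::setNames(as.vector(step), red)
    }
    y <- full(z)
    list(state = y, residual = max(abs(mean_field_rhs(y, p))))
  }
  fit <- relax(x0)
  if (fit$residual > 1e-10)
    stop(sprintf("mean-field solve did not reach stationarity (residual %.2e)",
                 fit$residual), call. = FALSE)
  unique_fp <- NA
  if (check_uniqueness) {
    others <- lapply(1:5, function(k) {
      y <- x0
      amp <- p$sA / p$dA * 6
      y[c("A", "B", "C")] <- amp * (k * c(17, 31, 47) %% 11) / 11
      frac <- (k * c(3, 5) %% 7) / 7
      y["bA"] <- p$Nb * frac[1]; y["b"] <- p$Nb - y["bA"]
      y["cA"] <- p$Nc * frac[2] / 2; y["cB"] <- p$Nc * frac[2] / 2
      y["c"] <- p$Nc - y["cA"] - y["cB"]
      relax(y)$state
    })
    scale <- pmax(abs(fit$state), 1)
    unique_fp <- all(vapply(others, function(s)
      max(abs(s - fit$state) / scale) < 1e-6, logical(1)))
  }
  list(state = fit$state, residual = fit$residual, unique = unique_fp)
}
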