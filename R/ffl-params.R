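#' Parameter set for a stochastic feed-forward loop model
#'
#' An FFL couples three genes: the input gene `a` expresses protein A, which
#' binds the promoters of genes `b` and `c`; protein B (product of `b`) also
#' binds the promoter of `c` ("OR"-gate: the `c` promoter carries A or B, never
#' both). Bound promoters express at a fold-change of the basal rate: `k1` for
#' `b` bound by A, `k2` for `c` bound by B, and `k3` for `c` bound by A.
#'
#' The default rates are the slow-promoter "generic case": binding 0.005/s,
#' unbinding 0.1/s, synthesis 10/s and degradation 1/s for every species, with
#' single-copy genes.
#'
#' @param k1,k2,k3 Dimensionless regulation intensities (> 0). Values >= 1 are
#'   activating, < 1 inhibiting.
#' @param sA,sB,sC Basal protein synthesis rates (per second).
#' @param dA,dB,dC Protein degradation rates (per second).
#' @param rbA,rcA,rcB Promoter binding rates (per second): A to `b`, A to `c`,
#'   B to `c`.
#' @param fbA,fcA,fcB Promoter unbinding rates (per second).
#' @param Nb,Nc Gene copy numbers of `b` and `c` (1 or 2).
#' @param n Fold multiplier applied by [scale_binding()] in binding-dynamics
#'   sweeps; carried along for bookkeeping, 1 by default.
#' @return An object of class `ffl_params`.
#' @seealso [classify_ffl_type()], [scale_binding()], [build_ffl_network()]
#' @examples
#' p <- ffl_params(3.0, 0.025, 5.1)
#' classify_ffl_type(p$k1, p$k2, p$k3)
#' @export
ffl_params <- function(k1 = 1, k2 = 1, k3 = 1,
                       sA = 10, sB = 10, sC = 10,
                       dA = 1, dB = 1, dC = 1,
                       rbA = 0.005, rcA = 0.005, rcB = 0.005,
                       fbA = 0.1, fcA = 0.1, fcB = 0.1,
                       Nb = 1L, Nc = 1L, n = 1) {
  p <- list(k1 = k1, k2 = k2, k3 = k3,
            sA = sA, sB = sB, sC = sC,
            dA = dA, dB = dB, dC = dC,
            rbA = rbA, rcA = rcA, rcB = rcB,
            fbA = fbA, fcA = fcA, fcB = fcB,
            Nb = as.integer(Nb), Nc = as.integer(Nc), n = n)
  class(p) <- "ffl_params"
  validate_ffl_params(p)
  p
}

validate_ffl_params <- function(p) {
  num <- c("k1", "k2", "k3", "sA", "sB", "sC", "dA", "dB", "dC",
           "rbA", "rcA", "rcB", "fbA", "fcA", "fcB", "n")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a finite numeric scalar", call. = FALSE)
  }
  if (any(unlist(p[num]) < 0))
    stop("all rates must be non-negative", call. = FALSE)
  if (p$k1 <= 0 || p$k2 <= 0 || p$k3 <= 0)
    stop("regulation intensities k1, k2, k3 must be positive", call. = FALSE)
  if (p$n <= 0) stop("binding fold 'n' must be positive", call. = FALSE)
  if (!p$Nb %in% c(1L, 2L) || !p$Nc %in% c(1L, 2L))
    stop("gene copy numbers Nb and Nc must be 1 or 2", call. = FALSE)
  invisible(p)
}

#' @export
print.ffl_params <- function(x, ...) {
  cat(sprintf("FFL parameters [%s]: k = (%g, %g, %g), s = (%g, %g, %g)\n",
              classify_ffl_type(x$k1, x$k2, x$k3)$label,
              x$k1, x$k2, x$k3, x$sA, x$sB, x$sC))
  cat(sprintf("  binding r = (%g, %g, %g), unbinding f = (%g, %g, %g), d = (%g, %g, %g)\n",
              x$rbA, x$rcA, x$rcB, x$fbA, x$fcA, x$fcB, x$dA, x$dB, x$dC))
  cat(sprintf("  gene copies Nb = %d, Nc = %d, binding fold n = %g\n",
              x$Nb, x$Nc, x$n))
  invisible(x)
}

#' Classify a feed-forward loop by its regulation intensities
#'
#' Each of the three regulatory edges is activating when its fold-change is
#' at least 1 and inhibiting when below 1 (exactly 1 counts as activating). The FFL is
#' coherent when the direct A-to-c effect (`k3`) has the same sign as the
#' product of the indirect path (`k1` times `k2`); incoherent FFLs have an odd
#' number of inhibiting edges.
#'
#' @param k1,k2,k3 Positive regulation intensities.
#' @return A list with elements `label` (one of `"C1".."C4"`, `"I1".."I4"`)
#'   and `coherent` (logical).
#' @examples
#' classify_ffl_type(1.2, 1.2, 1.2)  # C1
#' classify_ffl_type(3.0, 0.025, 5.1)  # I1
#' @export
classify_ffl_type <- function(k1, k2, k3) {
  if (k1 <= 0 || k2 <= 0 || k3 <= 0)
    stop("regulation intensities must be positive", call. = FALSE)
  a1 <- k1 >= 1; a2 <- k2 >= 1; a3 <- k3 >= 1
  key <- paste0(as.integer(a1), as.integer(a2), as.integer(a3))
  label <- switch(key,
    "111" = "C1", "010" = "C2", "100" = "C3", "001" = "C4",
    "101" = "I1", "000" = "I2", "110" = "I3", "011" = "I4")
  coherent <- (a3 == (a1 == a2))
  list(label = label, coherent = coherent)
}

#' Rescale promoter binding dynamics while preserving affinity
#'
#' Multiplies both the binding and the unbinding rate of each targeted
#' gene-protein pair by `n`, so the equilibrium occupancy ratio r/f is
#' unchanged while the switching time scale speeds up (`n` > 1) or slows down
#' (`n` < 1) relative to the generic case.
#'
#' @param params An [ffl_params()] object.
#' @param target Character subset of `c("bA", "cA", "cB")` naming the
#'   gene-protein pairs to rescale.
#' @param n Positive fold change.
#' @return A new `ffl_params` object with the rescaled rates and the `n`
#'   field updated.
#' @examples
#' p <- scale_binding(ffl_params(3.0, 0.025, 5.1), c("cA", "cB"), 16)
#' c(p$rcA, p$fcA)  # 0.08, 1.6
#' @export
scale_binding <- function(params, target, n) {
  stopifnot(inherits(params, "ffl_params"))
  if (length(target) == 0L) stop("'target' must not be empty", call. = FALSE)
  if (!all(target %in% c("bA", "cA", "cB")))
    stop("'target' must be a subset of c(\"bA\", \"cA\", \"cB\")", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop("'n' must be a positive scalar", call. = FALSE)
  p <- unclass(params)
  if ("bA" %in% target) { p$rbA <- p$rbA * n; p$fbA <- p$fbA * n }
  if ("cA" %in% target) { p$rcA <- p$rcA * n; p$fcA <- p$fcA * n }
  if ("cB" %in% target) { p$rcB <- p$rcB * n; p$fcB <- p$fcB * n }
  p$n <- n
  class(p) <- "ffl_params"
  validate_ffl_params(p)
  p
}

#' Build an ordered grid of FFL parameter sets
#'
#' Takes value sequences for any subset of the model parameters and expands
#' their Cartesian product in deterministic lexicographic order (later
#' arguments vary fastest, like [expand.grid()] with the first argument
#' slowest). Each grid point is an [ffl_params()] object tagged with its FFL
#' type label.
#'
#' Range specifications follow the study's sweeps, e.g.
#' `k2 = seq(0.025, 5.0, by = 0.25)`.
#'
#' @param ... Named numeric vectors of values for `ffl_params` arguments
#'   (e.g. `k1`, `k2`, `k3`, `sA`, `Nb`, `Nc`).
#' @param base An `ffl_params` object providing the values of parameters not
#'   swept.
#' @return A list of `ffl_params` objects with attributes `manifest` (a
#'   `data.frame`, one row per condition with all parameters and the FFL type
#'   label) and class `ffl_grid`.
#' @examples
#' g <- parameter_grid(k1 = c(0.8, 2.4), k2 = c(0.5, 2.0))
#' attr(g, "manifest")
#' @export
parameter_grid <- function(..., base = ffl_params()) {
  stopifnot(inherits(base, "ffl_params"))
  axes <- list(...)
  if (length(axes) == 0L) stop("no grid axes given", call. = FALSE)
  if (is.null(names(axes)) || any(!nzchar(names(axes))))
    stop("grid axes must be named", call. = FALSE)
  ok <- names(axes) %in% setdiff(names(unclass(base)), character())
  if (!all(ok))
    stop("unknown parameter(s): ", paste(names(axes)[!ok], collapse = ", "),
         call. = FALSE)
  if (any(lengths(axes) == 0L)) stop("empty grid axis", call. = FALSE)
  # lexicographic: first named axis varies slowest
  rev_axes <- rev(axes)
  tab <- do.call(expand.grid, c(rev_axes, KEEP.OUT.ATTRS = FALSE))
  tab <- tab[, rev(seq_along(axes)), drop = FALSE]
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- unclass(base)
    for (nm in names(axes)) p[[nm]] <- tab[i, nm]
    p$Nb <- as.integer(p$Nb); p$Nc <- as.integer(p$Nc)
    class(p) <- "ffl_params"
    validate_ffl_params(p)
    out[[i]] <- p
  }
  manifest <- do.call(rbind, lapply(seq_along(out), function(i) {
    p <- out[[i]]
    data.frame(condition = sprintf("c%04d", i),
               k1 = p$k1, k2 = p$k2, k3 = p$k3,
               sA = p$sA, sB = p$sB, sC = p$sC,
               dA = p$dA, dB = p$dB, dC = p$dC,
               rbA = p$rbA, rcA = p$rcA, rcB = p$rcB,
               fbA = p$fbA, fcA = p$fcA, fcB = p$fcB,
               Nb = p$Nb, Nc = p$Nc, n = p$n,
               ffl_type = classify_ffl_type(p$k1, p$k2, p$k3)$label,
               stringsAsFactors = FALSE)
  }))
  structure(out, manifest = manifest, class = c("ffl_grid", "list"))
}

#' Write the manifest of a parameter grid to CSV
#'
#' One row per condition: condition id, all parameters and the FFL type label.
#'
#' @param grid An [parameter_grid()] result.
#' @param file Output path.
#' @return The manifest `data.frame`, invisibly.
#' @export
write_grid_manifest <- function(grid, file) {
  stopifnot(inherits(grid, "ffl_grid"))
  manifest <- attr(grid, "manifest")
  utils::write.csv(manifest, file, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' @export
print.ffl_grid <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf("FFL parameter grid: %d conditions, types: %s\n", length(x),
              paste(sort(unique(m$ffl_type)), collapse = " ")))
  invisible(x)
}
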