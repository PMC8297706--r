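#' Run the full landscape pipeline for one parameter condition
#'
#' Convenience orchestration: build the network, enumerate the truncated
#' state space, assemble the generator, solve for the steady state, and
#' summarise the landscape topology. Returns everything the downstream
#' experiments need — joint peak count, marginal modalities with mode
#' locations, and the truncation/solver diagnostics that certify the
#' numbers.
#'
#' @param params An [ffl_params()] object.
#' @param caps Optional explicit truncation caps (default
#'   [truncation_caps()]).
#' @param rel_threshold Relative persistence threshold for peak counting.
#' @param keep_landscape Keep the full probability vector in the result
#'   (default `TRUE`; set `FALSE` when sweeping many conditions).
#' @return Object of class `ffl_condition`: `params`, `ffl_type`,
#'   `landscape` (or `NULL`), `joint` (persistence diagram and `n_peaks`),
#'   `marginal_B`/`marginal_C` (probabilities, `n_modes`, `modes`), and
#'   `diagnostics` (`n_states`, `caps`, `residual`, `boundary_mass`,
#'   `iterations`, timing).
#' @examples
#' \dontrun{
#' cond <- run_condition(ffl_params(1.2, 1.2, 1.2))
#' cond$joint$n_peaks
#' }
#' @export
run_condition <- function(params, caps = NULL, rel_threshold = 0.01,
                          keep_landscape = TRUE) {
  t0 <- proc.time()[[3]]
  net <- build_ffl_network(params)
  space <- enumerate_states(net, caps = caps)
  gen <- build_generator(space)
  ls <- solve_steady_state(gen)
  t_solve <- proc.time()[[3]]
  diagram <- superlevel_persistence(ls, generator = gen)
  n_peaks <- count_peaks(diagram, rel_threshold = rel_threshold)
  mB <- marginalize(ls, "B"); mC <- marginalize(ls, "C")
  modB <- marginal_modality(mB, rel_threshold = rel_threshold)
  modC <- marginal_modality(mC, rel_threshold = rel_threshold)
  bm <- boundary_mass(ls)
  peak_states <- index_state(space, diagram$representative[
    diagram$essential | diagram$persistence > rel_threshold * max(diagram$birth)])
  out <- list(
    params = params,
    ffl_type = classify_ffl_type(params$k1, params$k2, params$k3),
    landscape = if (keep_landscape) ls else NULL,
    joint = list(diagram = diagram, n_peaks = n_peaks,
                 peak_states = peak_states),
    marginal_B = list(prob = mB$prob, n_modes = modB$n_modes, modes = modB$modes),
    marginal_C = list(prob = mC$prob, n_modes = modC$n_modes, modes = modC$modes),
    diagnostics = list(n_states = space$n, caps = space$caps,
                       residual = ls$residual, iterations = ls$iterations,
                       boundary_mass = bm$total,
                       seconds = proc.time()[[3]] - t0,
                       seconds_solve = t_solve - t0))
  class(out) <- "ffl_condition"
  out
}

#' @export
print.ffl_condition <- function(x, ...) {
  p <- x$params
  cat(sprintf("FFL condition %s (k1=%g, k2=%g, k3=%g): %d joint peaks, B %d-modal, C %d-modal\n",
              x$ffl_type$label, p$k1, p$k2, p$k3, x$joint$n_peaks,
              x$marginal_B$n_modes, x$marginal_C$n_modes))
  cat(sprintf("  %d states, residual %.1e, boundary mass %.1e, %.1f s\n",
              x$diagnostics$n_states, x$diagnostics$residual,
              x$diagnostics$boundary_mass, x$diagnostics$seconds))
  invisible(x)
}

condition_row <- function(cond, id) {
  p <- cond$params
  data.frame(
    id = id, ffl_type = cond$ffl_type$label,
    k1 = p$k1, k2 = p$k2, k3 = p$k3, sA = p$sA, Nb = p$Nb, Nc = p$Nc,
    n = p$n %||% 1,
    n_states = cond$diagnostics$n_states,
    residual = cond$diagnostics$residual,
    boundary_mass = cond$diagnostics$boundary_mass,
    joint_peaks = cond$joint$n_peaks,
    m_B = cond$marginal_B$n_modes, m_C = cond$marginal_C$n_modes,
    modes_B = paste(cond$marginal_B$modes, collapse = ";"),
    modes_C = paste(cond$marginal_C$modes, collapse = ";"),
    seconds = cond$diagnostics$seconds,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sweep a parameter grid and tabulate landscape topology
#'
#' Runs [run_condition()] for every row of a [parameter_grid()] manifest
#' and collects one summary row per condition. When `out_csv` is given the
#' table is appended row by row, and a restart skips conditions already
#' present in the file, so long sweeps are resumable. All computations are
#' deterministic, so a resumed sweep produces the same table as an
#' uninterrupted one.
#'
#' @param grid A [parameter_grid()] object (list of `ffl_params` with a
#'   manifest attribute).
#' @param out_csv Optional path of the running output table.
#' @param rel_threshold Relative persistence threshold.
#' @param caps Optional fixed truncation caps; by default each condition
#'   recomputes its own [truncation_caps()].
#' @param verbose Print one line per condition.
#' @return Data frame: one row per condition with `id`, parameters,
#'   `ffl_type`, state count, residual and boundary-mass diagnostics,
#'   `joint_peaks`, `m_B`, `m_C`, and semicolon-separated mode locations.
#' @export
run_phase_diagram <- function(grid, out_csv = NULL, rel_threshold = 0.01,
                              caps = NULL, verbose = TRUE) {
  manifest <- attr(grid, "manifest")
  stopifnot(!is.null(manifest))
  done <- character(0)
  rows <- list()
  if (!is.null(out_csv) && file.exists(out_csv)) {
    prev <- utils::read.csv(out_csv, stringsAsFactors = FALSE)
    done <- as.character(prev$id)
    rows <- list(prev)
  }
  for (k in seq_along(grid)) {
    id <- manifest$condition[k]
    if (as.character(id) %in% done) next
    cond <- run_condition(grid[[k]], caps = caps,
                          rel_threshold = rel_threshold,
                          keep_landscape = FALSE)
    row <- condition_row(cond, id)
    rows[[length(rows) + 1L]] <- row
    if (!is.null(out_csv))
      utils::write.table(row, out_csv, sep = ",", row.names = FALSE,
                         col.names = !file.exists(out_csv), append = file.exists(out_csv))
    if (verbose)
      message(sprintf("[%s] %s: peaks=%d m_B=%d m_C=%d (%.1f s)", id,
                      cond$ffl_type$label, cond$joint$n_peaks,
                      cond$marginal_B$n_modes, cond$marginal_C$n_modes,
                      cond$diagnostics$seconds))
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(as.character(out$id), as.character(manifest$condition))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Landscape response to input intensity
#'
#' Re-solves a condition over a range of A-synthesis rates `sA` (the input
#' intensity) and tabulates how the peak structure responds, pairing each
#' landscape with its mean-field fixed point for comparison.
#'
#' @param params Base [ffl_params()].
#' @param sA_values Input synthesis rates to scan.
#' @param rel_threshold Relative persistence threshold.
#' @return Data frame with one row per `sA`: topology summary columns as in
#'   [run_phase_diagram()] plus the mean-field `C` level `ode_C`.
#' @export
compare_input_intensity <- function(params, sA_values, rel_threshold = 0.01) {
  rows <- lapply(seq_along(sA_values), function(k) {
    p <- params
    p$sA <- sA_values[k]
    cond <- run_condition(p, rel_threshold = rel_threshold,
                          keep_landscape = FALSE)
    row <- condition_row(cond, id = sprintf("sA_%g", sA_values[k]))
    row$ode_C <- mean_field_steady_state(p, check_uniqueness = FALSE)$state[["C"]]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Landscape response to gene duplication
#'
#' Compares the single-copy network against duplicated gene copies
#' (`Nb`, `Nc` in 1 or 2). Extra copies add promoter occupancy
#' configurations and shift the accessible synthesis levels, reshaping the
#' number and position of probability peaks.
#'
#' @param params Base [ffl_params()] (its `Nb`, `Nc` are overridden).
#' @param copies Data frame or matrix with columns `Nb`, `Nc`; default all
#'   four combinations of 1 and 2.
#' @param rel_threshold Relative persistence threshold.
#' @param caps Optional fixed truncation caps (default: per-condition
#'   heuristic).
#' @return Data frame, one row per copy-number combination, with the
#'   topology summary columns of [run_phase_diagram()].
#' @export
compare_duplication <- function(params, copies = NULL, rel_threshold = 0.01,
                                caps = NULL) {
  if (is.null(copies)) copies <- expand.grid(Nb = 1:2, Nc = 1:2)
  rows <- lapply(seq_len(nrow(copies)), function(k) {
    p <- params
    p$Nb <- copies$Nb[k]; p$Nc <- copies$Nc[k]
    cond <- run_condition(p, caps = caps, rel_threshold = rel_threshold,
                          keep_landscape = FALSE)
    condition_row(cond, id = sprintf("Nb%d_Nc%d", p$Nb, p$Nc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- tabular output --------------------------------------------------------

#' Write a landscape or persistence diagram to a text table
#'
#' `write_landscape()` writes the joint steady-state distribution as a
#' tab-separated table with one microstate per row (columns: the state
#' coordinates over [ffl_species()] and `prob`), skipping states below
#' `min_prob` to keep files reviewable. `write_persistence()` writes a
#' persistence diagram with the representative state coordinates resolved.
#'
#' @param landscape An `ffl_landscape`.
#' @param path Output file path.
#' @param min_prob Rows with smaller probability are omitted (default
#'   1e-12).
#' @return The path, invisibly.
#' @export
write_landscape <- function(landscape, path, min_prob = 1e-12) {
  stopifnot(inherits(landscape, "ffl_landscape"), !is.null(landscape$space))
  keep <- which(landscape$p >= min_prob)
  st <- index_state(landscape$space, keep)
  df <- data.frame(st, prob = landscape$p[keep])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @param diagram An `ffl_persistence`.
#' @param space The `ffl_state_space` the diagram was computed on (omit for
#'   marginal diagrams; representatives are then written as `index - 1`,
#'   the copy number).
#' @export
write_persistence <- function(diagram, path, space = NULL) {
  stopifnot(inherits(diagram, "ffl_persistence"))
  df <- data.frame(peak_id = seq_len(nrow(diagram)),
                   birth = diagram$birth, death = diagram$death,
                   persistence = diagram$persistence,
                   essential = diagram$essential)
  if (!is.null(space)) {
    df <- cbind(df, index_state(space, diagram$representative))
  } else {
    df$position <- diagram$representative - 1L
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
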