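test_that("run_condition assembles a coherent summary at small caps", {
  cond <- run_condition(ffl_params(1.2, 1.2, 1.2), caps = c(25, 28, 28))
  expect_s3_class(cond, "ffl_condition")
  expect_equal(cond$ffl_type$label, "C1")
  expect_equal(cond$joint$n_peaks, 1)
  expect_equal(cond$marginal_B$n_modes, 1)
  expect_equal(cond$marginal_C$n_modes, 1)
  expect_equal(sum(cond$marginal_C$prob), 1, tolerance = 1e-12)
  expect_lt(cond$diagnostics$residual,
            1e-9 * cond$diagnostics$n_states^0)  # certified solve
  expect_equal(cond$diagnostics$n_states, 6 * 26 * 29 * 29)
  # peak state coordinates are resolvable microstates
  expect_equal(ncol(cond$joint$peak_states), 9)
})

test_that("phase diagram sweeps are tabulated, resumable and deterministic", {
  g <- parameter_grid(k1 = c(1, 2), base = ffl_params())
  # small fixed caps keep this a seconds-scale sweep; the topology columns
  # still have definite values
  caps <- c(25, 30, 30)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  # run only the first condition, then resume
  g1 <- structure(list(g[[1]]), manifest = attr(g, "manifest")[1, ],
                  class = c("ffl_grid", "list"))
  t1 <- run_phase_diagram(g1, out_csv = f, caps = caps, verbose = FALSE)
  expect_equal(nrow(t1), 1)
  expect_true(file.exists(f))
  t2 <- run_phase_diagram(g, out_csv = f, caps = caps, verbose = FALSE)
  expect_equal(nrow(t2), 2)
  expect_equal(t2$id, c("c0001", "c0002"))
  # resumed first row identical to the fresh computation
  t3 <- run_phase_diagram(g, out_csv = NULL, caps = caps, verbose = FALSE)
  expect_equal(t2$joint_peaks, t3$joint_peaks)
  expect_equal(t2$m_C, t3$m_C)
  expect_true(all(c("k1", "ffl_type", "residual", "boundary_mass",
                    "modes_C") %in% names(t2)))
})

test_that("landscape and persistence tables round-trip", {
  cond <- run_condition(ffl_params(1.2, 1.2, 1.2), caps = c(10, 12, 12))
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  write_landscape(cond$landscape, f1, min_prob = 1e-9)
  tab <- read.delim(f1)
  expect_true(all(c("A", "B", "C", "bA", "prob") %in% names(tab)))
  expect_equal(sum(tab$prob), 1, tolerance = 1e-6)  # only tiny states dropped
  # probabilities re-indexable to the landscape
  sp <- cond$landscape$space
  idx <- state_index(sp, as.matrix(tab[, ffl_species()]))
  expect_equal(tab$prob, cond$landscape$p[idx])
  write_persistence(cond$joint$diagram, f2, space = sp)
  d <- read.csv(f2)
  expect_equal(nrow(d), nrow(cond$joint$diagram))
  expect_true(all(c("peak_id", "birth", "death", "persistence", "C") %in% names(d)))
})

test_that("duplication sweep covers the copy-number combinations", {
  tab <- compare_duplication(ffl_params(1, 1, 1),
                             copies = data.frame(Nb = c(1, 2), Nc = c(1, 1)))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$id, c("Nb1_Nc1", "Nb2_Nc1"))
  expect_equal(tab$Nb, c(1, 2))
  # doubling gene b doubles the accessible B synthesis: mean mode moves up
  m1 <- as.integer(strsplit(tab$modes_B[1], ";")[[1]])
  m2 <- as.integer(strsplit(tab$modes_B[2], ";")[[1]])
  expect_gt(max(m2), max(m1))
})
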