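test_that("default parameters are the generic slow-promoter case", {
  p <- ffl_params()
  expect_equal(c(p$sA, p$sB, p$sC), c(10, 10, 10))
  expect_equal(c(p$dA, p$dB, p$dC), c(1, 1, 1))
  expect_equal(c(p$rbA, p$rcA, p$rcB), c(0.005, 0.005, 0.005))
  expect_equal(c(p$fbA, p$fcA, p$fcB), c(0.1, 0.1, 0.1))
  expect_equal(c(p$Nb, p$Nc), c(1L, 1L))
})

test_that("invalid parameters are rejected", {
  expect_error(ffl_params(k1 = 0), "positive")
  expect_error(ffl_params(k2 = -1))
  expect_error(ffl_params(sA = NA), "finite")
  expect_error(ffl_params(sA = -2), "non-negative")
  expect_error(ffl_params(Nb = 3), "1 or 2")
  expect_error(ffl_params(Nc = 0), "1 or 2")
})

test_that("all eight FFL types classify to their octants", {
  expect_equal(classify_ffl_type(1.2, 1.2, 1.2)$label, "C1")
  expect_equal(classify_ffl_type(0.5, 1.2, 0.5)$label, "C2")
  expect_equal(classify_ffl_type(1.2, 0.5, 0.5)$label, "C3")
  expect_equal(classify_ffl_type(0.5, 0.5, 1.2)$label, "C4")
  expect_equal(classify_ffl_type(3.0, 0.025, 5.1)$label, "I1")
  expect_equal(classify_ffl_type(0.5, 0.5, 0.5)$label, "I2")
  expect_equal(classify_ffl_type(1.2, 1.2, 0.5)$label, "I3")
  expect_equal(classify_ffl_type(0.5, 1.2, 1.2)$label, "I4")
  expect_true(classify_ffl_type(1.2, 1.2, 1.2)$coherent)
  expect_false(classify_ffl_type(3.0, 0.025, 5.1)$coherent)
  # boundary: exactly 1 counts as activating
  expect_equal(classify_ffl_type(1, 1, 1)$label, "C1")
  expect_error(classify_ffl_type(0, 1, 1), "positive")
})

test_that("coherence equals an even number of inhibiting edges", {
  for (k1 in c(0.5, 2)) for (k2 in c(0.5, 2)) for (k3 in c(0.5, 2)) {
    cls <- classify_ffl_type(k1, k2, k3)
    n_inhib <- sum(c(k1, k2, k3) < 1)
    expect_identical(cls$coherent, n_inhib %% 2 == 0)
    expect_identical(startsWith(cls$label, "C"), cls$coherent)
  }
})

test_that("scale_binding scales rate pairs and preserves affinity", {
  p0 <- ffl_params(3.0, 0.025, 5.1)
  p <- scale_binding(p0, c("cA", "cB"), 16)
  expect_equal(c(p$rcA, p$fcA, p$rcB, p$fcB), c(0.08, 1.6, 0.08, 1.6))
  expect_equal(c(p$rbA, p$fbA), c(p0$rbA, p0$fbA))  # untouched pair
  expect_equal(p$rcA / p$fcA, p0$rcA / p0$fcA)      # affinity invariant
  expect_equal(p$n, 16)
  expect_error(scale_binding(p0, "xy", 2), "subset")
  expect_error(scale_binding(p0, character(0), 2), "empty")
  expect_error(scale_binding(p0, "cA", -1), "positive")
})

test_that("parameter_grid expands deterministically with first axis slowest", {
  g <- parameter_grid(k1 = c(0.8, 2.4), k2 = c(0.5, 1.0, 2.0))
  expect_length(g, 6)
  m <- attr(g, "manifest")
  expect_equal(m$k1, rep(c(0.8, 2.4), each = 3))
  expect_equal(m$k2, rep(c(0.5, 1.0, 2.0), times = 2))
  expect_equal(m$condition, sprintf("c%04d", 1:6))
  expect_true(all(c("ffl_type", "rbA", "Nb") %in% names(m)))
  expect_equal(m$ffl_type[1], classify_ffl_type(0.8, 0.5, 1)$label)
  expect_error(parameter_grid(), "no grid axes")
  expect_error(parameter_grid(zz = 1), "unknown parameter")
})

test_that("grid manifests round-trip through CSV", {
  g <- parameter_grid(k3 = c(0.5, 2))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_grid_manifest(g, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$k3, c(0.5, 2))
  expect_equal(back$condition, c("c0001", "c0002"))
})
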