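test_that("two-state switch matches the closed form", {
  r <- 0.005; f <- 0.1
  M <- Matrix::Matrix(c(-r, r, f, -f), 2, 2, sparse = TRUE)
  p <- solve_steady_state(M)$p
  expect_equal(p, c(f, r) / (r + f), tolerance = 1e-10)
})

test_that("truncated birth-death matches the truncated Poisson closed form", {
  s <- 10; d <- 1; N <- 25
  x <- 0:N
  diag_out <- -(c(rep(s, N), 0) + d * x)
  M <- Matrix::bandSparse(N + 1, N + 1, k = c(-1, 0, 1),
                          diagonals = list(rep(s, N), diag_out, d * (1:N)))
  p <- solve_steady_state(M)$p
  ref <- dpois(x, s / d); ref <- ref / sum(ref)
  expect_lt(max(abs(p - ref)), 1e-10)
})

test_that("structured solver agrees with the dense null space", {
  sm <- small_landscape()
  expect_lte(sm$space$n, 5000)
  p_direct <- sm$landscape$p                                  # direct path
  p_struct <- solve_steady_state(sm$gen, direct_limit = 0)$p  # structured
  expect_lt(max(abs(p_direct - p_struct)), 1e-9)
  # and against a base-R dense null-space solve
  Md <- as.matrix(sm$gen$M)
  A <- Md; A[nrow(A), ] <- 1
  ref <- solve(A, c(rep(0, nrow(A) - 1), 1))
  expect_lt(max(abs(p_direct - ref)), 1e-9)
})

test_that("landscapes are normalised, non-negative and residual-certified", {
  sm <- small_landscape()
  ls <- sm$landscape
  expect_equal(sum(ls$p), 1, tolerance = 1e-12)
  expect_true(all(ls$p >= 0))
  expect_lt(ls$residual, 1e-10 * max(abs(Matrix::diag(sm$gen$M))))
})

test_that("reducible chains are rejected with component information", {
  # two disconnected 2-state chains: stationary distribution not unique
  blk <- matrix(c(-1, 1, 2, -2), 2, 2)
  M <- Matrix::bdiag(blk, blk)
  expect_error(solve_steady_state(M), "reducible")
  expect_error(solve_steady_state(Matrix::Matrix(1:4, 2, 2, sparse = TRUE)),
               "conservative")
})

test_that("neutral regulation gives exact product-form truncated Poissons", {
  net <- build_ffl_network(ffl_params(1, 1, 1))
  sp <- enumerate_states(net, caps = c(30, 32, 34))
  ls <- solve_steady_state(build_generator(sp))
  for (ax in c("A", "B", "C")) {
    m <- marginalize(ls, ax)$prob
    ref <- dpois(0:(length(m) - 1), 10); ref <- ref / sum(ref)
    expect_lt(max(abs(m - ref)), 1e-9)
  }
  # protein coordinates are independent: joint 2-d marginal factorises
  mBC <- marginalize(ls, c("B", "C"))$prob
  mB <- marginalize(ls, "B")$prob; mC <- marginalize(ls, "C")$prob
  expect_lt(max(abs(mBC - outer(mB, mC))), 1e-10)
})

test_that("marginalize validates its axes and preserves mass", {
  sm <- small_landscape()
  expect_error(marginalize(sm$landscape, character(0)), "empty")
  expect_error(marginalize(sm$landscape, "Z"), "unknown")
  expect_error(marginalize(sm$landscape, c("A", "B", "C")), "two axes")
  for (ax in list("A", "C", c("A", "B"), "bA", "cB"))
    expect_equal(sum(marginalize(sm$landscape, ax)$prob), 1,
                 tolerance = 1e-12)
  # gene-occupancy marginal of a single-copy gene is a two-point law
  mb <- marginalize(sm$landscape, "bA")$prob
  expect_length(mb, 2)
  expect_named(mb, c("0", "1"))
})

test_that("moments match direct summation", {
  sm <- small_landscape()
  mo <- moments(sm$landscape, "A")
  m <- marginalize(sm$landscape, "A")$prob
  x <- as.numeric(names(m))
  expect_equal(mo$mean, sum(x * m))
  expect_equal(mo$variance, sum(x^2 * m) - sum(x * m)^2, tolerance = 1e-12)
})

test_that("boundary mass flags inadequate truncation", {
  net <- build_ffl_network(ffl_params())
  tight <- solve_steady_state(build_generator(enumerate_states(net, caps = c(6, 7, 7))))
  expect_true(any(boundary_mass(tight)$flagged))  # caps cut into the bulk
  wide <- solve_steady_state(build_generator(enumerate_states(net, caps = c(40, 40, 40))))
  expect_false(any(boundary_mass(wide)$flagged))
  expect_lt(boundary_mass(wide)$total, 1e-10)
})
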