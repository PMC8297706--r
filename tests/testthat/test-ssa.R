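test_that("seeded trajectories are exactly reproducible", {
  net <- build_ffl_network(ffl_params(1.2, 1.2, 1.2))
  set.seed(42); t1 <- simulate_ssa(net, t_end = 20)
  set.seed(42); t2 <- simulate_ssa(net, t_end = 20)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$states, t2$states)
  set.seed(43); t3 <- simulate_ssa(net, t_end = 20)
  expect_false(identical(t1$times, t3$times))
})

test_that("trajectories respect stoichiometry and conservation", {
  net <- build_ffl_network(ffl_params(0.5, 2, 0.5, Nb = 2, Nc = 2))
  set.seed(1)
  tr <- simulate_ssa(net, t_end = 30)
  s <- tr$states
  expect_true(all(s >= 0))
  expect_true(all(s[, "b"] + s[, "bA"] == 2))
  expect_true(all(s[, "c"] + s[, "cA"] + s[, "cB"] == 2))
  expect_true(all(s[, "a"] == 1))
  # per-event jumps match the stoichiometry of the recorded reaction
  labels <- vapply(net$reactions, `[[`, "", "label")
  for (k in seq_len(min(50, length(tr$reactions)))) {
    r <- net$reactions[[match(tr$reactions[k], labels)]]
    expect_equal(unname(s[k + 1, ] - s[k, ]), unname(r$s))
  }
})

test_that("empirical distribution is the exact occupancy measure", {
  # hand-checkable fixture: two events, no burn-in
  tr <- structure(list(times = c(0, 1, 3), t_end = 4,
                       states = cbind(A = c(0L, 1L, 0L)),
                       reactions = c("x", "y"), absorbed = FALSE),
                  class = "ffl_trajectory")
  p <- empirical_distribution(tr, "A", burn_in = 0)
  expect_equal(unname(p), c(2, 2) / 4)  # A=0 for [0,1)+[3,4), A=1 for [1,3)
  expect_error(empirical_distribution(tr, "A", burn_in = 5), "burn_in")
})

test_that("SSA marginals converge in total variation to the exact landscape", {
  # birth-death fixture: isolate protein A (no regulation needed)
  net <- build_ffl_network(ffl_params())
  exact <- dpois(0:60, 10); exact <- exact / sum(exact)
  set.seed(7)
  h_short <- ssa_histogram(net, t_end = 600, species = "A", burn_in = 100,
                           caps = 60)
  set.seed(7)
  h_long <- ssa_histogram(net, t_end = 600, species = "A", burn_in = 100,
                          caps = 60, n_traj = 50)
  tv <- function(p, q) 0.5 * sum(abs(p - q))
  tv_short <- tv(h_short, exact)
  tv_long <- tv(h_long, exact)
  expect_lt(tv_long, tv_short)     # more sampling, closer
  expect_lt(tv_long, 0.03)
})

test_that("streaming histogram agrees with the trajectory-based estimate", {
  net <- build_ffl_network(ffl_params())
  set.seed(5)
  h <- ssa_histogram(net, t_end = 200, species = "A", burn_in = 50, caps = 60)
  set.seed(5)
  tr <- simulate_ssa(net, t_end = 200)
  e <- empirical_distribution(tr, "A", burn_in = 50)
  common <- seq_len(min(length(h), length(e)))
  expect_equal(unname(h[common]), unname(e[common]), tolerance = 1e-10)
})

test_that("two-species histograms are joint distributions", {
  net <- build_ffl_network(ffl_params(3, 6, 3.6))
  set.seed(9)
  h <- ssa_histogram(net, t_end = 300, species = c("B", "C"), burn_in = 50,
                     caps = c(80, 120))
  expect_equal(dim(h), c(81, 121))
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_true(all(h >= 0))
})
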