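test_that("the worked 1-d example gives the textbook diagram", {
  d <- superlevel_persistence(c(0.1, 0.3, 0.1, 0.4, 0.1))
  expect_equal(nrow(d), 2)
  expect_equal(d$birth, c(0.4, 0.3))
  expect_equal(d$death, c(0.0, 0.1))
  expect_equal(d$essential, c(TRUE, FALSE))
  expect_equal(d$representative, c(4L, 2L))
  expect_equal(count_peaks(d), 2)
})

test_that("the global maximum is always essential", {
  for (seed in 1:5) {
    rl <- random_landscape(c(30, 30), seed)
    d <- superlevel_persistence(rl$heights, rl$adjacency)
    expect_true(d$essential[which.max(d$birth)])
    expect_equal(sum(d$essential), 1)  # lattice is connected
  }
})

test_that("plateaus count once, ties resolve to the smaller index", {
  # truncated Poisson(10): p(9) == p(10) exactly, one mode reported at 9
  m <- poisson_landscape(10, 30)
  expect_equal(m[10], m[11])
  mod <- marginal_modality(m)
  expect_equal(mod$n_modes, 1)
  expect_equal(mod$modes, 9)
  # flat-top ridge inside a vector
  d <- superlevel_persistence(c(0.1, 0.5, 0.5, 0.5, 0.1))
  expect_equal(nrow(d), 1)
  expect_equal(d$representative, 2L)
})

test_that("persistence diagram equals the exhaustive-threshold oracle", {
  # classes alive at level r (born >= r, dying below) must equal the
  # number of connected components of the superlevel subgraph at r
  check <- function(h, adj) {
    d <- superlevel_persistence(h, adj)
    for (r in sort(unique(h))) {
      alive <- sum(d$birth >= r & (d$death < r | d$essential))
      expect_identical(alive, brute_force_components(h, r, adj))
    }
  }
  set.seed(404)
  for (k in 1:60) {
    n <- sample(5:200, 1)
    check(runif(n), NULL)  # 1-d path
  }
  for (k in 1:40) {
    dims <- sample(3:12, 2, replace = TRUE)
    rl <- random_landscape(dims, seed = 1000 + k)
    check(rl$heights, rl$adjacency)
  }
  # and one 3-d lattice fixture of 10 x 10 x 10
  rl <- random_landscape(c(10, 10, 10), seed = 7)
  check(rl$heights, rl$adjacency)
})

test_that("monotone rescaling scales the diagram and preserves counts", {
  rl <- random_landscape(c(15, 15), seed = 11)
  d1 <- superlevel_persistence(rl$heights, rl$adjacency)
  c_ <- 3.7
  d2 <- superlevel_persistence(c_ * rl$heights, rl$adjacency)
  expect_equal(d2$birth, c_ * d1$birth)
  expect_equal(d2$death, c_ * d1$death)
  expect_equal(d2$representative, d1$representative)
  thr <- 0.3 * max(d1$birth)
  expect_equal(count_peaks(d2, threshold = c_ * thr),
               count_peaks(d1, threshold = thr))
})

test_that("a threshold above max birth leaves only essential classes", {
  rl <- random_landscape(c(20, 20), seed = 3)
  d <- superlevel_persistence(rl$heights, rl$adjacency)
  expect_equal(count_peaks(d, threshold = max(d$birth) * 2), 1)
})

test_that("peak count at threshold zero equals local-maximum plateaus", {
  set.seed(12)
  h <- runif(300)  # continuous draws: no plateaus, strict local maxima
  d <- superlevel_persistence(h)
  n_max <- sum(h > c(-Inf, h[-300]) & h > c(h[-1], -Inf))
  expect_equal(count_peaks(d, threshold = 0), n_max)
})

test_that("mixture landscapes have the designed number of modes", {
  m2 <- mixture_landscape(c(5, 40), c(0.5, 0.5), 80)
  expect_equal(marginal_modality(m2)$n_modes, 2)
  m3 <- mixture_landscape(c(3, 30, 70), c(1, 1, 1), 120)
  expect_equal(marginal_modality(m3)$n_modes, 3)
  expect_equal(marginal_modality(poisson_landscape(7.5, 40))$n_modes, 1)
})

test_that("2-d marginal modality locates modes on the grid", {
  m <- outer(mixture_landscape(c(4, 20), c(1, 1), 30),
             poisson_landscape(6, 25))
  mod <- marginal_modality(m)
  expect_equal(mod$n_modes, 2)
  # Poisson(6) has an exact plateau at 5 and 6 (tie resolves to 5); the
  # upper mixture component peaks at 19 because the Poisson(4) tail breaks
  # the 19/20 plateau of Poisson(20) toward the smaller count
  expect_equal(mod$modes[, 2], c(5, 5))
  expect_equal(mod$modes[, 1], c(4, 19))
})

test_that("adjacency constructors are sane", {
  A <- lattice_adjacency(c(3, 2))
  expect_equal(dim(A), c(6, 6))
  expect_equal(sum(A > 0), 2 * (2 * 2 + 3 * 1))  # edges counted both ways
  expect_true(Matrix::isSymmetric(A))
  sm <- small_landscape()
  G <- generator_adjacency(sm$gen)
  expect_true(Matrix::isSymmetric(G * 1))
  expect_equal(sum(Matrix::diag(G) != 0), 0)
})

test_that("invalid heights are rejected", {
  expect_error(superlevel_persistence(numeric(0)), "empty")
  expect_error(superlevel_persistence(c(0.1, -0.2)), "non-negative")
  expect_error(superlevel_persistence(c(0.1, NA)), "finite")
  expect_error(superlevel_persistence(c(0.1, 0.2), lattice_adjacency(3)),
               "dimension")
})
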