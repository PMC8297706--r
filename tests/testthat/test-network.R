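test_that("the FFL network has the 15 expected reactions", {
  net <- build_ffl_network(ffl_params(1.2, 1.2, 1.2))
  labels <- vapply(net$reactions, `[[`, "", "label")
  expect_length(labels, 15)
  expect_setequal(labels, c("bind_bA", "unbind_bA", "bind_cA", "unbind_cA",
                            "bind_cB", "unbind_cB", "syn_A", "deg_A",
                            "syn_B", "syn_B_bA", "deg_B",
                            "syn_C", "syn_C_cB", "syn_C_cA", "deg_C"))
  expect_equal(net$species, c("A", "B", "C", "a", "b", "c", "bA", "cA", "cB"))
})

test_that("every reaction conserves gene totals", {
  net <- build_ffl_network(ffl_params(0.5, 2, 0.5, Nb = 2, Nc = 2))
  for (r in net$reactions) {
    expect_identical(unname(r$s["a"]), 0L)
    expect_identical(unname(r$s["b"] + r$s["bA"]), 0L)
    expect_identical(unname(r$s["c"] + r$s["cA"] + r$s["cB"]), 0L)
  }
})

test_that("regulated synthesis rates carry the fold changes", {
  p <- ffl_params(3.0, 0.025, 5.1)
  net <- build_ffl_network(p)
  rates <- vapply(net$reactions, `[[`, 0, "rate")
  labels <- vapply(net$reactions, `[[`, "", "label")
  expect_equal(rates[labels == "syn_B_bA"], p$sB * 3.0, ignore_attr = TRUE)
  expect_equal(rates[labels == "syn_C_cB"], p$sC * 0.025, ignore_attr = TRUE)
  expect_equal(rates[labels == "syn_C_cA"], p$sC * 5.1, ignore_attr = TRUE)
})

test_that("propensities follow mass action at hand-checked states", {
  p <- ffl_params()
  net <- build_ffl_network(p)
  x <- initial_state(net)
  x["A"] <- 4L; x["B"] <- 2L
  byl <- function(l) net$reactions[[which(
    vapply(net$reactions, `[[`, "", "label") == l)]]
  expect_equal(propensity(byl("bind_bA"), x), 0.005 * 1 * 4)
  expect_equal(propensity(byl("bind_cB"), x), 0.005 * 1 * 2)
  expect_equal(propensity(byl("unbind_bA"), x), 0)   # nothing bound
  expect_equal(propensity(byl("syn_A"), x), 10)
  expect_equal(propensity(byl("deg_A"), x), 4)
  x2 <- x; x2["b"] <- 0L; x2["bA"] <- 1L
  expect_equal(propensity(byl("bind_bA"), x2), 0)
  expect_equal(propensity(byl("unbind_bA"), x2), 0.1)
  expect_equal(propensity(byl("syn_B_bA"), x2), 10)  # k1 = 1
})

test_that("initial state reflects gene copy numbers", {
  net <- build_ffl_network(ffl_params(Nb = 2, Nc = 1))
  x <- initial_state(net)
  expect_equal(unname(x[c("a", "b", "c")]), c(1L, 2L, 1L))
  expect_true(all(x[c("A", "B", "C", "bA", "cA", "cB")] == 0L))
})
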