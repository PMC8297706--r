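test_that("occupancy configurations enumerate correctly", {
  expect_equal(nrow(gene_configs(1, 1)), 6)     # 2 x 3
  expect_equal(nrow(gene_configs(2, 1)), 9)     # 3 x 3
  expect_equal(nrow(gene_configs(1, 2)), 12)    # 2 x 6
  expect_equal(nrow(gene_configs(2, 2)), 18)    # 3 x 6
  cfg <- gene_configs(1, 1)
  expect_true(all(cfg[, "xb"] + cfg[, "xbA"] == 1))
  expect_true(all(cfg[, "xc"] + cfg[, "xcA"] + cfg[, "xcB"] == 1))
  # pinned order: b-states major; gene-c states ascending in (xcA, xcB)
  expect_equal(unname(cfg[1, ]), c(1L, 0L, 1L, 0L, 0L))
  expect_equal(unname(cfg[2, ]), c(1L, 0L, 0L, 0L, 1L))
  expect_equal(unname(cfg[6, ]), c(0L, 1L, 0L, 1L, 0L))
})

test_that("state counts match the closed-form product", {
  net <- build_ffl_network(ffl_params())
  expect_equal(enumerate_states(net, caps = c(1, 1, 1))$n, 6 * 8)   # 48
  expect_equal(enumerate_states(net, caps = c(0, 0, 0))$n, 6)
  expect_equal(enumerate_states(net, caps = c(3, 1, 0))$n, 6 * 4 * 2 * 1)
  net2 <- build_ffl_network(ffl_params(Nb = 2, Nc = 2))
  expect_equal(enumerate_states(net2, caps = c(1, 1, 1))$n, 18 * 8)
  expect_error(enumerate_states(net, caps = c(300, 300, 300)),
               "too large")
  expect_error(enumerate_states(net, caps = c(-1, 2, 2)))
})

test_that("cap heuristic covers the largest conditional Poisson mean", {
  caps <- truncation_caps(ffl_params(3.0, 6.0, 3.6))
  lam <- c(10, 30, 60)
  expect_equal(unname(caps), as.integer(ceiling(lam + 8 * sqrt(lam) + 10)))
  expect_true(caps["B"] >= 65 && caps["C"] >= 110)
  # inhibiting folds never shrink the caps below the basal mean
  expect_equal(truncation_caps(ffl_params(0.1, 0.2, 0.3)),
               truncation_caps(ffl_params()))
})

test_that("state indexing round-trips and follows the pinned order", {
  net <- build_ffl_network(ffl_params())
  sp <- enumerate_states(net, caps = c(2, 3, 4))
  # round trip over the whole space
  st <- index_state(sp, seq_len(sp$n))
  expect_equal(state_index(sp, st), seq_len(sp$n))
  # xC varies fastest, then xB, then xA, then the occupancy block
  expect_equal(unname(diff(st[1:5, "C"])), rep(1L, 4))
  expect_equal(unname(st[1 + sp$dims[3], "B"] - st[1, "B"]), 1L)
  i0 <- state_index(sp, initial_state(net))
  expect_equal(i0, 1L)  # unbound zero-protein state is first
  # out-of-range states map to NA
  bad <- initial_state(net); bad["C"] <- 5L
  expect_true(is.na(state_index(sp, bad)))
})

test_that("truncated chain is strongly connected at workable caps", {
  net <- build_ffl_network(ffl_params())
  sp <- enumerate_states(net, caps = c(3, 3, 3))
  gen <- build_generator(sp)
  rep <- reachable_check(sp, gen)
  expect_true(rep$connected)
  expect_length(rep$unreachable, 0)
})

test_that("degenerate caps disconnect the bound configurations", {
  net <- build_ffl_network(ffl_params())
  sp <- enumerate_states(net, caps = c(0, 2, 2))  # A can never exist
  gen <- build_generator(sp)
  rep <- reachable_check(sp, gen)
  expect_false(rep$connected)
  expect_gt(length(rep$unreachable), 0)
  cfgs <- index_state(sp, rep$unreachable)
  expect_true(all(cfgs[, "bA"] + cfgs[, "cA"] + cfgs[, "cB"] > 0))
})
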