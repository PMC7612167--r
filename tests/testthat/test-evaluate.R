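test_that("a single-block design reaches each state with the block pmf mass", {
  d <- block_design(r = 1, n = 8, block = 4, p0 = 0.3, p1 = 0.5)
  tab <- cp_table_nsc(d)
  reach <- reach_probabilities(tab, 0.25, 0.45)
  expect_length(reach, 1L)
  expect_equal(reach[[1]], unname(block_success_pmf(4, 0.25, 0.45)))
})

test_that("absorbed stopping mass is conserved", {
  designs <- list(
    block_design(r = 2, n = 20, theta_f = 0.15, theta_e = 0.9,
                 p0 = 0.3, p1 = 0.5),
    block_design(r = 1, n = 24, block = 2, theta_f = 0.3, theta_e = 0.8,
                 p0 = 0.2, p1 = 0.4))
  for (d in designs) {
    tab <- cp_table_sc(d)
    for (rates in list(c(0.3, 0.3), c(0.3, 0.5), c(0.1, 0.9))) {
      ev <- scblock:::eval_at_rates(tab, rates[1], rates[2])
      expect_equal(sum(ev$stop_dist$prob), 1, tolerance = 1e-12)
    }
  }
})

test_that("first-passage probabilities and characteristics match path enumeration", {
  d <- block_design(r = 1, n = 8, theta_f = 0.3, theta_e = 0.9,
                    p0 = 0.3, p1 = 0.5)
  tab <- cp_table_sc(d)
  for (rates in list(c(0.3, 0.3), c(0.3, 0.5), c(0.6, 0.2))) {
    oracle <- oracle_trial_eval(tab, rates[1], rates[2])
    reach <- reach_probabilities(tab, rates[1], rates[2])
    ev <- scblock:::eval_at_rates(tab, rates[1], rates[2])
    for (j in seq_along(reach)) {
      # the forward recursion propagates continue mass only; enumeration
      # reaches exactly the same first-passage probabilities
      expect_equal(reach[[j]], oracle$reach[[j]], tolerance = 1e-14)
    }
    expect_equal(ev$ess, oracle$ess, tolerance = 1e-13)
    expect_equal(ev$reject, oracle$reject, tolerance = 1e-14)
  }
})

test_that("stochastic curtailment never increases expected sample size", {
  for (row in published_block_rows_main()[c(1, 4)]) {
    d_sc <- build_published(row)
    d_nsc <- block_design(r = row$r, n = row$n, block = row$block,
                          p0 = row$p0, p1 = row$p1)
    oc_sc <- operating_characteristics(d_sc)
    oc_nsc <- operating_characteristics(d_nsc)
    expect_lte(oc_sc$ess00, oc_nsc$ess00)
    expect_lte(oc_sc$ess01, oc_nsc$ess01)
  }
})

test_that("rejection probability is monotone in the true response rates", {
  d <- block_design(r = 2, n = 20, theta_f = 0.1, theta_e = 0.95,
                    p0 = 0.3, p1 = 0.5)
  tab <- cp_table_sc(d)
  ps <- seq(0.1, 0.9, by = 0.2)
  for (pc in ps) {
    rej <- vapply(ps, function(pt) scblock:::eval_at_rates(tab, pc, pt)$reject,
                  numeric(1))
    expect_true(all(diff(rej) >= -1e-12))   # non-decreasing in pt
  }
  for (pt in ps) {
    rej <- vapply(ps, function(pc) scblock:::eval_at_rates(tab, pc, pt)$reject,
                  numeric(1))
    expect_true(all(diff(rej) <= 1e-12))    # non-increasing in pc
  }
})

test_that("a certain success stream stops at the earliest go boundary", {
  d <- build_published(published_block_rows_main()[[1]])
  oc <- operating_characteristics(d, pc = 0, pt = 1)
  expect_equal(oc$reject, 1, tolerance = 1e-12)
  # every block contributes 2B successes, so the first go-reachable block
  # is hit with certainty
  go_ns <- oc$stop_dist$n[oc$stop_dist$decision == "go"]
  expect_equal(oc$ess, min(go_ns))
})

test_that("operating characteristics expose feasibility of a published design", {
  d <- build_published(published_block_rows_main()[[1]])
  oc <- operating_characteristics(d)
  expect_lte(oc$alpha_star, 0.15)
  expect_gte(oc$power, 0.80)
  expect_equal(oc$n, 116L)
  expect_equal(oc$min_stop, 8L)
  df <- as.data.frame(oc)
  expect_named(df, c("r", "n_arm", "n", "ess00", "ess01", "alpha_star",
                     "power", "theta_f", "theta_e", "min_stop"))
})
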