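test_that("the single-arm two-stage design reproduces its published row exactly", {
  d <- two_stage_design("simon", r1 = 2, n1 = 8, r = 10, n_arm = 28)
  expect_equal(round1(simon_eval(d, 0.3)$expected_n), 17.0)
  expect_equal(round1(simon_eval(d, 0.5)$expected_n), 25.1)
  # p = 0: zero responses certain, so the trial always stops at stage 1
  e0 <- simon_eval(d, 0)
  expect_equal(e0$pet, 1)
  expect_equal(e0$expected_n, 8)
  expect_equal(e0$reject, 0)
})

test_that("the randomised two-stage design reproduces its published rows exactly", {
  d <- two_stage_design("jung", r1 = 0, n1 = 22, r = 5, n_arm = 46)
  expect_equal(round1(jung_eval(d, 0.3, 0.3)$expected_n), 64.9)
  expect_equal(round1(jung_eval(d, 0.3, 0.5)$expected_n), 86.7)
  expect_lte(jung_eval(d, 0.3, 0.3)$reject, 0.15)
  expect_gte(jung_eval(d, 0.3, 0.5)$reject, 0.80)
  # negative interim boundaries are representable
  d2 <- two_stage_design("jung", r1 = -1, n1 = 28, r = 5, n_arm = 41)
  expect_equal(round1(jung_eval(d2, 0.3, 0.3)$expected_n), 70.5)
  expect_equal(round1(jung_eval(d2, 0.3, 0.5)$expected_n), 80.8)
})

test_that("with no possible interim stop the two-arm design is a single-stage test", {
  n1 <- 5; n_arm <- 9; r <- 2
  # continuing requires the interim difference to exceed r1; the smallest
  # attainable difference is -n1, so r1 = -n1 - 1 disables the interim
  d <- two_stage_design("jung", r1 = -n1 - 1, n1 = n1, r = r, n_arm = n_arm)
  for (rates in list(c(0.5, 0.5), c(0.3, 0.6))) {
    ev <- jung_eval(d, rates[1], rates[2])
    expect_equal(ev$expected_n, 2 * n_arm)
    # single-stage oracle: P(XT - XC >= r) by direct convolution
    direct <- 0
    for (a in 0:n_arm) for (b in 0:n_arm)
      if (a - b >= r)
        direct <- direct + dbinom(a, n_arm, rates[2]) * dbinom(b, n_arm, rates[1])
    expect_equal(ev$reject, direct, tolerance = 1e-12)
  }
})

test_that("a certain pair-success stream stops at exactly r pairs", {
  d <- two_stage_design("carsten", r1 = 2, n1 = 5, r = 4, n_arm = 10)
  ev <- carsten_eval(d, pc = 0, pt = 1)      # ps = 1
  expect_equal(ev$reject, 1)
  expect_equal(ev$expected_n, 2 * d$r)
})

test_that("the paired-success dynamic programme matches path enumeration", {
  designs <- list(
    two_stage_design("carsten", 1, 3, 3, 7),
    two_stage_design("carsten", 2, 4, 4, 8),
    two_stage_design("carsten", 0, 2, 2, 5))
  for (d in designs) for (rates in list(c(0.3, 0.3), c(0.3, 0.6), c(0.1, 0.8))) {
    ev <- carsten_eval(d, rates[1], rates[2])
    or <- oracle_carsten(d, rates[1], rates[2])
    expect_equal(ev$reject, or$reject, tolerance = 1e-13)
    expect_equal(ev$expected_n, or$expected_n, tolerance = 1e-13)
  }
})

test_that("paired-success rejection probability is monotone in the pair success rate", {
  d <- two_stage_design("carsten", 2, 6, 5, 12)
  ps <- seq(0.05, 0.95, by = 0.1)
  rej <- vapply(ps, function(p) carsten_eval(d, pc = 0, pt = p)$reject,
                numeric(1))
  expect_true(all(diff(rej) >= -1e-12))
})

test_that("an unreachable final boundary always curtails to a no-go", {
  d <- two_stage_design("chen", r1 = 0, n1 = 2, r = 6, n_arm = 5)
  ev <- chen_eval(d, 0.3, 0.9)
  expect_equal(ev$reject, 0)
})

test_that("the per-patient dynamic programme matches path enumeration", {
  designs <- list(
    two_stage_design("chen", 0, 2, 1, 5),
    two_stage_design("chen", 1, 3, 2, 6),
    two_stage_design("chen", -1, 2, 2, 4))
  for (d in designs) for (rates in list(c(0.3, 0.3), c(0.2, 0.6))) {
    ev <- chen_eval(d, rates[1], rates[2])
    or <- oracle_chen(d, rates[1], rates[2])
    expect_equal(ev$reject, or$reject, tolerance = 1e-13)
    expect_equal(ev$expected_n, or$expected_n, tolerance = 1e-13)
  }
})

test_that("each exact dynamic programme agrees with its seeded Monte Carlo", {
  designs <- list(
    two_stage_design("simon", 2, 8, 10, 28),
    two_stage_design("jung", 0, 22, 5, 46),
    two_stage_design("carsten", 5, 19, 12, 44),
    two_stage_design("chen", 0, 16, 5, 45))
  for (d in designs) {
    exact <- comparator_eval(d, 0.3, 0.3)
    mc <- comparator_simulate(d, 0.3, 0.3, nreps = 10000, seed = 99)
    expect_lt(abs(mc$reject - exact$reject),
              3 * max(mc$se_reject, 1e-4))
    expect_lt(abs(mc$expected_n - exact$expected_n), 3 * mc$se_n)
  }
})

test_that("comparator admissible search returns feasible, non-dominated designs", {
  ctx <- design_context(0.3, 0.5, alpha = 0.25, beta = 0.3)
  adm <- comparator_admissible("carsten", ctx, n_range = c(10, 40))
  expect_gt(nrow(adm), 0)
  expect_true(all(adm$alpha_star <= ctx$alpha))
  expect_true(all(adm$power >= 1 - ctx$beta))
  expect_equal(nrow(pareto_filter(adm)), nrow(adm))
  expect_true(all(adm$design_type == "carsten"))
})
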