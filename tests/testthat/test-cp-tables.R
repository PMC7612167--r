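tiny_design <- function(theta_f = 0, theta_e = 1)
  block_design(r = 1, n = 8, block = 1, theta_f = theta_f,
               theta_e = theta_e, p0 = 0.3, p1 = 0.5)

test_that("final analysis classifies by the final difference boundary", {
  d <- tiny_design()
  tab <- cp_table_nsc(d)
  M <- d$n / 2
  final <- tab$values[[length(tab$values)]]
  # rejection iff XT - XC > r, i.e. successes >= M + r + 1
  expect_equal(final, as.numeric(0:(2 * M) >= M + d$r + 1))
})

test_that("go-certain interim states have conditional power one", {
  d <- block_design(r = 2, n = 12, p0 = 0.3, p1 = 0.5)
  tab <- cp_table_nsc(d)
  M <- d$n / 2
  for (j in seq_along(tab$m)) {
    m <- tab$m[j]
    S <- 0:(2 * m)
    expect_true(all(tab$values[[j]][S >= M + d$r + 1] == 1))
  }
})

test_that("NSC conditional power equals exhaustive path enumeration", {
  for (r in c(0, 1, 2)) {
    d <- block_design(r = r, n = 8, p0 = 0.3, p1 = 0.5)
    tab <- cp_table_nsc(d)
    expect_equal(tab$values, oracle_nsc_cp(d), tolerance = 1e-14)
  }
  # a larger case still within enumeration reach
  d <- block_design(r = 1, n = 12, p0 = 0.2, p1 = 0.6)
  expect_equal(cp_table_nsc(d)$values, oracle_nsc_cp(d), tolerance = 1e-14)
})

test_that("thresholds at 0 and 1 reduce stochastic to non-stochastic curtailment", {
  for (row in published_block_rows_main()[c(1, 2)]) {
    d <- block_design(r = row$r, n = row$n, block = row$block,
                      theta_f = 0, theta_e = 1, p0 = row$p0, p1 = row$p1)
    expect_identical(cp_table_sc(d)$values, cp_table_nsc(d)$values)
  }
})

test_that("lowering theta_e just below an interior value creates a go state and raises ancestors", {
  d <- tiny_design()
  nsc <- cp_table_nsc(d)
  ints <- interior_cp_values(nsc)
  target <- max(ints)
  d2 <- block_design(r = 1, n = 8, theta_f = 0, theta_e = target - 1e-9,
                     p0 = 0.3, p1 = 0.5)
  sc <- cp_table_sc(d2)
  for (j in seq_along(nsc$values)) {
    was_target <- nsc$values[[j]] == target
    expect_true(all(sc$values[[j]][was_target] == 1))
    # curtailing for efficacy can only increase conditional power anywhere
    expect_true(all(sc$values[[j]] >= nsc$values[[j]] - 1e-14))
  }
})

test_that("conditional power is monotone in successes and confined by thresholds", {
  cases <- list(
    block_design(r = 2, n = 20, p0 = 0.3, p1 = 0.5,
                 theta_f = 0.1, theta_e = 0.9),
    block_design(r = 1, n = 24, block = 2, p0 = 0.2, p1 = 0.4,
                 theta_f = 0.2, theta_e = 0.85),
    block_design(r = 3, n = 36, block = 3, p0 = 0.5, p1 = 0.7,
                 theta_f = 0.05, theta_e = 0.95))
  for (d in cases) {
    for (tab in list(cp_table_nsc(d), cp_table_sc(d))) {
      for (v in tab$values) {
        expect_true(all(diff(v) >= -1e-14))        # non-decreasing in S
        expect_true(all(v >= 0 & v <= 1))
      }
    }
    sc <- cp_table_sc(d)
    interior <- interior_cp_values(sc)
    expect_true(all(interior >= d$theta_f & interior <= d$theta_e))
  }
})

test_that("threshold misordering is rejected", {
  expect_error(block_design(r = 1, n = 8, theta_f = 0.8, theta_e = 0.5,
                            p0 = 0.3, p1 = 0.5),
               "theta_f < theta_e")
})

test_that("long-format export carries one row per block-end state", {
  d <- tiny_design(theta_f = 0.2, theta_e = 0.9)
  df <- as.data.frame(cp_table_sc(d))
  expect_named(df, c("m", "S", "cp", "decision"))
  expect_equal(nrow(df), sum(2 * (1:4) + 1))
  expect_true(all(df$decision[df$cp == 1] == "go"))
  expect_true(all(df$decision[df$cp == 0] == "no-go"))
  expect_true(all(df$decision[df$cp > 0 & df$cp < 1] == "continue"))
  path <- tempfile(fileext = ".csv")
  write_cp_table(cp_table_sc(d), path)
  expect_equal(read.csv(path)$cp, df$cp)
})
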