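# Exhaustive-enumeration oracles for tiny designs (B = 1).  These walk every
# per-block (XT, XC) outcome sequence explicitly and never use the package's
# recursions, so they provide an independent ground truth.

# conditional power at every block-end state, ignoring early stopping:
# P(final successes >= N/2 + r + 1 | S successes after m per arm)
oracle_nsc_cp <- function(design) {
  stopifnot(design$block == 1L)
  M <- design$n / 2L
  r <- design$r
  p0 <- design$context$p0
  p1 <- design$context$p1
  xt <- c(0L, 1L, 0L, 1L)
  xc <- c(0L, 0L, 1L, 1L)
  pr <- dbinom(xt, 1, p1) * dbinom(xc, 1, p0)
  ds <- xt + 1L - xc
  rec <- function(S, m) {
    if (m == M) return(as.numeric(S >= M + r + 1L))
    tot <- 0
    for (k in 1:4) tot <- tot + pr[k] * rec(S + ds[k], m + 1L)
    tot
  }
  lapply(1:M, function(m) vapply(0:(2L * m), rec, numeric(1), m = m))
}

# evaluate a trial defined by an arbitrary decision table (stop where
# cp == 0 or 1) by walking every outcome path under true rates (pc, pt)
oracle_trial_eval <- function(table, pc, pt) {
  design <- table$design
  stopifnot(design$block == 1L)
  nb <- length(table$m)
  xt <- c(0L, 1L, 0L, 1L)
  xc <- c(0L, 0L, 1L, 1L)
  pr <- dbinom(xt, 1, pt) * dbinom(xc, 1, pc)
  ds <- xt + 1L - xc
  reach <- lapply(1:nb, function(j) numeric(2L * j + 1L))
  ess <- 0
  reject <- 0
  rec <- function(S, j, prob) {
    for (k in 1:4) {
      p <- prob * pr[k]
      if (p == 0) next
      S2 <- S + ds[k]
      reach[[j]][S2 + 1L] <<- reach[[j]][S2 + 1L] + p
      v <- table$values[[j]][S2 + 1L]
      if (v == 0 || v == 1) {
        ess <<- ess + 2 * j * p
        if (v == 1) reject <<- reject + p
      } else {
        rec(S2, j + 1L, p)
      }
    }
  }
  rec(0L, 1L, 1)
  list(ess = ess, reject = reject, reach = reach)
}

# curtailed paired-success design by explicit recursion over pair outcomes
oracle_carsten <- function(design, pc, pt) {
  ps <- pt * (1 - pc)
  r1 <- design$r1; n1 <- design$n1; r <- design$r; np <- design$n_arm
  ess <- 0; reject <- 0
  rec <- function(s, j, prob) {
    for (succ in c(0L, 1L)) {
      p <- prob * if (succ == 1L) ps else 1 - ps
      if (p == 0) next
      s2 <- s + succ
      stop_go <- s2 >= r
      stop_ng <- (j <= n1 && s2 + (n1 - j) < r1) || (s2 + (np - j) < r)
      if (stop_go || stop_ng || j == np) {
        ess <<- ess + 2 * j * p
        if (stop_go) reject <<- reject + p
      } else rec(s2, j + 1L, p)
    }
  }
  rec(0L, 1L, 1)
  list(expected_n = ess, reject = reject)
}

# per-patient curtailed difference design by explicit recursion over
# patient outcomes (allocation alternates starting on treatment)
oracle_chen <- function(design, pc, pt) {
  r1 <- design$r1; n1 <- design$n1; r <- design$r
  N <- 2L * design$n_arm
  k_int <- 2L * n1; s_int <- n1 + r1; goal <- design$n_arm + r
  ess <- 0; reject <- 0
  rec <- function(s, k, prob) {
    pk <- if ((k + 1L) %% 2L == 1L) pt else 1 - pc
    for (succ in c(0L, 1L)) {
      p <- prob * if (succ == 1L) pk else 1 - pk
      if (p == 0) next
      k2 <- k + 1L
      s2 <- s + succ
      stop_go <- s2 >= goal
      stop_ng <- (s2 + (N - k2) < goal) ||
        (k2 <= k_int && s2 + (k_int - k2) < s_int)
      if (stop_go || stop_ng || k2 == N) {
        ess <<- ess + k2 * p
        if (stop_go) reject <<- reject + p
      } else rec(s2, k2, p)
    }
  }
  rec(0L, 0L, 1)
  list(expected_n = ess, reject = reject)
}
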