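#' First-passage probabilities of block-end states
#'
#' Forward probability recursion under true response rates
#' \code{(pc, pt)}: the mass at the first block end is the block success
#' distribution; mass then propagates from \emph{continue} states only,
#' convolved with the block distribution, while go and no-go states absorb.
#' The result is the probability that the trial is still running and first
#' reaches each state -- exactly the quantities needed for expected sample
#' size and rejection probability, with stopped paths counted once.
#'
#' @param table a \code{"cp_table"} (from \code{\link{cp_table_sc}} or
#'   \code{\link{cp_table_nsc}}).
#' @param pc,pt true response rates on control and treatment.
#' @return List of numeric vectors parallel to \code{table$values}:
#'   element \code{S + 1} of block \code{j} is the first-passage
#'   probability of state \eqn{(S, m_j)}.
#' @export
reach_probabilities <- function(table, pc, pt) {
  stopifnot(inherits(table, "cp_table"))
  d <- table$design
  B <- d$block
  pmf <- block_success_pmf(B, pc, pt)
  nb <- length(table$values)
  reach <- vector("list", nb)
  reach[[1L]] <- as.numeric(pmf)
  if (nb > 1L) for (j in 1:(nb - 1L)) {
    v <- table$values[[j]]
    w <- reach[[j]]
    cont <- w * (v > 0 & v < 1)
    m <- table$m[j]
    nxt <- numeric(2L * (m + B) + 1L)
    idx <- 0:(2L * m)
    for (i in 0:(2L * B))
      nxt[idx + i + 1L] <- nxt[idx + i + 1L] + cont * pmf[i + 1L]
    reach[[j + 1L]] <- nxt
  }
  reach
}

## ESS / rejection probability / stopping distribution at one rate pair.
eval_at_rates <- function(table, pc, pt) {
  reach <- reach_probabilities(table, pc, pt)
  nb <- length(reach)
  ess <- 0; rej <- 0
  stop_m <- integer(0); stop_dec <- character(0); stop_p <- numeric(0)
  for (j in 1:nb) {
    v <- table$values[[j]]
    w <- reach[[j]]
    m <- table$m[j]
    go <- v == 1; ng <- v == 0
    pgo <- sum(w[go]); png <- sum(w[ng])
    ess <- ess + 2 * m * (pgo + png)
    rej <- rej + pgo
    if (pgo > 0 || png > 0) {
      stop_m <- c(stop_m, 2L * m, 2L * m)
      stop_dec <- c(stop_dec, "go", "no-go")
      stop_p <- c(stop_p, pgo, png)
    }
  }
  keep <- stop_p > 0
  list(ess = ess, reject = rej,
       stop_dist = data.frame(n = stop_m[keep], decision = stop_dec[keep],
                              prob = stop_p[keep], stringsAsFactors = FALSE))
}

## Smallest total sample size at which the trial can terminate, from the
## structure of the table alone: a stop state counts if a chain of continue
## states can lead to it (every block increment 0..2B is possible on some
## sample path).
min_stop_size <- function(table) {
  nb <- length(table$values)
  B <- table$design$block
  reachable <- rep(TRUE, 2L * B + 1L)   # all first-block states attainable
  for (j in 1:nb) {
    v <- table$values[[j]]
    if (any(reachable & (v == 0 | v == 1))) return(2L * table$m[j])
    if (j < nb) {
      m <- table$m[j]
      cont <- reachable & v > 0 & v < 1
      nxt <- rep(FALSE, 2L * (m + B) + 1L)
      idx <- which(cont) - 1L
      for (i in 0:(2L * B)) nxt[idx + i + 1L] <- TRUE
      reachable <- nxt
    }
  }
  2L * table$m[nb]
}

#' Exact operating characteristics of a block design
#'
#' Evaluates a design realisation exactly: type I error
#' \eqn{\alpha^* = P(reject \mid p_0, p_0)}, power
#' \eqn{1 - \beta^* = P(reject \mid p_0, p_1)}, expected sample sizes (both
#' arms counted) under the null and alternative anticipated rates, the
#' smallest possible terminating sample size, and the full stopping-point
#' distribution.  All quantities come from the backward conditional-power
#' recursion and the forward first-passage recursion; nothing is simulated.
#'
#' If \code{pc} and \code{pt} are supplied, the expected sample size,
#' rejection probability and stopping distribution are additionally
#' reported under those true rates (the design's boundaries are unchanged).
#'
#' @param design a \code{\link{block_design}}.
#' @param pc,pt optional true response rates for an additional evaluation.
#' @param table optionally, a precomputed \code{\link{cp_table_sc}} for
#'   \code{design} (saves recomputation in loops).
#' @return An object of class \code{"op_chars"}: list with
#'   \code{alpha_star}, \code{power}, \code{ess00}, \code{ess01},
#'   \code{n}, \code{min_stop}, \code{stop_dist00}, \code{stop_dist01},
#'   \code{design}, and -- when \code{pc, pt} are given -- \code{ess},
#'   \code{reject}, \code{stop_dist} at those rates.
#' @examples
#' d <- block_design(r = 5, n = 116, theta_f = 0.1348, theta_e = 0.9831,
#'                   p0 = 0.3, p1 = 0.5, snap = TRUE)
#' operating_characteristics(d)
#' @export
operating_characteristics <- function(design, pc = NULL, pt = NULL,
                                      table = NULL) {
  stopifnot(inherits(design, "block_design"))
  if (is.null(table)) table <- cp_table_sc(design)
  ctx <- design$context
  e00 <- eval_at_rates(table, ctx$p0, ctx$p0)
  e01 <- eval_at_rates(table, ctx$p0, ctx$p1)
  out <- list(alpha_star = e00$reject, power = e01$reject,
              ess00 = e00$ess, ess01 = e01$ess,
              n = design$n, min_stop = min_stop_size(table),
              stop_dist00 = e00$stop_dist, stop_dist01 = e01$stop_dist,
              design = design)
  if (!is.null(pc) || !is.null(pt)) {
    if (is.null(pc) || is.null(pt))
      stop("supply both 'pc' and 'pt', or neither")
    ex <- eval_at_rates(table, pc, pt)
    out$pc <- pc; out$pt <- pt
    out$ess <- ex$ess; out$reject <- ex$reject; out$stop_dist <- ex$stop_dist
  }
  structure(out, class = "op_chars")
}

## display rounding: 1 decimal place, half-up (as in published tables)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.op_chars <- function(x, ...) {
  cat("Exact operating characteristics\n")
  cat(sprintf("  alpha* = %.4f, power = %.4f\n", x$alpha_star, x$power))
  cat(sprintf("  ESS(p0,p0) = %.1f, ESS(p0,p1) = %.1f, max N = %d, min stop = %d\n",
              round_half_up(x$ess00), round_half_up(x$ess01), x$n, x$min_stop))
  if (!is.null(x$reject))
    cat(sprintf("  at true rates (%g, %g): P(reject) = %.4f, ESS = %.1f\n",
                x$pc, x$pt, x$reject, round_half_up(x$ess)))
  invisible(x)
}

#' @export
as.data.frame.op_chars <- function(x, ...) {
  d <- x$design
  data.frame(r = d$r, n_arm = d$n / 2L, n = d$n,
             ess00 = x$ess00, ess01 = x$ess01,
             alpha_star = x$alpha_star, power = x$power,
             theta_f = d$theta_f, theta_e = d$theta_e,
             min_stop = x$min_stop)
}
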