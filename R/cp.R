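#' Conditional-power tables
#'
#' \code{cp_table_nsc} computes, for every block-end state \eqn{(S, m)},
#' the conditional power \eqn{CP(S, m)}: the probability of ultimately
#' rejecting \eqn{H_0}, given \eqn{S} successes after \eqn{m} participants
#' per arm, computed at the anticipated rates \eqn{(p_0, p_1)} (there is no
#' re-estimation of response rates).  Under non-stochastic curtailment the
#' trial stops only when the decision is certain, i.e. when \eqn{CP} is
#' exactly 0 or 1.
#'
#' The table is built by backward recursion from the final analysis
#' \eqn{m = N/2}, where \eqn{CP = 1} iff \eqn{S \ge N/2 + r + 1}
#' (equivalently \eqn{X_T - X_C > r}).  At earlier block ends,
#' \eqn{CP = 1} when \eqn{S \ge N/2 + r + 1} (go certain), \eqn{CP = 0}
#' when \eqn{2m - S \ge N/2 - r} (no-go certain: even an all-success future
#' cannot push the final difference past \code{r}), and otherwise
#' \deqn{D = \sum_{i=0}^{2B} P(i, B | p_0, p_1) \; CP(S + i, m + B).}
#'
#' \code{cp_table_sc} additionally applies stochastic curtailment during
#' the backward pass: an interior value \eqn{D < \theta_F} is rounded down
#' to 0 (no-go) and \eqn{D > \theta_E} is rounded up to 1 (go); values with
#' \eqn{\theta_F \le D \le \theta_E} are retained as continue states.  The
#' rounded values feed the sums of earlier blocks, so the resulting table
#' is the exact description of the curtailed trial and the operating
#' characteristics derived from it carry no approximation.  Comparisons
#' against the thresholds are strict (equality continues) and use no
#' epsilon: thresholds are meant to be drawn from the attainable
#' conditional-power grid itself (see \code{\link{snap_thresholds}} and
#' \code{\link{candidate_thresholds}}), which keeps search and evaluation
#' in exact agreement.
#'
#' @param design a \code{\link{block_design}}; \code{cp_table_sc} uses its
#'   \code{theta_f} and \code{theta_e}, \code{cp_table_nsc} ignores them.
#' @return An object of class \code{"cp_table"}: a list with elements
#'   \code{values} (list of numeric vectors, one per block end \code{m};
#'   element \code{S + 1} holds \eqn{CP(S, m)}), \code{m} (the block ends),
#'   \code{type} (\code{"nsc"} or \code{"sc"}) and \code{design}.
#'   Use \code{as.data.frame()} for the long format with a
#'   \code{decision} column (\code{"go"} iff \eqn{CP = 1}, \code{"no-go"}
#'   iff \eqn{CP = 0}, else \code{"continue"}).
#' @examples
#' d <- block_design(r = 1, n = 8, p0 = 0.3, p1 = 0.5)
#' tab <- cp_table_nsc(d)
#' head(as.data.frame(tab))
#' @export
cp_table_nsc <- function(design) {
  stopifnot(inherits(design, "block_design"))
  build_cp_table(design, theta_f = 0, theta_e = 1, type = "nsc")
}

#' @rdname cp_table_nsc
#' @export
cp_table_sc <- function(design) {
  stopifnot(inherits(design, "block_design"))
  if (!(design$theta_f < design$theta_e))
    stop("stochastic curtailment requires theta_f < theta_e")
  build_cp_table(design, design$theta_f, design$theta_e, type = "sc")
}

## Backward pass.  Certainty masks are applied explicitly (not left to the
## recursion) so that go/no-go states hold exact 0/1 doubles rather than
## accumulated sums that merely approach them.
build_cp_table <- function(design, theta_f, theta_e, type) {
  r <- design$r; M <- design$n / 2L; B <- design$block
  nb <- M %/% B
  pmf <- block_success_pmf(B, design$context$p0, design$context$p1)
  values <- vector("list", nb)
  S <- 0:(2L * M)
  values[[nb]] <- as.numeric(S >= M + r + 1L)
  if (nb > 1L) for (j in (nb - 1L):1L) {
    m <- j * B
    S <- 0:(2L * m)
    nxt <- values[[j + 1L]]
    D <- numeric(2L * m + 1L)
    for (i in 0:(2L * B)) D <- D + pmf[i + 1L] * nxt[S + i + 1L]
    v <- D
    v[D < theta_f] <- 0
    v[D > theta_e] <- 1
    v[2L * m - S >= M - r] <- 0    # no-go certain
    v[S >= M + r + 1L] <- 1        # go certain
    values[[j]] <- v
  }
  structure(list(values = values, m = (1:nb) * B, type = type,
                 design = design),
            class = "cp_table")
}

#' Interior conditional-power values of a table
#'
#' The sorted unique conditional-power values strictly between 0 and 1
#' across all block-end states.  These are the attainable values from which
#' curtailment thresholds are drawn.
#'
#' @param table a \code{"cp_table"}.
#' @return Sorted numeric vector (possibly empty).
#' @export
interior_cp_values <- function(table) {
  stopifnot(inherits(table, "cp_table"))
  v <- sort(unique(unlist(table$values, use.names = FALSE)))
  v[v > 0 & v < 1]
}

cp_decision <- function(cp) {
  ifelse(cp == 1, "go", ifelse(cp == 0, "no-go", "continue"))
}

#' @export
as.data.frame.cp_table <- function(x, ...) {
  m <- rep.int(x$m, 2L * x$m + 1L)
  S <- unlist(lapply(x$m, function(mm) 0:(2L * mm)), use.names = FALSE)
  cp <- unlist(x$values, use.names = FALSE)
  data.frame(m = m, S = S, cp = cp, decision = cp_decision(cp),
             stringsAsFactors = FALSE)
}

#' @export
print.cp_table <- function(x, ...) {
  d <- x$design
  df <- as.data.frame(x)
  cat(sprintf("Conditional power table (%s) for r = %d, N = %d, B = %d\n",
              toupper(x$type), d$r, d$n, d$block))
  if (x$type == "sc")
    cat(sprintf("  theta_f = %.6g, theta_e = %.6g\n", d$theta_f, d$theta_e))
  tb <- table(df$decision)
  cat(sprintf("  %d block-end states: %s\n", nrow(df),
              paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Plot the stopping regions of a conditional-power table
#'
#' Draws every block-end state \eqn{(2m, S)} coloured by its decision:
#' go (blue), no-go (red) or continue (grey).
#'
#' @param x a \code{"cp_table"}.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.cp_table <- function(x, ...) {
  df <- as.data.frame(x)
  col <- c(go = "#2166AC", `no-go` = "#B2182B", continue = "grey70")
  graphics::plot(2 * df$m, df$S, col = col[df$decision], pch = 15, cex = 0.5,
                 xlab = "participants enrolled (both arms)",
                 ylab = "successes S(m)", ...)
  graphics::legend("topleft", legend = names(col), col = col, pch = 15,
                   bty = "n")
  invisible(x)
}

#' Export a conditional-power table as long-format CSV
#'
#' Columns \code{m, S, cp, decision}, one row per block-end state.
#'
#' @param table a \code{"cp_table"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cp_table <- function(table, path) {
  stopifnot(inherits(table, "cp_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
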