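#' Rejection-probability surface under misspecified response rates
#'
#' A design's stopping boundaries are fixed at the anticipated rates
#' \eqn{(p_0, p_1)}; if the true rates \eqn{(p_C, p_T)} differ, the
#' probability of rejecting \eqn{H_0} can depart considerably from the
#' nominal error rates.  This function evaluates the exact rejection
#' probability of a fixed design realisation over a grid of true rates,
#' with the boundaries unchanged.
#'
#' The surface is non-decreasing along \eqn{p_T} and non-increasing along
#' \eqn{p_C}; its diagonal cell at \eqn{(p_0, p_0)} equals the design's
#' \eqn{\alpha^*} and the cell at \eqn{(p_0, p_1)} its power.
#'
#' @param design a \code{\link{block_design}} or
#'   \code{\link{two_stage_design}}.
#' @param p_grid probabilities at which both true rates are evaluated
#'   (default \code{seq(0, 1, 0.1)}).
#' @return A numeric matrix; rows are indexed by \eqn{p_C}, columns by
#'   \eqn{p_T}, both named by the grid values.
#' @examples
#' d <- block_design(r = 3, n = 62, theta_f = 0.128, theta_e = 0.932,
#'                   p0 = 0.1, p1 = 0.3, snap = TRUE)
#' s <- rejection_surface(d, p_grid = c(0.2, 0.3))
#' s["0.3", "0.3"]  # about 0.34
#' @export
rejection_surface <- function(design, p_grid = seq(0, 1, by = 0.1)) {
  if (any(p_grid < 0 | p_grid > 1)) stop("'p_grid' values must lie in [0, 1]")
  if (inherits(design, "block_design")) {
    table <- cp_table_sc(design)
    f <- function(pc, pt) eval_at_rates(table, pc, pt)$reject
  } else if (inherits(design, "two_stage_design")) {
    f <- function(pc, pt) comparator_eval(design, pc, pt)$reject
  } else stop("'design' must be a block_design or two_stage_design")
  out <- matrix(NA_real_, length(p_grid), length(p_grid),
                dimnames = list(pC = format(p_grid), pT = format(p_grid)))
  for (i in seq_along(p_grid))
    for (j in seq_along(p_grid))
      out[i, j] <- f(p_grid[i], p_grid[j])
  out
}

#' Export a rejection surface as CSV
#'
#' Matrix layout mirroring the design's sensitivity figures: rows
#' \eqn{p_C}, columns \eqn{p_T}; cells below the diagonal correspond to a
#' treatment effect in the anticipated direction (\eqn{p_T > p_C}), cells
#' above it to a harmful treatment, and the diagonal to no effect.
#'
#' @param surface matrix from \code{\link{rejection_surface}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_rejection_surface <- function(surface, path) {
  df <- data.frame(pC = rownames(surface), surface, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
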