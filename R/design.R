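#' Hypothesis-test frame for a two-arm binary-outcome trial
#'
#' Bundles the anticipated response rates and error constraints that define
#' the testing problem: anticipated control and treatment response rates
#' \code{p0 < p1}, maximum type I error \code{alpha} under
#' \eqn{p_C = p_T = p_0} and maximum type II error \code{beta} under
#' \eqn{p_C = p_0, p_T = p_1}.  The null hypothesis is
#' \eqn{H_0: p_T \le p_C}.
#'
#' @param p0 anticipated control-arm response rate, in \[0, 1).
#' @param p1 anticipated treatment-arm response rate, in (\code{p0}, 1\].
#' @param alpha maximal type I error rate, in (0, 1).
#' @param beta maximal type II error rate, in (0, 1).
#'
#' @return An object of class \code{"design_context"}: a list with elements
#'   \code{p0}, \code{p1}, \code{alpha}, \code{beta}.
#' @examples
#' design_context(p0 = 0.3, p1 = 0.5)
#' @export
design_context <- function(p0, p1, alpha = 0.15, beta = 0.2) {
  stopifnot(is.numeric(p0), is.numeric(p1), is.numeric(alpha), is.numeric(beta),
            length(p0) == 1L, length(p1) == 1L, length(alpha) == 1L,
            length(beta) == 1L)
  if (!(p0 >= 0 && p0 < p1 && p1 <= 1))
    stop("require 0 <= p0 < p1 <= 1 (got p0 = ", p0, ", p1 = ", p1, ")")
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must lie in (0, 1)")
  if (!(beta > 0 && beta < 1)) stop("'beta' must lie in (0, 1)")
  structure(list(p0 = p0, p1 = p1, alpha = alpha, beta = beta),
            class = "design_context")
}

#' @export
print.design_context <- function(x, ...) {
  cat("Two-arm binary outcome testing frame\n")
  cat(sprintf("  H0: pT <= pC at anticipated rates (p0, p1) = (%g, %g)\n",
              x$p0, x$p1))
  cat(sprintf("  constraints: alpha <= %g, power >= %g\n",
              x$alpha, 1 - x$beta))
  invisible(x)
}

#' Specify a stochastically curtailed block-randomised design realisation
#'
#' A design realisation is characterised by the final stopping boundary
#' \code{r}, the maximum total sample size \code{n} (both arms), the number
#' of participants per arm per block \code{block} (so blocks hold
#' \code{2 * block} participants), and the conditional-power thresholds
#' \code{theta_f} (futility / no-go) and \code{theta_e} (efficacy / go).
#'
#' The trial rejects \eqn{H_0} when the final difference in responses
#' \eqn{X_T(n/2) - X_C(n/2)} \emph{exceeds} \code{r}.  Counting a "success"
#' as a treatment response or a control non-response,
#' \eqn{S(m) = X_T(m) + m - X_C(m)}, rejection at the final analysis is
#' equivalent to \eqn{S(n/2) \ge n/2 + r + 1}.  At the end of any earlier
#' block the trial stops for a go decision when rejection is certain
#' (\eqn{S(m) \ge n/2 + r + 1}) or the conditional power exceeds
#' \code{theta_e}, and for a no-go decision when rejection is impossible
#' (\eqn{2m - S(m) \ge n/2 - r}) or the conditional power falls below
#' \code{theta_f}.
#'
#' Thresholds reported to a few decimal places (as in published design
#' tables) should be snapped back onto the exact attainable
#' conditional-power grid with \code{snap = TRUE}; the search in
#' \code{\link{find_admissible}} draws candidate thresholds from that same
#' grid, so classification of a state against its threshold is exact, with
#' no epsilon comparisons.
#'
#' @param r final stopping boundary: the largest difference
#'   \eqn{X_T - X_C} that still fails to reject \eqn{H_0}.
#' @param n maximum total sample size over both arms; must be even and a
#'   multiple of \code{2 * block}.
#' @param block participants per arm per block (\code{B}); block size is
#'   \code{2 * block}.
#' @param theta_f lower conditional-power threshold for no-go curtailment,
#'   in \[0, 1).  \code{0} disables stochastic futility stopping.
#' @param theta_e upper conditional-power threshold for go curtailment, in
#'   (\code{theta_f}, 1\].  \code{1} disables stochastic efficacy stopping.
#' @param p0,p1,alpha,beta passed to \code{\link{design_context}}, or give
#'   \code{context} directly.
#' @param context a \code{\link{design_context}}; overrides
#'   \code{p0, p1, alpha, beta}.
#' @param snap snap \code{theta_f} and \code{theta_e} to the nearest
#'   attainable interior conditional-power value of the design's NSC table.
#'
#' @return An object of class \code{"block_design"}.
#' @examples
#' ## published p0-optimal realisation for (alpha, beta, p0, p1) =
#' ## (0.15, 0.2, 0.3, 0.5) with blocks of two
#' d <- block_design(r = 5, n = 116, block = 1, theta_f = 0.1348,
#'                   theta_e = 0.9831, p0 = 0.3, p1 = 0.5, snap = TRUE)
#' d
#' @export
block_design <- function(r, n, block = 1, theta_f = 0, theta_e = 1,
                         p0, p1, alpha = 0.15, beta = 0.2,
                         context = NULL, snap = FALSE) {
  if (is.null(context)) context <- design_context(p0, p1, alpha, beta)
  stopifnot(inherits(context, "design_context"))
  r <- as.integer(r); n <- as.integer(n); block <- as.integer(block)
  if (n < 2L || n %% 2L != 0L) stop("'n' must be a positive even integer")
  if (block < 1L || (n / 2L) %% block != 0L)
    stop("'block' must divide n/2 (got block = ", block, ", n = ", n, ")")
  if (r < 0L || r > n / 2L) stop("'r' must satisfy 0 <= r <= n/2")
  if (!(theta_f >= 0 && theta_f < theta_e && theta_e <= 1))
    stop("require 0 <= theta_f < theta_e <= 1")
  d <- structure(list(r = r, n = n, block = block,
                      theta_f = theta_f, theta_e = theta_e,
                      context = context),
                 class = "block_design")
  if (snap) d <- snap_thresholds(d)
  d
}

#' Snap thresholds to the attainable conditional-power grid
#'
#' Replaces \code{theta_f} and \code{theta_e} by the nearest interior
#' conditional-power values attainable in the design's NSC table.  Design
#' tables print thresholds rounded to 3--4 decimals; because stopping is
#' classified by exact comparison against the conditional-power grid, a
#' rounded threshold can misclassify the handful of states whose conditional
#' power falls between the printed and the exact value.  Snapping restores
#' the exact realisation.
#'
#' @param design a \code{\link{block_design}}.
#' @return The design with thresholds replaced (thresholds equal to the
#'   absorbing values 0 or 1 are kept as-is).
#' @export
snap_thresholds <- function(design) {
  stopifnot(inherits(design, "block_design"))
  nsc <- cp_table_nsc(design)
  cp <- interior_cp_values(nsc)
  if (length(cp)) {
    if (design$theta_f > 0)
      design$theta_f <- cp[which.min(abs(cp - design$theta_f))]
    if (design$theta_e < 1)
      design$theta_e <- cp[which.min(abs(cp - design$theta_e))]
  }
  if (design$theta_f >= design$theta_e)
    stop("snapping collapsed theta_f and theta_e onto the same grid value")
  design
}

#' @export
print.block_design <- function(x, ...) {
  ctx <- x$context
  cat("Stochastically curtailed block-randomised two-arm design\n")
  cat(sprintf("  r = %d, N = %d (%d per arm), block = %d per arm (%d analyses)\n",
              x$r, x$n, x$n / 2L, x$block, x$n / (2L * x$block)))
  cat(sprintf("  CP thresholds: theta_f = %.6g, theta_e = %.6g\n",
              x$theta_f, x$theta_e))
  cat(sprintf("  anticipated rates (p0, p1) = (%g, %g); alpha = %g, beta = %g\n",
              ctx$p0, ctx$p1, ctx$alpha, ctx$beta))
  invisible(x)
}

#' @export
summary.block_design <- function(object, ...) {
  oc <- operating_characteristics(object)
  structure(list(design = object, oc = oc), class = "summary.block_design")
}

#' @export
print.summary.block_design <- function(x, ...) {
  print(x$design)
  cat("\n")
  print(x$oc)
  invisible(x)
}
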