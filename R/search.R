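#' Configuration of an admissible-design search
#'
#' Bounds and grid limits for \code{\link{find_admissible}}.  Defaults
#' mirror the reference search: maximum total sample size 120, final
#' boundary range \eqn{r \in \{0, \dots, \lceil N p_1 \rceil\}} per
#' \eqn{N}, futility threshold capped at \eqn{p_1}
#' (\code{theta_f_max = NULL}), efficacy threshold floored at 0.7, and at
#' most \eqn{10^6} \eqn{(\theta_F, \theta_E)} pairs per \eqn{(r, N)}.
#'
#' @param max_n upper bound on the total sample size \code{N} (both arms).
#' @param block participants per arm per block.
#' @param r_range integer vector of final boundaries to search, or
#'   \code{NULL} for the default \code{0:ceiling(N * p1)} per \code{N}.
#' @param theta_f_max largest admissible futility threshold; \code{NULL}
#'   means "use the context's \code{p1}".
#' @param theta_e_min smallest admissible efficacy threshold.
#' @param max_combos maximum number of \eqn{(\theta_F, \theta_E)} pairs
#'   examined per \eqn{(r, N)}; when exceeded, the candidate grid is
#'   repeatedly halved (see \code{\link{candidate_thresholds}}).
#' @param n_values optional integer vector restricting the total sample
#'   sizes searched (each a multiple of \code{2 * block}); \code{NULL}
#'   searches every multiple up to \code{max_n}.
#' @return An object of class \code{"search_config"}.
#' @export
search_config <- function(max_n = 120, block = 1, r_range = NULL,
                          theta_f_max = NULL, theta_e_min = 0.7,
                          max_combos = 1e6, n_values = NULL) {
  max_n <- as.integer(max_n); block <- as.integer(block)
  if (max_n < 2L * block || max_n %% (2L * block) != 0L)
    stop("'max_n' must be a multiple of the block size 2 * block")
  if (!is.null(n_values)) {
    n_values <- as.integer(n_values)
    if (any(n_values < 2L * block | n_values %% (2L * block) != 0L |
            n_values > max_n))
      stop("'n_values' must be multiples of 2 * block, at most max_n")
  }
  if (!is.null(theta_f_max) && !(theta_f_max > 0 && theta_f_max < 1))
    stop("'theta_f_max' must lie in (0, 1)")
  if (!(theta_e_min > 0 && theta_e_min <= 1)) stop("'theta_e_min' must lie in (0, 1]")
  if (max_combos < 1) stop("'max_combos' must be >= 1")
  structure(list(max_n = max_n, block = block, r_range = r_range,
                 theta_f_max = theta_f_max, theta_e_min = theta_e_min,
                 max_combos = max_combos, n_values = n_values),
            class = "search_config")
}

## number of (f, e) pairs with f < e, f <= fmax, e >= emin over one sorted
## candidate vector
count_pairs <- function(vals, fmax, emin) {
  fv <- vals[vals <= fmax]
  ev <- vals[vals >= emin]
  if (!length(fv) || !length(ev)) return(0)
  ## for each f, admissible e are those >= emin and > f
  sum(length(ev) - findInterval(fv, ev))
}

#' Candidate curtailment thresholds for one (r, N, B)
#'
#' The operating characteristics of a curtailed design change only when a
#' threshold crosses one of the conditional-power values attainable in the
#' trial, so candidate thresholds are drawn from the interior
#' conditional-power values of the design's NSC table (pooled over all
#' block ends) rather than from a uniform grid.  Pairs must satisfy
#' \eqn{\theta_F < \theta_E}, \eqn{\theta_F \le} \code{theta_f_max} and
#' \eqn{\theta_E \ge} \code{theta_e_min}.  If more than
#' \code{cfg$max_combos} pairs result, the sorted candidate values are
#' thinned by deleting every other value (keeping the first, third,
#' \dots), repeatedly, until the pair count fits.
#'
#' @param nsc_table the \code{\link{cp_table_nsc}} of the \eqn{(r, N, B)}
#'   under consideration.
#' @param cfg a \code{\link{search_config}}.
#' @return A list with \code{theta_f}, \code{theta_e} (candidate value
#'   vectors; every pair with \eqn{\theta_F < \theta_E} is a candidate),
#'   \code{pairs} (two-column matrix of all candidate pairs) and
#'   \code{n_pairs}.
#' @export
candidate_thresholds <- function(nsc_table, cfg) {
  stopifnot(inherits(nsc_table, "cp_table"), inherits(cfg, "search_config"))
  fmax <- cfg$theta_f_max
  if (is.null(fmax)) fmax <- nsc_table$design$context$p1
  vals <- interior_cp_values(nsc_table)
  while (count_pairs(vals, fmax, cfg$theta_e_min) > cfg$max_combos)
    vals <- vals[seq(1L, length(vals), by = 2L)]
  fv <- vals[vals <= fmax]
  ev <- vals[vals >= cfg$theta_e_min]
  pairs <- if (length(fv) && length(ev)) {
    g <- expand.grid(theta_f = fv, theta_e = ev, KEEP.OUT.ATTRS = FALSE)
    as.matrix(g[g$theta_f < g$theta_e, , drop = FALSE])
  } else matrix(numeric(0), ncol = 2L,
                dimnames = list(NULL, c("theta_f", "theta_e")))
  rownames(pairs) <- NULL
  list(theta_f = fv, theta_e = ev, pairs = pairs, n_pairs = nrow(pairs))
}

#' Remove dominated designs
#'
#' A design is dominated when another design in the set is no worse on all
#' of \eqn{ESS(p_0,p_0)}, \eqn{ESS(p_0,p_1)} and \eqn{N}, and strictly
#' better on at least one.  Designs identical on all three criteria are
#' all retained.  The filter is idempotent and independent of row order.
#'
#' @param designs data frame with columns \code{ess00}, \code{ess01},
#'   \code{n}.
#' @return The non-dominated rows (original row order preserved).
#' @export
pareto_filter <- function(designs) {
  stopifnot(is.data.frame(designs),
            all(c("ess00", "ess01", "n") %in% names(designs)))
  nr <- nrow(designs)
  if (nr <= 1L) return(designs)
  crit <- cbind(designs$ess00, designs$ess01, designs$n)
  ord <- order(crit[, 1L], crit[, 2L], crit[, 3L])
  ## a dominator always sorts strictly earlier lexicographically, and is
  ## itself non-dominated, so sweeping forward against the kept front is
  ## exact
  front <- matrix(numeric(0), ncol = 3L)
  keep <- logical(nr)
  for (i in ord) {
    x <- crit[i, ]
    dominated <- FALSE
    if (nrow(front)) {
      le <- front[, 1L] <= x[1L] & front[, 2L] <= x[2L] & front[, 3L] <= x[3L]
      lt <- front[, 1L] < x[1L] | front[, 2L] < x[2L] | front[, 3L] < x[3L]
      dominated <- any(le & lt)
    }
    if (!dominated) {
      keep[i] <- TRUE
      if (!nrow(front) || !any(front[, 1L] == x[1L] & front[, 2L] == x[2L] &
                               front[, 3L] == x[3L]))
        front <- rbind(front, x)
    }
  }
  designs[keep, , drop = FALSE]
}

## label p0/p1-optimal and p0/p1-minimax rows; tie-breaks: smaller n, then
## smaller ESS at the other rate, then larger theta_e
label_admissible <- function(df) {
  pick <- function(cand, primary, other) {
    o <- order(cand[[primary]], cand$n, cand[[other]], -cand$theta_e)
    rownames(cand)[o[1L]]
  }
  labs <- setNames(vector("list", 4L),
                   c("p0_optimal", "p1_optimal", "p0_minimax", "p1_minimax"))
  labs$p0_optimal <- pick(df, "ess00", "ess01")
  labs$p1_optimal <- pick(df, "ess01", "ess00")
  mm <- df[df$n == min(df$n), , drop = FALSE]
  labs$p0_minimax <- pick(mm, "ess00", "ess01")
  labs$p1_minimax <- pick(mm, "ess01", "ess00")
  lab_col <- character(nrow(df))
  for (nm in names(labs)) {
    i <- match(labs[[nm]], rownames(df))
    lab_col[i] <- if (nzchar(lab_col[i]))
      paste(lab_col[i], nm, sep = "+") else nm
  }
  df$label <- lab_col
  df
}

#' Search for admissible stochastically curtailed block designs
#'
#' Enumerates \eqn{(r, N)} combinations with
#' \eqn{N \in \{2B, 4B, \dots,} \code{max_n}\eqn{\}}, draws candidate
#' \eqn{(\theta_F, \theta_E)} threshold pairs from each design's attainable
#' conditional-power grid (\code{\link{candidate_thresholds}}), evaluates
#' every curtailed design exactly, keeps the feasible ones
#' (\eqn{\alpha^* \le \alpha}, power \eqn{\ge 1 - \beta}) and removes
#' dominated designs (\code{\link{pareto_filter}}).  The surviving designs
#' are the admissible set; the \eqn{p_0}-/\eqn{p_1}-optimal (smallest
#' \eqn{ESS} under null / alternative rates) and minimax (smallest
#' \eqn{ESS} among designs of minimal \eqn{N}) realisations are labelled.
#'
#' The threshold grid is evaluated in compiled code; a full per-\eqn{(r,N)}
#' grid of several hundred thousand pairs evaluates in well under a minute
#' for \eqn{N \approx 120}, but a search over all \eqn{(r, N)} at
#' \code{max_n = 120} is hours of CPU -- restrict \code{r_range},
#' \code{max_n} or \code{max_combos} for interactive use.
#'
#' @param context a \code{\link{design_context}}.
#' @param cfg a \code{\link{search_config}}.
#' @param verbose print per-(r, N) progress.
#' @return An object of class \code{"admissible_set"}: a data frame with
#'   columns \code{r, n_arm, n, ess00, ess01, alpha_star, power, theta_f,
#'   theta_e, min_stop, label} (attributes \code{context} and \code{cfg}).
#'   Empty (zero rows, with a warning) when no feasible design exists.
#' @examples
#' \donttest{
#' ctx <- design_context(0.3, 0.5)
#' cfg <- search_config(max_n = 40, block = 1, max_combos = 500)
#' find_admissible(ctx, cfg)
#' }
#' @export
find_admissible <- function(context, cfg = search_config(), verbose = FALSE) {
  stopifnot(inherits(context, "design_context"),
            inherits(cfg, "search_config"))
  B <- cfg$block
  rows <- list()
  n_seq <- cfg$n_values
  if (is.null(n_seq)) n_seq <- seq(2L * B, cfg$max_n, by = 2L * B)
  for (N in n_seq) {
    r_range <- cfg$r_range
    if (is.null(r_range)) r_range <- 0:ceiling(N * context$p1)
    r_range <- r_range[r_range >= 0L & r_range <= N / 2L]
    for (r in r_range) {
      d0 <- block_design(r = r, n = N, block = B, context = context)
      nsc <- cp_table_nsc(d0)
      cand <- candidate_thresholds(nsc, cfg)
      if (cand$n_pairs == 0L) next
      tf <- cand$theta_f
      te <- cand$theta_e
      pmf1 <- block_success_pmf(B, context$p0, context$p1)
      pmf0 <- block_success_pmf(B, context$p0, context$p0)
      fea <- sc_grid_eval_cpp(r, N, B, as.numeric(pmf1), as.numeric(pmf0),
                              tf, te, context$alpha, context$beta)
      if (verbose)
        message(sprintf("r = %d, N = %d: %d candidate pairs, %d feasible",
                        r, N, cand$n_pairs, nrow(fea)))
      if (nrow(fea)) {
        fea$r <- r; fea$n <- N; fea$n_arm <- N / 2L
        ## per-(r, N) Pareto prefilter keeps the global pass cheap
        rows[[length(rows) + 1L]] <- pareto_filter(fea)
      }
    }
  }
  if (!length(rows)) {
    warning("no feasible design found under the given constraints")
    out <- data.frame(r = integer(0), n_arm = integer(0), n = integer(0),
                      ess00 = numeric(0), ess01 = numeric(0),
                      alpha_star = numeric(0), power = numeric(0),
                      theta_f = numeric(0), theta_e = numeric(0),
                      min_stop = integer(0), label = character(0))
    return(structure(out, class = c("admissible_set", "data.frame"),
                     context = context, cfg = cfg))
  }
  all <- do.call(rbind, rows)
  adm <- pareto_filter(all)
  rownames(adm) <- NULL
  adm$min_stop <- vapply(seq_len(nrow(adm)), function(i) {
    d <- block_design(r = adm$r[i], n = adm$n[i], block = B,
                      theta_f = adm$theta_f[i], theta_e = adm$theta_e[i],
                      context = context)
    min_stop_size(cp_table_sc(d))
  }, integer(1L))
  adm <- label_admissible(adm)
  adm <- adm[, c("r", "n_arm", "n", "ess00", "ess01", "alpha_star", "power",
                 "theta_f", "theta_e", "min_stop", "label")]
  rownames(adm) <- NULL
  structure(adm, class = c("admissible_set", "data.frame"),
            context = context, cfg = cfg)
}

#' @export
print.admissible_set <- function(x, ...) {
  ctx <- attr(x, "context")
  cat(sprintf("Admissible curtailed block designs (%d realisations)\n",
              nrow(x)))
  if (!is.null(ctx))
    cat(sprintf("  (p0, p1) = (%g, %g), alpha = %g, beta = %g\n",
                ctx$p0, ctx$p1, ctx$alpha, ctx$beta))
  if (nrow(x)) {
    y <- as.data.frame(x)
    y$ess00 <- round_half_up(y$ess00)
    y$ess01 <- round_half_up(y$ess01)
    y$alpha_star <- round(y$alpha_star, 4)
    y$power <- round(y$power, 4)
    y$theta_f <- round(y$theta_f, 4)
    y$theta_e <- round(y$theta_e, 4)
    print(y, row.names = FALSE)
  }
  invisible(x)
}
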