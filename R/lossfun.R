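#' Loss score of a design
#'
#' Weighted sum of the three optimality criteria,
#' \deqn{L = w_0\, ESS(p_0, p_0) + w_1\, ESS(p_0, p_1) + (1 - w_0 - w_1) N,}
#' with \eqn{w_0, w_1 \in [0, 1]} and \eqn{w_0 + w_1 \le 1}.  The corner
#' weights recover the individual criteria: \eqn{(1, 0)} scores
#' \eqn{ESS(p_0,p_0)}, \eqn{(0, 1)} scores \eqn{ESS(p_0,p_1)} and
#' \eqn{(0, 0)} scores \eqn{N}.
#'
#' @param chars an \code{"op_chars"} object, or anything with elements (or
#'   columns) \code{ess00}, \code{ess01}, \code{n}.
#' @param w0,w1 criterion weights.
#' @return The loss score (vectorised over rows when \code{chars} is a
#'   data frame).
#' @examples
#' loss_score(list(ess00 = 47.3, ess01 = 47.2, n = 116), 0.5, 0.5)
#' @export
loss_score <- function(chars, w0, w1) {
  stopifnot(is.numeric(w0), is.numeric(w1), length(w0) == 1L,
            length(w1) == 1L)
  if (w0 < 0 || w0 > 1 || w1 < 0 || w1 > 1 || w0 + w1 > 1)
    stop("weights must satisfy w0, w1 in [0, 1] and w0 + w1 <= 1")
  w0 * chars$ess00 + w1 * chars$ess01 + (1 - w0 - w1) * chars$n
}

#' Omni-admissible design map over the weight simplex
#'
#' For every weight point \eqn{(w_0, w_1)} on a regular grid over the
#' simplex \eqn{\{w_0 + w_1 \le 1\}}, each design approach contributes the
#' minimum loss score over its admissible set; the approach attaining the
#' overall minimum is the omni-admissible design at that point.  Because
#' the loss is linear in the weights, the winning regions of any two fixed
#' realisations are separated by straight lines.
#'
#' @param sets named list of admissible sets (data frames with columns
#'   \code{ess00}, \code{ess01}, \code{n}); names are the design types.
#' @param grid_step weight grid step (default 0.01, i.e. 5151 points).
#' @return A data frame with columns \code{w0}, \code{w1}, one loss column
#'   \code{loss_<type>} per approach (its best realisation's loss), and
#'   \code{winner} (ties joined with \code{"/"}).  Attribute
#'   \code{"area_fractions"}: named vector of grid fractions won per type,
#'   ties split equally; sums to 1.
#' @examples
#' a <- data.frame(ess00 = 50, ess01 = 48, n = 100)
#' b <- data.frame(ess00 = 55, ess01 = 44, n = 90)
#' m <- omni_admissible_map(list(block = a, chen = b), grid_step = 0.1)
#' attr(m, "area_fractions")
#' @export
omni_admissible_map <- function(sets, grid_step = 0.01) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a non-empty named list of admissible sets")
  for (nm in names(sets))
    if (!nrow(sets[[nm]]))
      stop("admissible set '", nm, "' is empty")
  w <- seq(0, 1, by = grid_step)
  grid <- expand.grid(w0 = w, w1 = w, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$w0 + grid$w1 <= 1 + 1e-12, ]
  rownames(grid) <- NULL
  types <- names(sets)
  loss <- matrix(NA_real_, nrow(grid), length(types),
                 dimnames = list(NULL, types))
  for (k in seq_along(types)) {
    s <- sets[[k]]
    ## linear in weights: evaluate all realisations, take the best
    L <- outer(grid$w0, s$ess00) + outer(grid$w1, s$ess01) +
      outer(1 - grid$w0 - grid$w1, s$n)
    loss[, k] <- apply(L, 1L, min)
  }
  best <- apply(loss, 1L, min)
  win <- loss <= best  # ties possible
  winner <- apply(win, 1L, function(z) paste(types[z], collapse = "/"))
  frac <- setNames(numeric(length(types)), types)
  share <- win / rowSums(win)
  frac[] <- colSums(share) / nrow(grid)
  out <- cbind(grid, setNames(as.data.frame(loss),
                              paste0("loss_", types)))
  out$winner <- winner
  attr(out, "area_fractions") <- frac
  out
}

#' Pairwise loss-difference surface
#'
#' Difference in best-of-type loss between two approaches over the weight
#' simplex (negative favours \code{type_a}).
#'
#' @param map output of \code{\link{omni_admissible_map}}.
#' @param type_a,type_b approach names present in \code{map}.
#' @return Data frame \code{w0, w1, loss_diff}.
#' @export
loss_difference <- function(map, type_a, type_b) {
  ca <- paste0("loss_", type_a); cb <- paste0("loss_", type_b)
  if (!all(c(ca, cb) %in% names(map)))
    stop("types not found in map: ", type_a, ", ", type_b)
  data.frame(w0 = map$w0, w1 = map$w1, loss_diff = map[[ca]] - map[[cb]])
}
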