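#' Exact distribution of block successes
#'
#' Distribution of the number of successes contributed by one randomised
#' block with \code{B} participants per arm, where a success is a response
#' on the treatment arm or a non-response on the control arm:
#' \eqn{S(B) = X_T(B) + B - X_C(B)} with \eqn{X_T \sim Binom(B, p_T)} and
#' \eqn{X_C \sim Binom(B, p_C)} independent.  Equivalently the convolution
#' of \eqn{Binom(B, p_T)} with \eqn{Binom(B, 1 - p_C)}.
#'
#' @param B participants per arm in the block (block size is \code{2B}).
#' @param pc true control-arm response rate.
#' @param pt true treatment-arm response rate.
#' @return Numeric vector of length \code{2B + 1}; element \code{i + 1} is
#'   \eqn{P(S(B) = i)} for \eqn{i = 0, \dots, 2B}, named by \code{i}.
#' @examples
#' block_success_pmf(1, pc = 0.3, pt = 0.5)
#' sum(block_success_pmf(4, 0.3, 0.5))  # 1
#' @export
block_success_pmf <- function(B, pc, pt) {
  stopifnot(length(B) == 1L, length(pc) == 1L, length(pt) == 1L)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("'B' must be a positive integer")
  if (!is.numeric(pc) || pc < 0 || pc > 1) stop("'pc' must lie in [0, 1]")
  if (!is.numeric(pt) || pt < 0 || pt > 1) stop("'pt' must lie in [0, 1]")
  ## probs[i+1] = sum_a P(XT = a) P(B - XC = i - a)
  pT <- dbinom(0:B, B, pt)
  pF <- dbinom(0:B, B, 1 - pc)    # distribution of B - XC
  probs <- numeric(2L * B + 1L)
  for (a in 0:B)
    probs[a + seq_len(B + 1L)] <- probs[a + seq_len(B + 1L)] + pT[a + 1L] * pF
  names(probs) <- 0:(2L * B)
  probs
}
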