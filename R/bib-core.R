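#' Peaked initial likelihood matrix
#'
#' Builds the one-parameter family of likelihoods used as the initial (and, in
#' Bayes-only mode, permanent) hypothesis set: hypothesis `k` assigns
#' probability `p` to symbol `k` and spreads the remainder evenly over the
#' other `n - 1` symbols. With `m = n` hypotheses, hypothesis `k` is "the
#' local state is symbol `k`".
#'
#' @param p Peak probability assigned by hypothesis `k` to symbol `k`.
#'   Must lie in `(1/n, 1]`; at `p = 1/n` all hypotheses coincide and the
#'   belief can never discriminate between them.
#' @param n Alphabet size (number of data symbols), `n >= 2`. The hypothesis
#'   count equals `n`.
#' @return An `n x n` likelihood matrix; row `k` is the conditional
#'   distribution over symbols under hypothesis `k`. Rows sum to 1.
#' @examples
#' initial_likelihood(0.7, 4)
#' @export
initial_likelihood <- function(p, n) {
  stopifnot(is.numeric(p), length(p) == 1L, is.numeric(n), length(n) == 1L)
  n <- as.integer(n)
  if (n < 2L) stop("alphabet size n must be at least 2")
  if (!(p > 1 / n && p <= 1)) {
    stop(sprintf("p must lie in (1/n, 1] = (%.4g, 1], got %.4g", 1 / n, p))
  }
  off <- (1 - p) / (n - 1)
  L <- matrix(off, n, n, dimnames = list(
    hypothesis = paste0("h", seq_len(n) - 1L),
    symbol = paste0("d", seq_len(n) - 1L)
  ))
  diag(L) <- p
  L
}

#' Validate a likelihood matrix
#'
#' @param likelihood Numeric matrix, rows = hypotheses, columns = symbols.
#' @param tol Row-sum tolerance.
#' @return The matrix, invisibly; errors on violation.
#' @export
validate_likelihood <- function(likelihood, tol = 1e-9) {
  if (!is.matrix(likelihood) || !is.numeric(likelihood)) {
    stop("likelihood must be a numeric matrix")
  }
  if (any(!is.finite(likelihood)) || any(likelihood < 0) || any(likelihood > 1)) {
    stop("likelihood entries must be probabilities in [0, 1]")
  }
  rs <- rowSums(likelihood)
  if (any(abs(rs - 1) > tol)) {
    stop(sprintf("likelihood rows must sum to 1 (max deviation %.3g)",
                 max(abs(rs - 1))))
  }
  invisible(likelihood)
}

#' Validate a belief vector
#'
#' @param belief Numeric probability vector over hypotheses.
#' @param tol Sum tolerance.
#' @return The vector, invisibly; errors on violation.
#' @export
validate_belief <- function(belief, tol = 1e-9) {
  if (!is.numeric(belief) || length(belief) < 1L) {
    stop("belief must be a numeric vector")
  }
  if (any(!is.finite(belief)) || any(belief < 0) || any(belief > 1)) {
    stop("belief entries must be probabilities in [0, 1]")
  }
  if (abs(sum(belief) - 1) > tol) {
    stop(sprintf("belief must sum to 1 (deviation %.3g)", abs(sum(belief) - 1)))
  }
  invisible(belief)
}

#' Windowed empirical symbol frequency
#'
#' Normalized frequency of each symbol over (at most) the last `M`
#' observations. This is the quantity that the inverse-Bayesian step
#' substitutes for the likelihood row of the least probable hypothesis.
#'
#' @param window Integer vector of observed symbols (values in `0..n-1`),
#'   oldest first. May be shorter than `M` or empty.
#' @param n Alphabet size.
#' @param M Optional window capacity; when given and `window` is longer, only
#'   the last `M` entries are used.
#' @return Numeric vector of length `n`. For a nonempty window the entries are
#'   counts divided by the effective window length and sum to 1. An empty
#'   window returns the all-zero vector, the sentinel for "frequency
#'   undefined"; [ib_update()] treats it as a no-op.
#' @examples
#' # at step t the last four observations are d1, d1, d2, d3
#' windowed_frequency(c(0L, 1L, 1L, 2L, 3L), n = 4, M = 4)
#' @export
windowed_frequency <- function(window, n, M = NULL) {
  n <- as.integer(n)
  if (length(window) == 0L) return(numeric(n))
  window <- as.integer(window)
  if (anyNA(window) || any(window < 0L) || any(window >= n)) {
    stop("corrupt window: symbol index outside alphabet 0..n-1")
  }
  if (!is.null(M) && length(window) > M) {
    window <- window[(length(window) - M + 1L):length(window)]
  }
  tabulate(window + 1L, nbins = n) / length(window)
}

#' Bayesian belief update
#'
#' Standard posterior update for one observed symbol: the prior over
#' hypotheses is reweighted by each hypothesis's likelihood for the symbol
#' and renormalized.
#'
#' @param belief Prior probability vector over hypotheses.
#' @param likelihood Likelihood matrix (rows = hypotheses, columns = symbols).
#' @param observed Observed symbol (integer in `0..n-1`).
#' @return Posterior belief vector.
#' @examples
#' L <- rbind(c(0.8, 0.2), c(0.4, 0.6))
#' bayes_update(c(0.5, 0.5), L, observed = 0) # (2/3, 1/3)
#' @export
bayes_update <- function(belief, likelihood, observed) {
  observed <- as.integer(observed)
  if (observed < 0L || observed >= ncol(likelihood)) {
    stop("observed symbol outside alphabet")
  }
  w <- likelihood[, observed + 1L] * belief
  den <- sum(w)
  if (den <= 0) {
    stop("inconsistent observation: symbol has probability zero under every weighted hypothesis")
  }
  w / den
}

#' Select the hypothesis targeted for inverse-Bayesian replacement
#'
#' The least probable hypothesis `h_s` is the replacement candidate; the
#' replacement actually happens with probability `1 - P(h_s)`, so a hypothesis
#' that is nearly ruled out is almost surely refreshed while a competitive one
#' is usually left alone. Ties for the minimum are broken uniformly at random.
#'
#' @param belief Probability vector over hypotheses.
#' @return The 1-based index of `h_s` when a replacement should occur this
#'   step, otherwise `NA_integer_`.
#' @export
select_hs <- function(belief) {
  bmin <- min(belief)
  cand <- which(belief == bmin)
  hs <- if (length(cand) > 1L) cand[sample_int(length(cand))] else cand
  if (stats::runif(1) < 1 - belief[hs]) hs else NA_integer_
}

#' Most probable hypothesis
#'
#' @param belief Probability vector over hypotheses.
#' @return 1-based index of the maximizing hypothesis; ties broken uniformly
#'   at random.
#' @export
argmax_hypothesis <- function(belief) {
  bmax <- max(belief)
  cand <- which(belief == bmax)
  if (length(cand) > 1L) cand[sample_int(length(cand))] else cand
}

#' Inverse-Bayesian likelihood replacement
#'
#' Replaces the likelihood row of hypothesis `h_s` by the windowed empirical
#' frequency: the hypothesis set itself is rewritten by experience, which is
#' what lets the combined system track abrupt changes a fixed hypothesis set
#' cannot.
#'
#' @param likelihood Likelihood matrix.
#' @param h_s 1-based row index to replace (typically from [select_hs()]).
#' @param freq Probability vector over symbols (from [windowed_frequency()]).
#'   The all-zero empty-window sentinel leaves the matrix unchanged.
#' @return The updated likelihood matrix.
#' @export
ib_update <- function(likelihood, h_s, freq) {
  if (length(freq) != ncol(likelihood)) {
    stop("frequency vector length must match the alphabet")
  }
  if (all(freq == 0)) return(likelihood) # empty-window sentinel: no-op
  if (abs(sum(freq) - 1) > 1e-9) stop("freq must sum to 1")
  likelihood[h_s, ] <- freq
  likelihood
}

#' Predicted probability of a symbol under a hypothesis
#'
#' Decision-making reads off `P(d | h_max)`: the probability the currently
#' dominant hypothesis assigns to a symbol.
#'
#' @param likelihood Likelihood matrix.
#' @param h 1-based hypothesis index.
#' @param symbol Symbol (integer in `0..n-1`).
#' @return The probability `likelihood[h, symbol]`.
#' @export
predict_prob <- function(likelihood, h, symbol) {
  likelihood[h, as.integer(symbol) + 1L]
}

# uniform draw from 1..k consuming one uniform variate (shared with the
# compiled engine, which uses the identical floor(unif*k) construction)
sample_int <- function(k) {
  i <- floor(stats::runif(1) * k) + 1
  if (i > k) i <- k
  as.integer(i)
}
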