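#' Create an inference agent
#'
#' Bundles one agent's belief over hypotheses, likelihood matrix, and sliding
#' observation window. Fresh agents start from a uniform belief and the peaked
#' likelihood of [initial_likelihood()].
#'
#' @param n Alphabet size (hypothesis count equals `n`).
#' @param p Initial likelihood peak, in `(1/n, 1]`.
#' @param M Window capacity for the empirical frequency.
#' @param belief Optional starting belief (defaults to uniform).
#' @param likelihood Optional starting likelihood (defaults to
#'   `initial_likelihood(p, n)`).
#' @param belief_floor Lower bound applied to the belief after each update
#'   (followed by renormalization). Replaced likelihood rows may contain
#'   exact zeros (a symbol absent from the window); without a floor, one
#'   observation of such a symbol makes the hypothesis's probability exactly
#'   zero, which is absorbing under multiplicative updating, and a
#'   permanently dead hypothesis both monopolizes [select_hs()] and can never
#'   be revived by a better likelihood row. The default `1e-12` is far below
#'   any probability of interest but lets a refreshed hypothesis climb back
#'   within a few dozen favourable observations.
#' @return An object of class `bib_agent` with fields `belief`, `likelihood`,
#'   `window`, `M`, `n`.
#' @examples
#' a <- bib_agent(n = 4, p = 0.7, M = 100)
#' a <- bib_step(a, observed = 2, mode = "bib")
#' @export
bib_agent <- function(n = 4, p = 0.7, M = 100, belief = NULL,
                      likelihood = NULL, belief_floor = 1e-12) {
  n <- as.integer(n)
  M <- as.integer(M)
  if (M < 1L) stop("window capacity M must be a positive integer")
  if (is.null(likelihood)) likelihood <- initial_likelihood(p, n)
  validate_likelihood(likelihood)
  if (nrow(likelihood) != ncol(likelihood) || ncol(likelihood) != n) {
    stop("likelihood must be n x n")
  }
  if (is.null(belief)) belief <- rep(1 / n, nrow(likelihood))
  validate_belief(belief)
  if (length(belief) != nrow(likelihood)) {
    stop("belief length must match the number of hypotheses")
  }
  structure(
    list(belief = belief, likelihood = likelihood, window = integer(0),
         M = M, n = n, belief_floor = belief_floor),
    class = "bib_agent"
  )
}

#' @export
print.bib_agent <- function(x, ...) {
  cat(sprintf("<bib_agent> %d hypotheses / %d symbols, window %d/%d\n",
              nrow(x$likelihood), x$n, length(x$window), x$M))
  cat("belief:", signif(x$belief, 4), "\n")
  invisible(x)
}

#' Advance an agent by one observation
#'
#' One full inference step: the observation is appended to the window, the
#' belief receives a Bayesian update, and in `"bib"` mode the likelihood row
#' of the least probable hypothesis is then (probabilistically) replaced by
#' the windowed frequency. In `"b"` mode the likelihood is never modified.
#'
#' An observation that is impossible under every positively weighted
#' hypothesis (zero Bayes denominator; only possible when some likelihood
#' entries are exactly zero) leaves the belief unchanged for that step.
#'
#' @param agent A [bib_agent()].
#' @param observed Observed symbol (integer in `0..n-1`).
#' @param mode `"bib"` (Bayes + inverse-Bayes) or `"b"` (Bayes only).
#' @return The updated agent.
#' @export
bib_step <- function(agent, observed, mode = c("bib", "b")) {
  mode <- match.arg(mode)
  observed <- as.integer(observed)
  if (observed < 0L || observed >= agent$n) stop("observed symbol outside alphabet")
  # window append, oldest evicted first
  w <- c(agent$window, observed)
  if (length(w) > agent$M) w <- w[(length(w) - agent$M + 1L):length(w)]
  agent$window <- w
  # Bayesian update (skip on inconsistent observation, keeping belief valid)
  wgt <- agent$likelihood[, observed + 1L] * agent$belief
  den <- sum(wgt)
  if (den > 0) agent$belief <- wgt / den
  if (any(agent$belief < agent$belief_floor)) {
    b <- pmax(agent$belief, agent$belief_floor)
    agent$belief <- b / sum(b)
  }
  # inverse-Bayesian replacement
  if (mode == "bib") {
    freq <- windowed_frequency(agent$window, agent$n)
    if (any(freq > 0)) {
      hs <- select_hs(agent$belief)
      if (!is.na(hs)) agent$likelihood <- ib_update(agent$likelihood, hs, freq)
    }
  }
  agent
}

#' Run an agent over a symbol stream
#'
#' Feeds a whole observation sequence through [bib_step()] and records, per
#' step, the dominant hypothesis and its predictive distribution over symbols
#' (the values `P(d | h_max)` used for decision-making).
#'
#' @param agent A [bib_agent()].
#' @param observations Integer vector of symbols in `0..n-1`.
#' @param mode `"bib"` or `"b"`.
#' @return A list with `agent` (final state), `h_max` (integer vector,
#'   1-based), and `prediction` (matrix, steps x n, row `t` =
#'   `P(. | h_max)` after the update at step `t`).
#' @export
run_bib <- function(agent, observations, mode = c("bib", "b")) {
  mode <- match.arg(mode)
  observations <- as.integer(observations)
  Tn <- length(observations)
  n <- agent$n
  hmax <- integer(Tn)
  pred <- matrix(NA_real_, Tn, n)
  # unrolled copy of bib_step on plain locals: identical semantics and RNG
  # consumption, without per-step list overhead
  belief <- agent$belief
  lik <- agent$likelihood
  floor_ <- agent$belief_floor
  M <- agent$M
  win <- integer(M)
  counts <- integer(n)
  wlen <- length(agent$window)
  wpos <- 0L
  if (wlen > 0L) {
    win[seq_len(wlen)] <- agent$window
    counts <- tabulate(agent$window + 1L, nbins = n)
    wpos <- wlen %% M
  }
  bib <- mode == "bib"
  for (t in seq_len(Tn)) {
    obs <- observations[t]
    if (obs < 0L || obs >= n) stop("observed symbol outside alphabet")
    if (wlen == M) {
      counts[win[wpos + 1L] + 1L] <- counts[win[wpos + 1L] + 1L] - 1L
    } else wlen <- wlen + 1L
    win[wpos + 1L] <- obs
    counts[obs + 1L] <- counts[obs + 1L] + 1L
    wpos <- (wpos + 1L) %% M
    wgt <- lik[, obs + 1L] * belief
    den <- sum(wgt)
    if (den > 0) belief <- wgt / den
    if (any(belief < floor_)) {
      b <- pmax(belief, floor_)
      belief <- b / sum(b)
    }
    if (bib) {
      bmin <- min(belief)
      cand <- which(belief == bmin)
      hs <- if (length(cand) > 1L) cand[sample_int(length(cand))] else cand
      if (stats::runif(1) < 1 - belief[hs]) lik[hs, ] <- counts / wlen
    }
    bmax <- max(belief)
    cand <- which(belief == bmax)
    hm <- if (length(cand) > 1L) cand[sample_int(length(cand))] else cand
    hmax[t] <- hm
    pred[t, ] <- lik[hm, ]
  }
  agent$belief <- belief
  agent$likelihood <- lik
  agent$window <- if (wlen < M) win[seq_len(wlen)] else {
    win[((wpos + seq_len(M) - 1L) %% M) + 1L]
  }
  list(agent = agent, h_max = hmax, prediction = pred)
}
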