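#' Sinusoidally drifting symbol source
#'
#' A nonstationary environment over `n` symbols in which the probability of
#' symbol 0 follows a sine curve, `P^t(d0) = b + A sin(2*pi*t / period)` for
#' `t = 0, 1, ..., horizon - 1`, while the remaining mass is split equally
#' over the other `n - 1` symbols. This is the standard stress test for the
#' inference engine: a fixed hypothesis set can only average over the drift,
#' whereas inverse-Bayesian replacement lets the agent re-anchor on the
#' recent empirical frequency.
#'
#' @param n Alphabet size (4 by default; 20 is the other studied case).
#' @param baseline Baseline `b` of `P^t(d0)`.
#' @param amplitude Amplitude `A`; `b - A >= 0` and `b + A <= 1` required.
#' @param period Period of the sine in steps.
#' @param horizon Number of steps to simulate.
#' @return An object of class `sin_environment` with the truth series
#'   `$p_d0` (length `horizon`).
#' @examples
#' env <- make_sin_env(n = 4, baseline = 0.5, amplitude = 0.4,
#'                     period = 1000, horizon = 5000)
#' range(env$p_d0)
#' @export
make_sin_env <- function(n = 4, baseline = 0.5, amplitude = 0.4,
                         period = 1000, horizon = 5000) {
  n <- as.integer(n)
  if (n < 2L) stop("alphabet size n must be at least 2")
  if (amplitude < 0) stop("amplitude must be nonnegative")
  if (baseline - amplitude < 0 || baseline + amplitude > 1) {
    stop("P(d0) leaves [0, 1]: require 0 <= baseline - amplitude and baseline + amplitude <= 1")
  }
  if (period <= 0 || horizon < 1) stop("period and horizon must be positive")
  t <- seq_len(horizon) - 1
  structure(
    list(n = n, baseline = baseline, amplitude = amplitude, period = period,
         horizon = as.integer(horizon),
         p_d0 = baseline + amplitude * sin(2 * pi * t / period)),
    class = "sin_environment"
  )
}

#' @export
print.sin_environment <- function(x, ...) {
  cat(sprintf("<sin_environment> n=%d, P(d0) = %.3g + %.3g*sin(2*pi*t/%g), horizon %d\n",
              x$n, x$baseline, x$amplitude, x$period, x$horizon))
  invisible(x)
}

# one draw per step: symbol 0 with probability p_t, else uniform over the rest
sample_sin_stream <- function(env) {
  u <- stats::runif(env$horizon)
  d <- integer(env$horizon)
  other <- u >= env$p_d0
  if (any(other)) {
    d[other] <- 1L + floor((u[other] - env$p_d0[other]) /
                             (1 - env$p_d0[other]) * (env$n - 1L))
    d[other] <- pmin(d[other], env$n - 1L)
  }
  d
}

#' Track the drifting source with one inference agent
#'
#' Draws one symbol per step from the environment, feeds it to a fresh agent
#' (uniform prior, peaked initial likelihood), and records the truth
#' `P^t(d0)` against the agent's prediction `P^t(d0 | h_max)`. The summary
#' error is the mean absolute deviation between the two series.
#'
#' @param env A [make_sin_env()] environment.
#' @param M Window capacity for the empirical frequency.
#' @param mode `"bib"` or `"b"`.
#' @param p Initial likelihood peak.
#' @param seed Optional integer seed (set once for the whole run).
#' @return An object of class `tracking_result`: data.frame `$series` with
#'   columns `t`, `truth`, `prediction`, plus `$error`, `$mode`, `$M`.
#' @examples
#' env <- make_sin_env(horizon = 500, period = 250)
#' res <- run_tracking(env, M = 50, mode = "bib", seed = 1)
#' res$error
#' @export
run_tracking <- function(env, M = 100, mode = c("bib", "b"), p = 0.7,
                         seed = NULL) {
  mode <- match.arg(mode)
  if (!inherits(env, "sin_environment")) stop("env must be a sin_environment")
  if (!is.null(seed)) set.seed(seed)
  obs <- sample_sin_stream(env)
  agent <- bib_agent(n = env$n, p = p, M = M)
  out <- run_bib(agent, obs, mode = mode)
  prediction <- out$prediction[, 1L]
  series <- data.frame(t = seq_len(env$horizon) - 1L, truth = env$p_d0,
                       prediction = prediction)
  structure(
    list(series = series, error = mean(abs(env$p_d0 - prediction)),
         mode = mode, M = as.integer(M), p = p),
    class = "tracking_result"
  )
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("<tracking_result> mode=%s, M=%d, mean |truth - prediction| = %.4f\n",
              x$mode, x$M, x$error))
  invisible(x)
}

#' Sweep the window length
#'
#' Mean tracking error as a function of the frequency-window capacity `M`,
#' averaged over seeded replicates. Too small an `M` makes the empirical
#' frequency noisy; too large an `M` makes it lag the drift; errors are low
#' over a broad intermediate plateau.
#'
#' @param env A [make_sin_env()] environment.
#' @param M_values Integer vector of window capacities.
#' @param replicates Replicates per `M` (fresh stream and agent each).
#' @param mode `"bib"` or `"b"`.
#' @param p Initial likelihood peak.
#' @param seed Optional integer seed.
#' @return data.frame with columns `M` and `error` (mean over replicates).
#' @export
m_sweep <- function(env, M_values, replicates = 20, mode = "bib", p = 0.7,
                    seed = NULL) {
  if (length(M_values) < 1L) stop("M_values must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  err <- vapply(M_values, function(M) {
    mean(vapply(seq_len(replicates), function(i) {
      run_tracking(env, M = M, mode = mode, p = p)$error
    }, numeric(1)))
  }, numeric(1))
  data.frame(M = as.integer(M_values), error = err)
}
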