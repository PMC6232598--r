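#' Discretized relative local density
#'
#' Codes the neighbourhood of a focal point into the four-symbol alphabet
#' `D = {0, 1, 2, 3}` from two neighbour counts: `n_r` individuals within
#' radius `r` and `n_2r` within `2r`. The ratio `n_r / n_2r` is a
#' dimensionless relative density (how concentrated the neighbourhood is
#' toward its centre); it is mapped onto the alphabet by
#' `d = min(3, floor(4 * n_r / n_2r))`, with `d = 0` for an empty
#' neighbourhood (`n_2r = 0`). A spatially uniform field gives
#' `n_r / n_2r ~ 1/4`, i.e. `d = 1`; a compact cluster inside `r` gives
#' `d = 3`.
#'
#' @param n_r Count of individuals within `r`.
#' @param n_2r Count of individuals within `2r` (includes those within `r`).
#' @return Integer symbol in `0..3`.
#' @examples
#' density_symbol(2, 8) # 1
#' density_symbol(5, 5) # 3
#' @export
density_symbol <- function(n_r, n_2r) {
  stopifnot(n_r <= n_2r)
  ifelse(n_2r == 0L, 0L, pmin(3L, as.integer(4 * n_r / n_2r)))
}

#' Density datum of one individual at one frame
#'
#' Counts the other individuals within `r` and `2r` of the focal position and
#' codes them with [density_symbol()]. The focal individual itself is
#' excluded from both counts.
#'
#' @param x,y Numeric vectors: positions of all individuals at the frame
#'   (`NA` allowed for absent individuals, which are ignored).
#' @param i Focal index (1-based).
#' @param r Inner radius, in the same units as the coordinates.
#' @return Integer symbol in `0..3`.
#' @export
density_datum <- function(x, y, i, r) {
  if (r <= 0) stop("r must be positive")
  d2 <- (x - x[i])^2 + (y - y[i])^2
  d2 <- d2[-i]
  d2 <- d2[!is.na(d2)]
  density_symbol(sum(d2 <= r^2), sum(d2 <= (2 * r)^2))
}

#' Density-datum streams for all individuals
#'
#' @param traj A [trajectory_dataset()].
#' @param r Inner radius.
#' @return Integer `T x N` matrix of symbols (`NA` where the individual is
#'   absent).
#' @export
density_series <- function(traj, r) {
  stopifnot(inherits(traj, "trajectory_dataset"))
  if (r <= 0) stop("r must be positive")
  Tn <- nrow(traj$x)
  N <- ncol(traj$x)
  out <- matrix(NA_integer_, Tn, N)
  r2 <- r^2
  r4 <- 4 * r^2
  for (t in seq_len(Tn)) {
    xs <- traj$x[t, ]
    ys <- traj$y[t, ]
    ok <- which(!is.na(xs))
    if (length(ok) == 0L) next
    dx <- outer(xs[ok], xs[ok], "-")
    dy <- outer(ys[ok], ys[ok], "-")
    d2 <- dx * dx + dy * dy
    diag(d2) <- Inf # exclude self
    nr <- rowSums(d2 <= r2)
    n2r <- rowSums(d2 <= r4)
    out[t, ok] <- density_symbol(nr, n2r)
  }
  out
}

#' Future symbol frequency
#'
#' The benchmark the predictions are judged against: for each frame `t`, the
#' normalized frequency of each symbol over the window
#' `[t - M/2, t + M]` (inclusive, clipped at the series boundaries). A
#' prediction that anticipates the stream should match this forward-looking
#' frequency.
#'
#' @param series Integer vector of symbols in `0..n-1` (`NA` allowed; `NA`
#'   frames are skipped in the counts).
#' @param M Window parameter; the window spans `floor(M/2)` frames back and
#'   `M` frames forward.
#' @param n Alphabet size.
#' @return List with `freq` (`T x n` matrix; row `t` sums to 1 where defined)
#'   and `valid` (logical; `FALSE` where the clipped window holds fewer than
#'   `M/2` observations, frames to exclude from summary metrics).
#' @export
future_frequency <- function(series, M, n = 4) {
  Tn <- length(series)
  half <- floor(M / 2)
  freq <- matrix(NA_real_, Tn, n)
  valid <- logical(Tn)
  # cumulative counts per symbol for O(1) window sums
  cum <- matrix(0L, Tn + 1L, n)
  for (j in seq_len(n)) {
    cum[-1L, j] <- cumsum(!is.na(series) & series == (j - 1L))
  }
  for (t in seq_len(Tn)) {
    lo <- max(1L, t - half)
    hi <- min(Tn, t + M)
    cnt <- cum[hi + 1L, ] - cum[lo, ]
    tot <- sum(cnt)
    if (tot > 0L) freq[t, ] <- cnt / tot
    valid[t] <- tot >= half
  }
  list(freq = freq, valid = valid)
}
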