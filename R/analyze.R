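#' Inference analysis of one tracked individual
#'
#' Runs the inference engine over an individual's density-datum stream: at
#' each frame the observed symbol updates the agent (Bayes, then in `"bib"`
#' mode the inverse-Bayesian replacement) and the predictive distribution
#' `P(d | h_max)` is recorded, alongside the forward-looking frequency
#' benchmark `F^t(d)` of [future_frequency()].
#'
#' @param traj A [trajectory_dataset()].
#' @param i Focal individual: 1-based column index or an id in `traj$ids`.
#' @param r Inner density radius (coordinate units).
#' @param M Window capacity (frames), used both for the agent's frequency
#'   window and for the future-frequency benchmark.
#' @param p Initial likelihood peak.
#' @param mode `"bib"` or `"b"`.
#' @param d_series Optional precomputed [density_series()] matrix (avoids
#'   recomputation when analysing many individuals of the same dataset).
#' @return An object of class `individual_analysis`: data.frame `$series`
#'   with columns `frame`, `d`, `pred_0..pred_{n-1}`, `F_0..F_{n-1}`,
#'   `valid`, plus fields `id`, `mode`, `M`, `r`, `p`.
#' @export
analyze_individual <- function(traj, i, r, M = 100, p = 0.7,
                               mode = c("bib", "b"), d_series = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "trajectory_dataset"))
  if (!is.numeric(i) || is.character(i)) i <- match(i, traj$ids)
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > ncol(traj$x)) stop("unknown individual")
  if (is.null(d_series)) d_series <- density_series(traj, r)
  ds <- d_series[, i]
  obs_idx <- which(!is.na(ds))
  if (length(obs_idx) <= M) {
    stop(sprintf("individual %s observed for %d frames; need more than M = %d",
                 traj$ids[i], length(obs_idx), M))
  }
  n <- 4L
  agent <- bib_agent(n = n, p = p, M = M)
  out <- run_bib(agent, ds[obs_idx], mode = mode)
  ff <- future_frequency(ds[obs_idx], M = M, n = n)
  series <- data.frame(frame = traj$frames[obs_idx], d = ds[obs_idx])
  pred <- out$prediction
  colnames(pred) <- paste0("pred_", seq_len(n) - 1L)
  fmat <- ff$freq
  colnames(fmat) <- paste0("F_", seq_len(n) - 1L)
  series <- cbind(series, pred, fmat, valid = ff$valid)
  structure(
    list(series = series, id = traj$ids[i], mode = mode, M = as.integer(M),
         r = r, p = p),
    class = "individual_analysis"
  )
}

#' @export
print.individual_analysis <- function(x, ...) {
  cat(sprintf("<individual_analysis> id=%s, mode=%s, %d frames (M=%d, r=%g)\n",
              x$id, x$mode, nrow(x$series), x$M, x$r))
  invisible(x)
}

#' Mean absolute prediction-vs-future error of one analysis
#'
#' @param analysis An [analyze_individual()] result.
#' @param symbol Symbol in `0..3` to score.
#' @return Mean of `|P(symbol | h_max) - F(symbol)|` over valid frames.
#' @export
prediction_error <- function(analysis, symbol = 0) {
  s <- analysis$series
  ok <- s$valid
  mean(abs(s[[paste0("pred_", symbol)]][ok] - s[[paste0("F_", symbol)]][ok]))
}

#' Analyse every individual of a dataset
#'
#' @inheritParams analyze_individual
#' @param min_frames Individuals observed for fewer frames are skipped.
#' @return List of [analyze_individual()] results.
#' @export
analyze_population <- function(traj, r, M = 100, p = 0.7,
                               mode = c("bib", "b"), min_frames = M + 1) {
  mode <- match.arg(mode)
  ds <- density_series(traj, r)
  keep <- which(colSums(!is.na(ds)) >= min_frames)
  lapply(keep, function(i) {
    analyze_individual(traj, i, r, M = M, p = p, mode = mode, d_series = ds)
  })
}

#' Population-averaged prediction and future frequency
#'
#' Unweighted mean over the individuals present at each frame of the
#' predicted probability of a symbol and of its future frequency.
#'
#' @param analyses List of [analyze_individual()] results (same dataset).
#' @param symbol Symbol in `0..3`.
#' @return data.frame with columns `frame`, `pred_mean`, `F_mean`,
#'   `n_individuals`.
#' @export
population_average <- function(analyses, symbol = 0) {
  if (length(analyses) < 1L) stop("need at least one analysed individual")
  pc <- paste0("pred_", symbol)
  fc <- paste0("F_", symbol)
  long <- do.call(rbind, lapply(analyses, function(a) {
    data.frame(frame = a$series$frame, pred = a$series[[pc]],
               F = a$series[[fc]])
  }))
  agg <- stats::aggregate(cbind(pred, F) ~ frame, data = long,
                          FUN = mean, na.action = stats::na.omit)
  cnt <- stats::aggregate(pred ~ frame, data = long, FUN = length)
  data.frame(frame = agg$frame, pred_mean = agg$pred, F_mean = agg$F,
             n_individuals = cnt$pred)
}
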