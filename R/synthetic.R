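#' Regime-switching symbol stream ("ball bag" scenario)
#'
#' Draws i.i.d. symbols within each regime of a schedule, emitting the true
#' generating distribution alongside. This reproduces the classic urn
#' demonstration: an observer repeatedly samples (with replacement) from a
#' bag whose composition is switched behind its back.
#'
#' @param durations Integer vector of regime lengths (steps).
#' @param probs Matrix with one row per regime: the distribution over the
#'   `n` symbols during that regime (rows sum to 1). A single regime may be
#'   given as a plain vector.
#' @param seed Optional integer seed.
#' @return List with `symbols` (integer vector, values `0..n-1`) and `truth`
#'   (matrix, steps x n, the generating distribution at each step).
#' @examples
#' s <- generate_bag_stream(c(50, 50), rbind(c(0.9, 0.1), c(0.2, 0.8)),
#'                          seed = 1)
#' table(s$symbols[1:50])
#' @export
generate_bag_stream <- function(durations, probs, seed = NULL) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1)
  durations <- as.integer(durations)
  if (length(durations) != nrow(probs)) {
    stop("need one distribution per regime")
  }
  if (any(durations < 1L)) stop("durations must be positive")
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("each regime distribution must be a probability vector")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(probs)
  symbols <- unlist(lapply(seq_along(durations), function(k) {
    sample.int(n, durations[k], replace = TRUE, prob = probs[k, ]) - 1L
  }))
  truth <- probs[rep(seq_along(durations), durations), , drop = FALSE]
  list(symbols = symbols, truth = truth)
}

#' Phase schedule for synthetic trajectories
#'
#' @param durations Integer vector of phase lengths (frames).
#' @param phases Character vector, `"coherent"` or `"dispersed"`, one per
#'   duration.
#' @return data.frame with columns `duration`, `phase`.
#' @export
phase_schedule <- function(durations, phases) {
  durations <- as.integer(durations)
  phases <- match.arg(phases, c("coherent", "dispersed"), several.ok = TRUE)
  if (length(durations) != length(phases)) {
    stop("durations and phases must have equal length")
  }
  if (any(durations < 1L)) stop("durations must be positive")
  data.frame(duration = durations, phase = phases)
}

#' Synthetic trajectories with alternating coherent and dispersed phases
#'
#' Generates `N` continuous 2-D trajectories that alternate between a
#' coherent phase -- a common travel heading with concentrated (wrapped
#' normal, von Mises-like) per-individual angular noise and a mild
#' centripetal drift toward the group centroid, producing high polarization
#' and high local density -- and a dispersed phase -- independent,
#' decorrelating headings plus outward drift, producing low polarization and
#' falling density. Positions are continuous across phase switches. This is
#' the stand-in for tracked swarm recordings in which gathering and
#' dispersing alternate.
#'
#' @param schedule A [phase_schedule()] (or data.frame with `duration`,
#'   `phase`).
#' @param N Number of individuals.
#' @param speed Distance travelled per frame (coordinate units).
#' @param coherent_sd Angular noise (radians) of individual headings around
#'   the shared heading during coherent phases.
#' @param heading_sd Per-frame random-walk step (radians) of the shared
#'   heading.
#' @param cohesion Centripetal drift per frame toward the centroid during
#'   coherent phases (fraction of the centroid distance).
#' @param disperse_sd Per-frame heading decorrelation (radians) during
#'   dispersed phases.
#' @param outward Outward drift per frame during dispersed phases
#'   (coordinate units).
#' @param cluster_radius Spread (s.d.) of the initial positions around the
#'   origin.
#' @param dt Frame interval metadata for the resulting dataset.
#' @param seed Optional integer seed.
#' @return List with `traj` (a [trajectory_dataset()]) and `phase`
#'   (character vector, one label per frame).
#' @examples
#' sched <- phase_schedule(c(100, 100), c("coherent", "dispersed"))
#' out <- generate_phase_trajectories(sched, N = 10, seed = 1)
#' table(out$phase)
#' @export
generate_phase_trajectories <- function(schedule, N = 30, speed = 2,
                                        coherent_sd = 0.25,
                                        heading_sd = 0.1, cohesion = 0.02,
                                        disperse_sd = 1.2, outward = 0.6,
                                        cluster_radius = 8, dt = 0.1,
                                        seed = NULL) {
  if (!all(c("duration", "phase") %in% names(schedule))) {
    stop("schedule must have columns duration and phase")
  }
  if (N < 2) stop("need at least 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  Tn <- sum(schedule$duration)
  phase <- rep(schedule$phase, schedule$duration)
  X <- matrix(NA_real_, Tn, N)
  Y <- matrix(NA_real_, Tn, N)
  x <- stats::rnorm(N, 0, cluster_radius)
  y <- stats::rnorm(N, 0, cluster_radius)
  shared <- stats::runif(1, 0, 2 * pi)
  headings <- stats::runif(N, 0, 2 * pi)
  for (t in seq_len(Tn)) {
    X[t, ] <- x
    Y[t, ] <- y
    cx <- mean(x)
    cy <- mean(y)
    if (phase[t] == "coherent") {
      shared <- shared + stats::rnorm(1, 0, heading_sd)
      headings <- shared + stats::rnorm(N, 0, coherent_sd)
      x <- x + speed * cos(headings) + cohesion * (cx - x)
      y <- y + speed * sin(headings) + cohesion * (cy - y)
    } else {
      headings <- headings + stats::rnorm(N, 0, disperse_sd)
      rx <- x - cx
      ry <- y - cy
      rn <- sqrt(rx^2 + ry^2)
      rn[rn == 0] <- 1
      x <- x + speed * cos(headings) + outward * rx / rn
      y <- y + speed * sin(headings) + outward * ry / rn
    }
  }
  df <- data.frame(
    id = rep(seq_len(N), each = Tn),
    frame = rep(seq_len(Tn) - 1L, N),
    x = as.vector(X),
    y = as.vector(Y)
  )
  list(traj = trajectory_dataset(df, dt = dt), phase = phase)
}
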