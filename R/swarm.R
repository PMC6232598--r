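#' Swarm simulation parameters
#'
#' Control parameters of the agent-based model: agents steer by averaging
#' neighbour velocities (radius `R`) and adjust position on a circle of
#' radius `u` around the anticipated position so that the local relative
#' density they would experience is as close as possible to the density level
#' their current best hypothesis predicts.
#'
#' @param n_agents Number of agents `N`.
#' @param r Inner density radius (the outer radius is `2r`).
#' @param R Alignment radius (defaults to `r`).
#' @param p Initial likelihood peak, in `(1/4, 1]`.
#' @param u Step length: candidate positions lie at distance `u` from the
#'   anticipated position.
#' @param M Window capacity of each agent's frequency window.
#' @param arena Side length of the square arena (default `10 * r`).
#' @param boundary `"periodic"` (default) or `"reflecting"`.
#' @param order `"async"` (default; agents move one at a time in a freshly
#'   shuffled order, each seeing predecessors' updated positions) or
#'   `"sync"` (all decisions from the step-start snapshot).
#' @param steps Simulation horizon `T`.
#' @return An object of class `swarm_params`.
#' @examples
#' swarm_params(n_agents = 50, r = 20, steps = 100)
#' @export
swarm_params <- function(n_agents = 100, r = 30, R = r, p = 0.7, u = 1,
                         M = 100, arena = 10 * r,
                         boundary = c("periodic", "reflecting"),
                         order = c("async", "sync"), steps = 5000) {
  boundary <- match.arg(boundary)
  order <- match.arg(order)
  if (n_agents < 2) stop("need at least 2 agents")
  if (r <= 0 || R <= 0 || u <= 0 || arena <= 0) {
    stop("r, R, u and arena must be positive")
  }
  if (!(p > 0.25 && p <= 1)) stop("p must lie in (1/4, 1]")
  if (M < 1) stop("M must be a positive integer")
  if (steps < 1) stop("steps must be positive")
  if (boundary == "periodic" && arena < 2 * (2 * r + u)) {
    stop("periodic arena too small: require arena >= 2 * (2r + u)")
  }
  structure(
    list(n_agents = as.integer(n_agents), r = r, R = R, p = p, u = u,
         M = as.integer(M), arena = arena, boundary = boundary,
         order = order, steps = as.integer(steps)),
    class = "swarm_params"
  )
}

#' @export
print.swarm_params <- function(x, ...) {
  cat(sprintf(
    "<swarm_params> N=%d, r=%g, R=%g, p=%g, u=%g, M=%d, arena=%g (%s, %s), T=%d\n",
    x$n_agents, x$r, x$R, x$p, x$u, x$M, x$arena, x$boundary, x$order, x$steps))
  invisible(x)
}

#' Run the swarm simulation
#'
#' Initial positions are uniform in the arena and initial headings uniform at
#' speed `u`; every agent starts from a uniform belief and the peaked initial
#' likelihood. Each step an agent observes its density datum, performs a
#' Bayesian update, derives its preferred density level `d_max` from the
#' dominant hypothesis, moves to the best-matching candidate around its
#' alignment-anticipated position, and (in `"bib"` mode) finally applies the
#' inverse-Bayesian likelihood replacement.
#'
#' @param params A [swarm_params()] object.
#' @param mode `"bib"` or `"b"` (Bayes only: likelihoods stay fixed).
#' @param seed Optional integer seed.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference;
#'   identical random-number consumption, for validation at small sizes).
#' @param record Record full position and density histories (memory scales
#'   with `steps * n_agents`).
#' @return An object of class `swarm_run`: `psi` (polarization per step),
#'   `d_mean` (population mean density datum per step), `belief` and
#'   `likelihood` (final per-agent state), and when `record = TRUE` the
#'   position matrices `x`, `y` (`steps + 1` rows) and density matrix `d`.
#' @examples
#' run <- run_swarm(swarm_params(n_agents = 20, r = 10, steps = 50),
#'                  mode = "bib", seed = 1)
#' range(run$psi)
#' @export
run_swarm <- function(params, mode = c("bib", "b"), seed = NULL,
                      engine = c("cpp", "r"), record = TRUE) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  stopifnot(inherits(params, "swarm_params"))
  if (!is.null(seed)) set.seed(seed)
  f <- if (engine == "cpp") .swarm_engine_cpp else swarm_engine_r
  out <- f(params$n_agents, params$r, params$R, params$p, params$u,
           params$M, params$arena, params$steps, mode == "bib",
           params$order == "async", params$boundary == "periodic", record)
  out$params <- params
  out$mode <- mode
  class(out) <- "swarm_run"
  out
}

#' @export
print.swarm_run <- function(x, ...) {
  cat(sprintf("<swarm_run> mode=%s, N=%d, T=%d; psi in [%.3f, %.3f]\n",
              x$mode, x$params$n_agents, x$params$steps,
              min(x$psi), max(x$psi)))
  invisible(x)
}

#' Swarm run as a trajectory dataset
#'
#' @param run A [run_swarm()] result with `record = TRUE`.
#' @param dt Frame interval to attach (model steps are unitless; default 1).
#' @return A [trajectory_dataset()] with `steps + 1` frames.
#' @export
swarm_trajectory <- function(run, dt = 1) {
  stopifnot(inherits(run, "swarm_run"))
  if (is.null(run$x)) stop("run was not recorded; use record = TRUE")
  Tn <- nrow(run$x)
  N <- ncol(run$x)
  df <- data.frame(
    id = rep(seq_len(N), each = Tn),
    frame = rep(seq_len(Tn) - 1L, N),
    x = as.vector(run$x),
    y = as.vector(run$y)
  )
  trajectory_dataset(df, dt = dt)
}

#' Detect swarming/dispersing phase turnover in a polarization series
#'
#' @param psi Polarization series.
#' @param hi Threshold defining a formed swarm (default 0.9).
#' @param lo Threshold defining a collapse (default 0.5).
#' @return List: `first_high` (first index with `psi > hi`, `NA` if never),
#'   `n_collapse` (downward crossings of `lo` after `first_high`),
#'   `n_cycle` (collapses that are followed by a return above `hi`,
#'   i.e. full collapse/re-formation cycles).
#' @export
phase_crossings <- function(psi, hi = 0.9, lo = 0.5) {
  fh <- which(psi > hi)[1L]
  if (is.na(fh)) {
    return(list(first_high = NA_integer_, n_collapse = 0L, n_cycle = 0L))
  }
  s <- psi[fh:length(psi)]
  down <- which(s[-1L] < lo & s[-length(s)] >= lo)
  ncycle <- 0L
  for (d in down) {
    if (any(s[(d + 1L):length(s)] > hi)) ncycle <- ncycle + 1L else break
  }
  list(first_high = fh, n_collapse = length(down), n_cycle = ncycle)
}

# ---------------------------------------------------------------------------
# Pure-R reference engine.  This is a line-by-line mirror of the compiled
# engine, kept deliberately free of long-double accumulators (sum(), mean())
# so that every floating-point intermediate and every RNG draw coincides with
# the C++ path; equality of the two engines is asserted in the test suite.
# ---------------------------------------------------------------------------

wrap_coord_r <- function(x, L) {
  x <- x - L * floor(x / L)
  if (x >= L) x <- x - L
  x
}

reflect_coord_r <- function(x, L) {
  if (x < 0) x <- -x
  if (x > L) x <- 2 * L - x
  if (x < 0) x <- 0
  if (x > L) x <- L
  x
}

coord_diff_r <- function(a, b, L, periodic) {
  d <- a - b
  if (periodic) {
    if (d > L / 2) d <- d - L
    else if (d < -L / 2) d <- d + L
  }
  d
}

density_code_r <- function(nr, n2r) {
  if (n2r == 0L) return(0L)
  min(3L, as.integer(4 * nr / n2r))
}

swarm_engine_r <- function(N, r, R_align, p, u, M, L, T, bib, async,
                           periodic, record) {
  n <- 4L
  belief <- matrix(1 / n, N, n)
  lik <- array(0, c(n, n, N))
  for (i in seq_len(N)) lik[, , i] <- initial_likelihood(p, n)
  win <- matrix(-1L, M, N)
  winlen <- integer(N)
  winpos <- integer(N)
  counts <- matrix(0L, n, N)
  px <- py <- vx <- vy <- numeric(N)
  for (i in seq_len(N)) {
    px[i] <- stats::runif(1) * L
    py[i] <- stats::runif(1) * L
    th <- stats::runif(1) * 2 * pi
    vx[i] <- u * cos(th)
    vy[i] <- u * sin(th)
  }
  psi <- d_mean <- numeric(T)
  if (record) {
    X <- matrix(NA_real_, T + 1L, N)
    Y <- matrix(NA_real_, T + 1L, N)
    D <- matrix(NA_integer_, T, N)
    X[1L, ] <- px
    Y[1L, ] <- py
  }
  cth <- cos((0:71) * pi / 36)
  sth <- sin((0:71) * pi / 36)
  pick <- function(ties) if (length(ties) > 1L) ties[sample_int(length(ties))] else ties

  for (t in seq_len(T)) {
    ord <- seq_len(N)
    if (async) {
      for (i in (N - 1L):1L) {
        j <- floor(stats::runif(1) * (i + 1))
        if (j > i) j <- i
        tmp <- ord[i + 1L]; ord[i + 1L] <- ord[j + 1L]; ord[j + 1L] <- tmp
      }
      qx <- NULL # asynchronous: always read live state
    } else {
      oqx <- px; oqy <- py; oqvx <- vx; oqvy <- vy
    }
    dsum <- 0
    for (i in ord) {
      if (async) { qx <- px; qy <- py; qvx <- vx; qvy <- vy
      } else { qx <- oqx; qy <- oqy; qvx <- oqvx; qvy <- oqvy }
      xi <- if (async) px[i] else oqx[i]
      yi <- if (async) py[i] else oqy[i]
      nr <- 0L; n2r <- 0L; nal <- 0L; svx <- 0; svy <- 0
      for (j in seq_len(N)) {
        dx <- coord_diff_r(qx[j], xi, L, periodic)
        dy <- coord_diff_r(qy[j], yi, L, periodic)
        d2 <- dx * dx + dy * dy
        if (j != i) {
          if (d2 <= r * r) nr <- nr + 1L
          if (d2 <= 4 * r * r) n2r <- n2r + 1L
        }
        if (d2 <= R_align * R_align) {
          svx <- svx + qvx[j]; svy <- svy + qvy[j]; nal <- nal + 1L
        }
      }
      dobs <- density_code_r(nr, n2r)
      dsum <- dsum + dobs
      if (record) D[t, i] <- dobs
      if (winlen[i] == M) {
        old <- win[winpos[i] + 1L, i]
        counts[old + 1L, i] <- counts[old + 1L, i] - 1L
      } else winlen[i] <- winlen[i] + 1L
      win[winpos[i] + 1L, i] <- dobs
      counts[dobs + 1L, i] <- counts[dobs + 1L, i] + 1L
      winpos[i] <- (winpos[i] + 1L) %% M
      den <- 0
      for (k in seq_len(n)) den <- den + lik[k, dobs + 1L, i] * belief[i, k]
      if (den > 0) {
        for (k in seq_len(n)) {
          belief[i, k] <- lik[k, dobs + 1L, i] * belief[i, k] / den
        }
      }
      if (any(belief[i, ] < 1e-12)) {
        bs <- 0
        for (k in seq_len(n)) {
          if (belief[i, k] < 1e-12) belief[i, k] <- 1e-12
          bs <- bs + belief[i, k]
        }
        for (k in seq_len(n)) belief[i, k] <- belief[i, k] / bs
      }
      bmax <- max(belief[i, ])
      hmax <- pick(which(belief[i, ] == bmax))
      pmax <- max(lik[hmax, , i])
      dmax <- pick(which(lik[hmax, , i] == pmax)) - 1L
      ax <- svx / nal; ay <- svy / nal
      hx <- xi + ax; hy <- yi + ay
      if (periodic) { hx <- wrap_coord_r(hx, L); hy <- wrap_coord_r(hy, L)
      } else { hx <- reflect_coord_r(hx, L); hy <- reflect_coord_r(hy, L) }
      base_r <- 0L; base_2r <- 0L
      sdx <- numeric(0); sdy <- numeric(0)
      rin <- max(r - u, 0); rout <- r + u
      r2in <- max(2 * r - u, 0); r2out <- 2 * r + u
      for (j in seq_len(N)) {
        if (j == i) next
        dx <- coord_diff_r(qx[j], hx, L, periodic)
        dy <- coord_diff_r(qy[j], hy, L, periodic)
        dd <- sqrt(dx * dx + dy * dy)
        if (dd < rin) { base_r <- base_r + 1L; base_2r <- base_2r + 1L; next }
        if (dd > r2out) next
        if (dd > rout && dd < r2in) { base_2r <- base_2r + 1L; next }
        sdx <- c(sdx, dx); sdy <- c(sdy, dy)
      }
      best <- n + 1L
      ties <- integer(0)
      for (k in 0:71) {
        cx <- u * cth[k + 1L]; cy <- u * sth[k + 1L]
        cnr <- base_r; cn2r <- base_2r
        if (length(sdx) > 0L) {
          for (s in seq_along(sdx)) {
            ddx <- sdx[s] - cx; ddy <- sdy[s] - cy
            d2 <- ddx * ddx + ddy * ddy
            if (d2 <= r * r) cnr <- cnr + 1L
            if (d2 <= 4 * r * r) cn2r <- cn2r + 1L
          }
        }
        sc <- abs(density_code_r(cnr, cn2r) - dmax)
        if (sc < best) { best <- sc; ties <- k
        } else if (sc == best) ties <- c(ties, k)
      }
      kc <- pick(ties)
      nxp <- hx + u * cth[kc + 1L]; nyp <- hy + u * sth[kc + 1L]
      if (periodic) { nxp <- wrap_coord_r(nxp, L); nyp <- wrap_coord_r(nyp, L)
      } else { nxp <- reflect_coord_r(nxp, L); nyp <- reflect_coord_r(nyp, L) }
      vx[i] <- coord_diff_r(nxp, xi, L, periodic)
      vy[i] <- coord_diff_r(nyp, yi, L, periodic)
      px[i] <- nxp; py[i] <- nyp
      if (bib && winlen[i] > 0L) {
        bmin <- min(belief[i, ])
        hs <- pick(which(belief[i, ] == bmin))
        if (stats::runif(1) < 1 - belief[i, hs]) {
          lik[hs, , i] <- counts[, i] / winlen[i]
        }
      }
    }
    sx <- 0; sy <- 0; inc <- 0L
    for (i in seq_len(N)) {
      nv <- sqrt(vx[i] * vx[i] + vy[i] * vy[i])
      if (nv > 0) { sx <- sx + vx[i] / nv; sy <- sy + vy[i] / nv; inc <- inc + 1L }
    }
    psi[t] <- if (inc > 0L) sqrt(sx * sx + sy * sy) / inc else NA_real_
    d_mean[t] <- dsum / N
    if (record) { X[t + 1L, ] <- px; Y[t + 1L, ] <- py }
  }
  out <- list(psi = psi, d_mean = d_mean, belief = belief, likelihood = lik)
  if (record) { out$x <- X; out$y <- Y; out$d <- D }
  out
}

# ---------------------------------------------------------------------------
# Stand-alone model components (the unit-testable surface of one agent step).
# ---------------------------------------------------------------------------

#' Alignment-anticipated velocity
#'
#' Mean velocity over all agents within distance `R` of the focal agent,
#' including the focal agent itself (so the neighbourhood is never empty and
#' a lone agent anticipates its own continuation).
#'
#' @param i Focal index (1-based).
#' @param x,y,vx,vy Position and velocity vectors of all agents.
#' @param R Alignment radius.
#' @param arena Arena side (used for periodic distances).
#' @param boundary `"periodic"` or `"reflecting"`.
#' @return Length-2 numeric vector, the anticipated velocity.
#' @export
alignment_velocity <- function(i, x, y, vx, vy, R, arena = Inf,
                               boundary = "periodic") {
  periodic <- boundary == "periodic" && is.finite(arena)
  dx <- vapply(x, coord_diff_r, numeric(1), b = x[i], L = arena, periodic = periodic)
  dy <- vapply(y, coord_diff_r, numeric(1), b = y[i], L = arena, periodic = periodic)
  ok <- dx^2 + dy^2 <= R^2
  c(mean(vx[ok]), mean(vy[ok]))
}

#' Candidate next positions
#'
#' The 72 positions at distance `u` from the anticipated position, at angles
#' `0, pi/36, ..., 71*pi/36` (the full turn; the angle `2*pi` coincides with
#' `0` and is not duplicated).
#'
#' @param xhat Length-2 numeric, the anticipated position.
#' @param u Step length.
#' @return A `72 x 2` matrix of candidate positions.
#' @export
candidate_positions <- function(xhat, u) {
  if (u <= 0) stop("u must be positive")
  th <- (0:71) * pi / 36
  cbind(x = xhat[1] + u * cos(th), y = xhat[2] + u * sin(th))
}

#' Choose the density-matching candidate
#'
#' Evaluates the density datum each candidate position would experience
#' against the other agents' current positions and returns the candidate
#' minimizing `|d - d_max|`; ties are broken uniformly at random.
#'
#' @param candidates Matrix of candidate positions (rows).
#' @param others_x,others_y Positions of the other agents.
#' @param d_max Preferred density level in `0..3`.
#' @param r Inner density radius.
#' @param arena Arena side (for periodic distances).
#' @param boundary `"periodic"` or `"reflecting"`.
#' @return Length-2 numeric, the chosen position, with attribute `d` (its
#'   density datum).
#' @export
choose_position <- function(candidates, others_x, others_y, d_max, r,
                            arena = Inf, boundary = "periodic") {
  if (nrow(candidates) < 1L) stop("candidates must be nonempty")
  periodic <- boundary == "periodic" && is.finite(arena)
  ds <- vapply(seq_len(nrow(candidates)), function(k) {
    dx <- vapply(others_x, coord_diff_r, numeric(1), b = candidates[k, 1],
                 L = arena, periodic = periodic)
    dy <- vapply(others_y, coord_diff_r, numeric(1), b = candidates[k, 2],
                 L = arena, periodic = periodic)
    d2 <- dx^2 + dy^2
    density_code_r(sum(d2 <= r^2), sum(d2 <= 4 * r^2))
  }, integer(1))
  sc <- abs(ds - d_max)
  ties <- which(sc == min(sc))
  k <- if (length(ties) > 1L) ties[sample_int(length(ties))] else ties
  structure(candidates[k, ], d = ds[k])
}
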