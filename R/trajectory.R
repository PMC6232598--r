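#' Multi-individual trajectory dataset
#'
#' Time-indexed 2-D positions for `N` individuals, stored as `T x N` matrices
#' of x and y coordinates (one row per frame). Built from a long-format
#' data.frame with columns `id`, `frame`, `x`, `y`, as produced by video
#' tracking software or by the simulators in this package. Frames are aligned
#' on the union of observed frame indices; an individual may be absent
#' (coded `NA`) outside its observed span, but gaps inside the span are
#' rejected.
#'
#' @param df data.frame with columns `id`, `frame`, `x`, `y`.
#' @param dt Frame interval in seconds (0.1 s for the tracking setup this
#'   pipeline emulates).
#' @param mm_per_unit Optional physical scale of the coordinate unit
#'   (4.76 mm per pixel for the targeted video-tracking setup); carried as
#'   metadata, never applied implicitly.
#' @return An object of class `trajectory_dataset` with fields `x`, `y`
#'   (`T x N` matrices), `ids`, `frames`, `dt`, `mm_per_unit`.
#' @examples
#' df <- data.frame(id = rep(1:2, each = 3), frame = rep(0:2, 2),
#'                  x = c(0, 1, 2, 5, 5, 5), y = 0)
#' traj <- trajectory_dataset(df, dt = 0.1)
#' dim(traj$x)
#' @export
trajectory_dataset <- function(df, dt = 0.1, mm_per_unit = NULL) {
  need <- c("id", "frame", "x", "y")
  if (!all(need %in% names(df))) {
    stop("df must have columns id, frame, x, y")
  }
  if (nrow(df) == 0L) {
    warning("empty trajectory dataset (N = 0)")
    return(structure(list(x = matrix(numeric(0), 0, 0),
                          y = matrix(numeric(0), 0, 0),
                          ids = character(0), frames = integer(0),
                          dt = dt, mm_per_unit = mm_per_unit),
                     class = "trajectory_dataset"))
  }
  if (!is.numeric(df$x) || !is.numeric(df$y) || any(!is.finite(df$x)) ||
      any(!is.finite(df$y))) {
    stop("coordinates must be finite numerics")
  }
  ids <- sort(unique(df$id))
  frames <- sort(unique(as.integer(df$frame)))
  if (anyDuplicated(df[c("id", "frame")])) {
    dup <- which(duplicated(df[c("id", "frame")]))[1L]
    stop(sprintf("duplicate (id, frame) pair at row %d: id=%s frame=%s",
                 dup, df$id[dup], df$frame[dup]))
  }
  Tn <- length(frames)
  N <- length(ids)
  X <- matrix(NA_real_, Tn, N)
  Y <- matrix(NA_real_, Tn, N)
  fi <- match(as.integer(df$frame), frames)
  ii <- match(df$id, ids)
  X[cbind(fi, ii)] <- df$x
  Y[cbind(fi, ii)] <- df$y
  # no gaps inside an individual's observed span
  for (j in seq_len(N)) {
    obs <- which(!is.na(X[, j]))
    if (length(obs) > 0L && any(diff(obs) != 1L)) {
      stop(sprintf("individual %s has missing frames inside its observed span",
                   ids[j]))
    }
  }
  structure(list(x = X, y = Y, ids = ids, frames = frames, dt = dt,
                 mm_per_unit = mm_per_unit),
            class = "trajectory_dataset")
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf("<trajectory_dataset> %d individuals x %d frames, dt = %g s\n",
              ncol(x$x), nrow(x$x), x$dt))
  invisible(x)
}

#' Convert a trajectory dataset to long format
#'
#' @param traj A [trajectory_dataset()].
#' @return data.frame with columns `id`, `frame`, `x`, `y` (observed
#'   positions only).
#' @export
as_trajectory_df <- function(traj) {
  stopifnot(inherits(traj, "trajectory_dataset"))
  out <- do.call(rbind, lapply(seq_along(traj$ids), function(j) {
    obs <- which(!is.na(traj$x[, j]))
    data.frame(id = traj$ids[j], frame = traj$frames[obs],
               x = traj$x[obs, j], y = traj$y[obs, j])
  }))
  rownames(out) <- NULL
  out
}

#' Frame-to-frame velocities
#'
#' Forward differences of position at the native frame interval:
#' `V^t = x^{t+1} - x^t`, defined for frames `1..T-1`.
#'
#' @param traj A [trajectory_dataset()].
#' @return List with `vx`, `vy` (`(T-1) x N` matrices, length units per
#'   frame) and `frames` (the frame index each velocity is attached to).
#' @export
velocities <- function(traj) {
  stopifnot(inherits(traj, "trajectory_dataset"))
  Tn <- nrow(traj$x)
  if (Tn < 2L) stop("need at least two frames for velocities")
  list(vx = diff(traj$x), vy = diff(traj$y),
       frames = traj$frames[-Tn])
}

#' Polarization of one frame
#'
#' The norm of the mean unit velocity vector:
#' `psi = || sum_k V_k / ||V_k|| || / N'`, with `N'` the number of
#' individuals included. Individuals with zero speed (undefined heading) or
#' missing velocity are excluded; a frame with no usable individual has
#' undefined polarization (`NA`).
#'
#' @param vx,vy Numeric vectors of velocity components for one frame.
#' @return `psi` in `[0, 1]`, with attribute `n_included`; `NA` when no
#'   individual has a defined heading.
#' @examples
#' polarization_frame(c(1, 0), c(0, 1)) # sqrt(2)/2
#' @export
polarization_frame <- function(vx, vy) {
  sp <- sqrt(vx^2 + vy^2)
  ok <- !is.na(sp) & sp > 0
  n <- sum(ok)
  if (n == 0L) return(structure(NA_real_, n_included = 0L))
  psi <- sqrt(sum(vx[ok] / sp[ok])^2 + sum(vy[ok] / sp[ok])^2) / n
  structure(psi, n_included = n)
}

#' Polarization time series
#'
#' @param traj A [trajectory_dataset()].
#' @return data.frame with columns `frame`, `psi`, `n_included`; one row per
#'   velocity frame (`T - 1` rows).
#' @export
polarization <- function(traj) {
  v <- velocities(traj)
  res <- lapply(seq_len(nrow(v$vx)), function(t) {
    polarization_frame(v$vx[t, ], v$vy[t, ])
  })
  data.frame(frame = v$frames,
             psi = vapply(res, as.numeric, numeric(1)),
             n_included = vapply(res, attr, integer(1), "n_included"))
}
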