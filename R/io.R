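#' Read a trajectory CSV
#'
#' Reads tracked positions from a CSV with the exact header
#' `id,frame,x,y` and validates it: numeric coordinates, no duplicate
#' `(id, frame)` pairs, no gaps inside an individual's observed span.
#' Errors cite the offending line number of the file.
#'
#' @param path Path to the CSV file.
#' @param dt Frame interval in seconds.
#' @param mm_per_unit Optional physical scale metadata.
#' @return A [trajectory_dataset()].
#' @export
read_trajectory_csv <- function(path, dt = 0.1, mm_per_unit = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "id,frame,x,y")) {
    stop(sprintf("%s: header must be exactly 'id,frame,x,y', got '%s'",
                 path, header))
  }
  df <- utils::read.csv(path, colClasses = c("character", "integer",
                                             "numeric", "numeric"))
  if (nrow(df) == 0L) {
    warning(sprintf("%s: no data rows", path))
    return(suppressWarnings(trajectory_dataset(df, dt = dt,
                                               mm_per_unit = mm_per_unit)))
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    bad <- which(!is.finite(df$x) | !is.finite(df$y))[1L]
    stop(sprintf("%s: non-finite coordinate at line %d", path, bad + 1L))
  }
  dup <- which(duplicated(df[c("id", "frame")]))
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicate (id, frame) = (%s, %d) at line %d",
                 path, df$id[dup[1L]], df$frame[dup[1L]], dup[1L] + 1L))
  }
  trajectory_dataset(df, dt = dt, mm_per_unit = mm_per_unit)
}

#' Write a trajectory CSV
#'
#' @param traj A [trajectory_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as_trajectory_df(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# every run-configurable key with its default and validity check
config_schema <- function() {
  list(
    n_symbols = list(default = 4L, check = function(v) v >= 2),
    p = list(default = 0.7, check = function(v) v > 0 && v <= 1),
    M = list(default = 100L, check = function(v) v >= 1),
    mode = list(default = "bib", check = function(v) v %in% c("bib", "b")),
    seed = list(default = NULL, check = function(v) is.null(v) || v == as.integer(v)),
    dt = list(default = 0.1, check = function(v) v > 0),
    mm_per_unit = list(default = 4.76, check = function(v) v > 0),
    r = list(default = 30, check = function(v) v > 0),
    R = list(default = NULL, check = function(v) is.null(v) || v > 0),
    u = list(default = 1, check = function(v) v > 0),
    n_agents = list(default = 100L, check = function(v) v >= 2),
    arena = list(default = NULL, check = function(v) is.null(v) || v > 0),
    boundary = list(default = "periodic",
                    check = function(v) v %in% c("periodic", "reflecting")),
    order = list(default = "async", check = function(v) v %in% c("async", "sync")),
    steps = list(default = 5000L, check = function(v) v >= 1),
    baseline = list(default = 0.5, check = function(v) v >= 0 && v <= 1),
    amplitude = list(default = 0.4, check = function(v) v >= 0 && v <= 1),
    period = list(default = 1000, check = function(v) v > 0),
    horizon = list(default = 5000L, check = function(v) v >= 1)
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration, applies defaults, rejects unknown keys and
#' out-of-range values, and enforces cross-field constraints (the likelihood
#' peak `p` must exceed `1/n`).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list of class `bib_config` with every key populated.
#' @export
load_config <- function(path = NULL) {
  schema <- config_schema()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(schema))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- lapply(names(schema), function(k) {
    v <- if (k %in% names(user)) user[[k]] else schema[[k]]$default
    if (!is.null(v) && !isTRUE(schema[[k]]$check(v))) {
      stop(sprintf("config key '%s' out of range: %s", k, format(v)))
    }
    v
  })
  names(cfg) <- names(schema)
  if (is.null(cfg$R)) cfg$R <- cfg$r
  if (is.null(cfg$arena)) cfg$arena <- 10 * cfg$r
  if (cfg$p <= 1 / cfg$n_symbols) {
    stop(sprintf("config: p = %g must exceed 1/n = %g", cfg$p,
                 1 / cfg$n_symbols))
  }
  class(cfg) <- "bib_config"
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg A [load_config()] result (or compatible named list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' @export
print.bib_config <- function(x, ...) {
  cat("<bib_config>\n")
  for (k in names(x)) {
    if (!is.null(x[[k]])) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  }
  invisible(x)
}

# provenance line: version, seed and effective config, enough to reproduce
log_run <- function(what, cfg, seed) {
  msg <- sprintf("[bibswarm %s] %s seed=%s %s",
                 as.character(utils::packageVersion("bibswarm")), what,
                 if (is.null(seed)) "NULL" else seed,
                 paste(sprintf("%s=%s",
                               names(cfg)[!vapply(cfg, is.null, logical(1))],
                               vapply(cfg[!vapply(cfg, is.null, logical(1))],
                                      function(v) paste(format(v), collapse = ","),
                                      character(1))),
                       collapse = " "))
  message(msg)
  invisible(msg)
}
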