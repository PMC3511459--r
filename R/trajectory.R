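#' Construct a trajectory of regularly sampled fixes
#'
#' @param time fix times in seconds, strictly increasing with constant spacing
#'   (within 1e-6 s).
#' @param x,y planar coordinates in meters.
#' @param label optional character label (e.g. a flight-section name).
#' @return an object of class `trajectory`: a list with `time`, `x`, `y`,
#'   `delta` (the sampling interval) and `label`.
#' @export
trajectory <- function(time, x, y, label = NULL) {
  stopifnot(length(time) >= 2, length(x) == length(time), length(y) == length(time))
  if (anyNA(time) || anyNA(x) || anyNA(y))
    stop("fixes must not contain NA", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0)) stop("fix times must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-6)
    stop("irregular sampling interval: resample the fixes to a constant step first",
         call. = FALSE)
  structure(list(time = as.numeric(time), x = as.numeric(x), y = as.numeric(y),
                 delta = mean(dt), label = label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory%s: %d fixes at %.3g s spacing, %.1f m total length\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$time), x$delta, total_length(x)))
  invisible(x)
}

#' Read trajectory fixes from delimited text
#'
#' Accepts comma- or tab-separated text with a header row naming either
#' `time,x,y` (planar meters, passed through) or `time,lon,lat` (degrees,
#' projected to a local tangent plane: equirectangular about the mean
#' latitude, spherical earth radius 6371008.8 m). The projection is a
#' convenience for roughly kilometre-scale tracks; proper map projections
#' should be applied upstream for anything larger.
#'
#' @param path file path.
#' @param label optional label stored on the trajectory.
#' @return a [trajectory()].
#' @export
read_fixes <- function(path, label = NULL) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep)
  nm <- tolower(names(d))
  names(d) <- nm
  if (!"time" %in% nm) stop("input must have a 'time' column", call. = FALSE)
  if (anyDuplicated(d$time)) stop("duplicate timestamps in input", call. = FALSE)
  if (all(c("x", "y") %in% nm)) {
    trajectory(d$time, d$x, d$y, label = label)
  } else if (all(c("lon", "lat") %in% nm)) {
    R <- 6371008.8
    lat0 <- mean(d$lat) * pi / 180
    lon0 <- mean(d$lon) * pi / 180
    x <- R * cos(lat0) * (d$lon * pi / 180 - lon0)
    y <- R * (d$lat * pi / 180 - lat0)
    message("projected lon/lat to a local tangent plane (meters)")
    trajectory(d$time, x, y, label = label)
  } else {
    stop("columns must be time,x,y or time,lon,lat", call. = FALSE)
  }
}

#' Write trajectory fixes as CSV
#'
#' Inverse of [read_fixes()] for planar input: writes `time,x,y` columns.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @export
write_fixes <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(data.frame(time = traj$time, x = traj$x, y = traj$y),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Total path length of a trajectory
#'
#' Sum of consecutive Euclidean fix-to-fix distances, in meters.
#'
#' @param traj a [trajectory()].
#' @export
total_length <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Construct a step series directly
#'
#' Aligned headings and speeds at a fixed time unit, the input to all model
#' fitting. Usually produced by [derive_steps()]; this constructor exists so
#' simulated heading/speed sequences can be fitted without a positional
#' round-trip.
#'
#' @param headings heading angles, radians (`[-pi, pi)`), one per step.
#' @param speeds speeds in m/s, one per step (may be `NA` when only the
#'   heading model is of interest).
#' @param time_unit step duration in seconds.
#' @param fixes optional `(n_steps + 1) x 2` matrix of the fix coordinates,
#'   required by focal-point models and the final-location test.
#' @return an object of class `step_series`.
#' @export
step_series <- function(headings, speeds = rep(NA_real_, length(headings)),
                        time_unit = 1, fixes = NULL) {
  stopifnot(length(speeds) == length(headings), time_unit > 0)
  if (!is.null(fixes)) {
    fixes <- as.matrix(fixes)
    stopifnot(nrow(fixes) == length(headings) + 1, ncol(fixes) == 2)
  }
  ok <- !is.na(headings)
  if (any(ok)) headings[ok] <- wrap_angle(headings[ok])
  structure(list(time_unit = time_unit,
                 headings = as.numeric(headings),
                 speeds = as.numeric(speeds),
                 n_steps = length(headings),
                 fixes = fixes),
            class = "step_series")
}

#' @export
print.step_series <- function(x, ...) {
  cat(sprintf("step_series: %d steps at time unit %g s\n", x$n_steps, x$time_unit))
  invisible(x)
}

#' Resample a trajectory and derive headings and speeds
#'
#' Keeps the fixes at indices 0, T/delta, 2T/delta, ... (anchored at the first
#' fix; a trailing partial step is dropped), then derives for each retained
#' step the heading as the two-argument arctangent of the displacement and the
#' speed as step length / T. A 500-s section sampled at 0.5 s (1001 fixes)
#' yields 500 steps at `time_unit = 1` and 166 at `time_unit = 3`.
#'
#' Zero-length steps have no defined heading; they are returned as `NA` with a
#' warning and are rejected by the fitting functions (the models describe
#' continuous movement).
#'
#' @param traj a [trajectory()].
#' @param time_unit resampling interval T in seconds; must be an integer
#'   multiple of the trajectory's sampling interval.
#' @return a [step_series()] carrying the retained fixes.
#' @export
derive_steps <- function(traj, time_unit) {
  stopifnot(inherits(traj, "trajectory"), time_unit > 0)
  k <- time_unit / traj$delta
  if (abs(k - round(k)) > 1e-9)
    stop("'time_unit' must be an integer multiple of the sampling interval ",
         traj$delta, call. = FALSE)
  k <- round(k)
  idx <- seq(1, length(traj$time), by = k)
  if (length(idx) < 2) stop("time unit too coarse for this trajectory", call. = FALSE)
  xs <- traj$x[idx]; ys <- traj$y[idx]
  dx <- diff(xs); dy <- diff(ys)
  len <- sqrt(dx^2 + dy^2)
  headings <- atan2(dy, dx)
  if (any(len == 0)) {
    warning("zero-length step(s): heading undefined, set to NA")
    headings[len == 0] <- NA_real_
  }
  step_series(headings = headings,
              speeds = len / time_unit,
              time_unit = time_unit,
              fixes = cbind(xs, ys))
}
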