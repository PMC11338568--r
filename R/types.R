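#' Pedestrian track
#'
#' Timed 2-D positions of one pedestrian. Coordinates follow the global
#' convention: x along the corridor long axis (increasing in the rightward
#' group's travel direction), y transverse in `[0, meas_width]`.
#'
#' @param ped_id Pedestrian identifier (character).
#' @param group `"rightward"` or `"leftward"`: direction of travel along x.
#' @param t Sample times (s), strictly increasing.
#' @param x,y Positions (m), finite, same length as `t`.
#' @param sample_rate Nominal sampling rate (Hz), default 30.
#' @param shoulders Optional data frame with columns `t`, `lx`, `ly`, `rx`,
#'   `ry`: left/right shoulder marker positions (m).
#' @return An object of class `pedestrian_track`.
#' @export
pedestrian_track <- function(ped_id, group, t, x, y, sample_rate = 30,
                             shoulders = NULL) {
  group <- match.arg(group, c("rightward", "leftward"))
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) < 1 || length(x) != length(t) || length(y) != length(t))
    stop("t, x, y must be non-empty and of equal length")
  if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y)))
    stop(sprintf("track %s: non-finite sample values", ped_id))
  if (any(diff(t) <= 0))
    stop(sprintf("track %s: sample times must be strictly increasing", ped_id))
  if (!is.null(shoulders)) {
    need <- c("t", "lx", "ly", "rx", "ry")
    if (!all(need %in% names(shoulders)))
      stop("shoulders must have columns t, lx, ly, rx, ry")
    shoulders <- as.data.frame(shoulders)[need]
  }
  structure(list(ped_id = as.character(ped_id), group = group,
                 t = t, x = x, y = y, sample_rate = sample_rate,
                 shoulders = shoulders),
            class = "pedestrian_track")
}

#' @export
print.pedestrian_track <- function(x, ...) {
  cat(sprintf("pedestrian %s (%s): %d samples, t in [%.2f, %.2f] s\n",
              x$ped_id, x$group, length(x$t), x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' Heel-strike series for one foot
#'
#' @param ped_id Pedestrian identifier.
#' @param foot `"left"` or `"right"`.
#' @param strikes Heel-strike times (s), strictly increasing.
#' @return Object of class `step_series`. Step durations (time between two
#'   consecutive heel strikes of this foot) are available via
#'   [step_durations()].
#' @export
step_series <- function(ped_id, foot, strikes) {
  foot <- match.arg(foot, c("left", "right"))
  strikes <- as.numeric(strikes)
  if (length(strikes) && any(diff(strikes) <= 0))
    stop(sprintf("step series %s/%s: strike times must be strictly increasing",
                 ped_id, foot))
  structure(list(ped_id = as.character(ped_id), foot = foot, strikes = strikes),
            class = "step_series")
}

#' Step durations of a series
#'
#' Time between consecutive heel strikes of the same foot.
#' @param series A [step_series()].
#' @return Numeric vector of length `length(strikes) - 1`.
#' @export
step_durations <- function(series) diff(series$strikes)

#' @export
print.step_series <- function(x, ...) {
  cat(sprintf("step series %s/%s: %d strikes\n", x$ped_id, x$foot,
              length(x$strikes)))
  invisible(x)
}

#' Inertial angular-velocity trace
#'
#' Medio-lateral angular velocity of one foot, regularly sampled.
#'
#' @param ped_id Pedestrian identifier.
#' @param foot `"left"` or `"right"`.
#' @param omega Medio-lateral angular velocity samples (deg/s), length >= 2.
#' @param sample_rate Sampling rate (Hz), default 100.
#' @param t0 Time of the first sample (s), default 0.
#' @param events_hint Optional data frame with columns `toe_off_t`,
#'   `heel_strike_t` delimiting swing intervals; when present, heel-strike
#'   detection is restricted to these intervals.
#' @return Object of class `imu_trace`.
#' @export
imu_trace <- function(ped_id, foot, omega, sample_rate = 100, t0 = 0,
                      events_hint = NULL) {
  foot <- match.arg(foot, c("left", "right"))
  omega <- as.numeric(omega)
  if (!is.finite(sample_rate) || sample_rate <= 0) stop("sample_rate must be > 0")
  if (length(omega) < 2) stop("imu trace must have at least 2 samples")
  if (!is.null(events_hint)) {
    need <- c("toe_off_t", "heel_strike_t")
    if (!all(need %in% names(events_hint)))
      stop("events_hint must have columns toe_off_t, heel_strike_t")
    events_hint <- as.data.frame(events_hint)[need]
  }
  structure(list(ped_id = as.character(ped_id), foot = foot, omega = omega,
                 sample_rate = sample_rate, t0 = t0,
                 events_hint = events_hint),
            class = "imu_trace")
}

# sample times of an imu trace
imu_times <- function(trace) {
  trace$t0 + (seq_along(trace$omega) - 1) / trace$sample_rate
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf("imu trace %s/%s: %d samples at %g Hz\n", x$ped_id, x$foot,
              length(x$omega), x$sample_rate))
  invisible(x)
}

#' Trial dataset
#'
#' A complete trial: geometry, condition label, all pedestrian tracks and the
#' step series of instrumented pedestrians.
#'
#' @param trial_id Trial identifier.
#' @param condition `"NO_CUE"` or `"CUE"`.
#' @param geometry A [corridor_geometry()].
#' @param tracks List of [pedestrian_track()]s; both travel directions must be
#'   present.
#' @param steps List of [step_series()]; every `ped_id` must exist among
#'   `tracks`.
#' @param imu Optional list of [imu_trace()]s.
#' @param order_index Integer order of the trial within its condition.
#' @param meta Optional named list of per-pedestrian metadata (e.g. start row
#'   and column), carried through to reports.
#' @return Object of class `trial_dataset`.
#' @export
trial_dataset <- function(trial_id, condition, geometry, tracks,
                          steps = list(), imu = list(), order_index = NA_integer_,
                          meta = NULL) {
  condition <- match.arg(condition, c("NO_CUE", "CUE"))
  stopifnot(inherits(geometry, "corridor_geometry"))
  if (length(tracks) < 1) stop("trial must contain at least one track")
  ok <- vapply(tracks, inherits, logical(1), "pedestrian_track")
  if (!all(ok)) stop("tracks must all be pedestrian_track objects")
  ids <- vapply(tracks, `[[`, character(1), "ped_id")
  if (anyDuplicated(ids)) stop("duplicate ped_id among tracks")
  names(tracks) <- ids
  groups <- vapply(tracks, `[[`, character(1), "group")
  if (length(unique(groups)) < 2)
    warning(sprintf("trial %s: only one travel direction present", trial_id))
  # transverse positions must respect the global coordinate convention
  for (tr in tracks) {
    if (any(tr$y < -1e-9 | tr$y > geometry$meas_width + 1e-9))
      stop(sprintf("track %s: y outside [0, %g] m; coordinates must have x along the corridor long axis",
                   tr$ped_id, geometry$meas_width))
  }
  for (ss in steps) {
    if (!inherits(ss, "step_series")) stop("steps must be step_series objects")
    if (!ss$ped_id %in% ids)
      stop(sprintf("step series for unknown pedestrian %s", ss$ped_id))
  }
  structure(list(trial_id = as.character(trial_id), condition = condition,
                 geometry = geometry, tracks = tracks, steps = steps,
                 imu = imu, order_index = as.integer(order_index),
                 meta = meta),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  groups <- vapply(x$tracks, `[[`, character(1), "group")
  cat(sprintf("trial %s (%s): %d pedestrians (%d rightward, %d leftward), %d step series\n",
              x$trial_id, x$condition, length(x$tracks),
              sum(groups == "rightward"), sum(groups == "leftward"),
              length(x$steps)))
  invisible(x)
}

#' Step series grouped by pedestrian
#'
#' @param ds A [trial_dataset()].
#' @return Named list: `ped_id -> list(left = , right = )` of
#'   [step_series()] objects (feet missing from the data are absent).
#' @export
steps_by_ped <- function(ds) {
  out <- list()
  for (ss in ds$steps) out[[ss$ped_id]][[ss$foot]] <- ss
  out
}

# all strikes of one pedestrian (both feet), sorted
merged_strikes <- function(ds, ped_id) {
  s <- steps_by_ped(ds)[[ped_id]]
  sort(c(if (!is.null(s$left)) s$left$strikes,
         if (!is.null(s$right)) s$right$strikes))
}

# group label per ped_id
ped_groups <- function(ds) {
  vapply(ds$tracks, `[[`, character(1), "group")
}
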