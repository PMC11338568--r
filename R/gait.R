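#' Heel-strike detection parameters
#'
#' @param median_window Median-filter window length in samples; odd, >= 3
#'   (default 5).
#' @param min_peak_separation Minimum time between retained peaks (s,
#'   default 0.4 - roughly half a stride at normal cadence).
#' @param prominence_fraction Minimum peak height as a fraction of the
#'   filtered trace maximum (default 0.3).
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(median_window = 5, min_peak_separation = 0.4,
                             prominence_fraction = 0.3) {
  if (median_window < 3 || median_window %% 2 == 0)
    stop("median_window must be odd and >= 3")
  if (min_peak_separation <= 0) stop("min_peak_separation must be > 0")
  structure(list(median_window = as.integer(median_window),
                 min_peak_separation = min_peak_separation,
                 prominence_fraction = prominence_fraction),
            class = "detection_params")
}

# strict local maxima; plateau ties resolved to the leftmost sample
local_maxima <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  starts <- cumsum(r$lengths) - r$lengths + 1L
  mid <- 2:(k - 1)
  ok <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
  starts[mid][ok]
}

#' Detect heel strikes in an IMU trace
#'
#' Applies a median filter of length `median_window`, then retains local
#' maxima of the filtered medio-lateral angular velocity that (i) reach at
#' least `prominence_fraction` of the filtered trace maximum, (ii) are at
#' least `min_peak_separation` apart (conflicts resolved by keeping the
#' higher peak; ties by the earlier one), and (iii) when the trace carries
#' `events_hint` annotations, lie inside a toe-off-to-heel-strike interval.
#' Plateau maxima are assigned to their leftmost sample.
#'
#' @param trace An [imu_trace()].
#' @param params A [detection_params()].
#' @return A [step_series()] of detected heel-strike times. An all-constant
#'   trace yields an empty series with a warning.
#' @export
detect_heel_strikes <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "imu_trace"))
  v <- trace$omega
  if (length(v) <= params$median_window)
    stop("trace shorter than the median-filter window")
  if (max(v) == min(v)) {
    warning(sprintf("imu trace %s/%s is constant; no strikes detected",
                    trace$ped_id, trace$foot))
    return(step_series(trace$ped_id, trace$foot, numeric(0)))
  }
  f <- as.numeric(stats::runmed(v, params$median_window, endrule = "keep"))
  tt <- imu_times(trace)
  cand <- local_maxima(f)
  cand <- cand[f[cand] >= params$prominence_fraction * max(f)]
  if (!is.null(trace$events_hint) && nrow(trace$events_hint)) {
    h <- trace$events_hint
    ok <- vapply(cand, function(i)
      any(tt[i] > h$toe_off_t & tt[i] <= h$heel_strike_t + 1e-9), logical(1))
    cand <- cand[ok]
  }
  # greedy separation constraint: keep higher peaks first, earlier on ties
  ord <- cand[order(-f[cand], tt[cand])]
  kept <- numeric(0)
  for (i in ord) {
    if (all(abs(tt[i] - kept) >= params$min_peak_separation))
      kept <- c(kept, tt[i])
  }
  step_series(trace$ped_id, trace$foot, sort(kept))
}

#' Relative deviation of realized cadence from a tempo
#'
#' Merges the strike times of both feet, computes the mean inter-strike
#' interval and the realized combined cadence (strikes/min), and returns the
#' absolute relative deviation from `tempo`.
#'
#' @param steps A list of one or two [step_series()] for the same pedestrian.
#' @param tempo Reference combined cadence (strikes/min, default 120).
#' @return Fraction `|cadence - tempo| / tempo`, or `NA` when fewer than 3
#'   strikes are available.
#' @export
step_frequency_deviation <- function(steps, tempo = 120) {
  if (inherits(steps, "step_series")) steps <- list(steps)
  strikes <- sort(unlist(lapply(steps, `[[`, "strikes")))
  if (length(strikes) < 3) return(NA_real_)
  ibar <- mean(diff(strikes))
  abs(60 / ibar - tempo) / tempo
}
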