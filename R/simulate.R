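#' Simulation configuration
#'
#' Free parameters of the kinematic bidirectional-flow generator. Two groups
#' of `n_per_group` pedestrians start on opposing waiting grids (`rows` start
#' lines of `cols` pedestrians, `row_spacing` apart) and walk toward opposite
#' ends of the corridor. Each pedestrian's transverse position relaxes
#' exponentially toward its assigned lane centre with mean-reverting
#' (Ornstein-Uhlenbeck) lateral noise and a transverse avoidance deflection
#' when an oncoming pedestrian is within 2 m ahead at small lateral offset.
#'
#' Lanes are unidirectional and alternate travel direction across the corridor
#' width; `n_lanes` is the total lane count, so rightward walkers occupy the
#' odd-numbered lanes and leftward walkers the even-numbered ones. Walking
#' speed is drawn once per lane (a platoon moving at common speed), which
#' keeps within-lane spacing - and hence the following relation - stable over
#' a trial.
#'
#' Heel strikes follow an alternating-foot phase model. With
#' `cue_mode = "metronome_locked"` strikes fall on metronome ticks (combined
#' two-foot cadence equal to `tempo`; the tick train starts at t = 0 and each
#' pedestrian randomly starts on either foot) plus `N(0, phase_jitter_sd^2)`
#' timing noise. With `cue_mode = "independent"` each pedestrian draws a
#' stride frequency `N(tempo/120, freq_sd^2)` (Hz per foot) and a uniform
#' initial phase; `duration_coupling` then shrinks the frequency gap between
#' each pedestrian and the pedestrian immediately ahead in its lane by that
#' fraction, front to back.
#'
#' @param n_per_group Pedestrians per group (default 24).
#' @param rows,cols Start grid: number of start lines and pedestrians per
#'   line (defaults 8 and 3).
#' @param row_spacing Distance between start lines (m, default 1.2).
#' @param n_lanes Total number of unidirectional lanes (default 3).
#' @param speed_mean,speed_sd Lane walking-speed distribution (m/s; defaults
#'   1.3 and 0.1).
#' @param lateral_relax_time Relaxation time of y toward the lane centre (s).
#' @param lateral_noise_sd Stationary SD of the lateral noise (m).
#' @param avoidance_gain Transverse deflection speed while avoiding (m/s).
#' @param tempo Metronome tempo: combined two-foot cadence (strikes/min,
#'   default 120).
#' @param cue_mode `"metronome_locked"` (CUE) or `"independent"` (NO_CUE).
#' @param phase_jitter_sd Per-strike timing jitter SD (s).
#' @param freq_sd SD of the per-pedestrian stride frequency (Hz), independent
#'   mode only.
#' @param duration_coupling Fraction in `[0, 1]` by which a follower's stride
#'   frequency is pulled toward its within-lane predecessor's (independent
#'   mode only).
#' @param imu_noise_sd Sample noise SD of synthesized IMU traces (deg/s).
#' @param sample_rate Trajectory sampling rate (Hz, default 30).
#' @param instrument Which group wears IMUs: `"rightward"`, `"leftward"` or
#'   `"both"`.
#' @param seed Integer seed; identical seeds give bitwise-identical trials.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 24, rows = 8, cols = 3, row_spacing = 1.2,
                       n_lanes = 3, speed_mean = 1.3, speed_sd = 0.1,
                       lateral_relax_time = 0.5, lateral_noise_sd = 0.1,
                       avoidance_gain = 0.8, tempo = 120,
                       cue_mode = c("independent", "metronome_locked"),
                       phase_jitter_sd = 0.02, freq_sd = 0.05,
                       duration_coupling = 0.5, imu_noise_sd = 0.05,
                       sample_rate = 30, instrument = "rightward",
                       seed = 1L) {
  cue_mode <- match.arg(cue_mode)
  instrument <- match.arg(instrument, c("rightward", "leftward", "both"))
  if (n_lanes < 1) stop("n_lanes must be >= 1")
  sds <- c(speed_sd, lateral_noise_sd, phase_jitter_sd, freq_sd, imu_noise_sd)
  if (any(sds < 0)) stop("all noise SDs must be >= 0")
  if (duration_coupling < 0 || duration_coupling > 1)
    stop("duration_coupling must lie in [0, 1]")
  if (n_per_group > rows * cols)
    stop("start grid too small for n_per_group")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d/group, %d lanes, %s, tempo %g/min, seed %d\n",
              x$n_per_group, x$n_lanes, x$cue_mode, x$tempo, x$seed))
  invisible(x)
}

#' Condition preset
#'
#' Generator configuration emulating one experimental condition. Relative to
#' the NO_CUE baseline, the CUE preset locks gait to the metronome, narrows
#' the lateral exploration noise and forms one more (thinner) lane - the
#' spatial signature reported for metronome-paced crowds.
#'
#' @param condition `"NO_CUE"` or `"CUE"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
condition_preset <- function(condition = c("NO_CUE", "CUE"), seed = 1L, ...) {
  condition <- match.arg(condition)
  over <- list(...)
  base <- if (condition == "CUE")
    list(cue_mode = "metronome_locked", n_lanes = 4, lateral_noise_sd = 0.05,
         phase_jitter_sd = 0.02, seed = seed)
  else
    list(cue_mode = "independent", n_lanes = 3, lateral_noise_sd = 0.1,
         duration_coupling = 0.5, seed = seed)
  base[names(over)] <- over
  do.call(sim_config, base)
}

# lane centres and travel direction of each lane
lane_layout <- function(n_lanes, width) {
  centre <- width * (seq_len(n_lanes) - 0.5) / n_lanes
  dir <- ifelse(seq_len(n_lanes) %% 2 == 1, "rightward", "leftward")
  data.frame(lane = seq_len(n_lanes), centre = centre, dir = dir,
             stringsAsFactors = FALSE)
}

#' Simulate one bidirectional-flow trial
#'
#' @param cfg A [sim_config()].
#' @param geometry A [corridor_geometry()].
#' @param trial_id Trial identifier.
#' @param condition Condition label; derived from `cfg$cue_mode` when `NULL`.
#' @param order_index Trial order within its condition.
#' @return A list with elements `dataset` (a [trial_dataset()]) and `truth`
#'   (a data frame with per-pedestrian lane assignment, lane centre, speed,
#'   stride frequency, phase offset and intended within-lane predecessor).
#' @examples
#' sim <- simulate_trial(sim_config(n_per_group = 6, rows = 2, seed = 42))
#' sim$dataset
#' head(sim$truth)
#' @export
simulate_trial <- function(cfg, geometry = corridor_geometry(),
                           trial_id = "T01", condition = NULL,
                           order_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (geometry$meas_width / cfg$n_lanes < 0.5)
    stop(sprintf("infeasible geometry: %d lanes do not fit a %g m wide corridor",
                 cfg$n_lanes, geometry$meas_width))
  if (is.null(condition))
    condition <- if (cfg$cue_mode == "metronome_locked") "CUE" else "NO_CUE"
  set.seed(cfg$seed)

  n <- cfg$n_per_group
  L <- geometry$meas_length
  W <- geometry$meas_width
  lanes <- lane_layout(cfg$n_lanes, W)
  idx <- seq_len(n) - 1L
  row <- idx %/% cfg$cols
  col <- idx %% cfg$cols
  stagger <- 0.25 * col
  y0 <- W * (col + 0.5) / cfg$cols

  ped <- data.frame(
    ped_id = c(sprintf("R%02d", seq_len(n)), sprintf("L%02d", seq_len(n))),
    group = rep(c("rightward", "leftward"), each = n),
    dir = rep(c(1, -1), each = n),
    row = c(row, row), col = c(col, col),
    x0 = c(-geometry$buffer_length - row * cfg$row_spacing - stagger,
           L + geometry$buffer_length + row * cfg$row_spacing + stagger),
    y0 = c(y0, y0),
    stringsAsFactors = FALSE)

  # round-robin lane assignment within each group, in start order
  for (g in c("rightward", "leftward")) {
    gl <- lanes$lane[lanes$dir == g]
    sel <- which(ped$group == g)
    ped$lane[sel] <- gl[(seq_along(sel) - 1L) %% length(gl) + 1L]
  }
  ped$lane_centre <- lanes$centre[ped$lane]

  lane_speed <- pmax(0.5, stats::rnorm(cfg$n_lanes, cfg$speed_mean, cfg$speed_sd))
  ped$speed <- lane_speed[ped$lane]

  # intended predecessor: the same-lane pedestrian immediately ahead
  ped$pred <- NA_character_
  for (l in unique(ped$lane)) {
    sel <- which(ped$lane == l)
    d <- ped$dir[sel[1]]
    ord <- sel[order(-d * ped$x0[sel])]  # front first
    if (length(ord) > 1)
      ped$pred[ord[-1]] <- ped$ped_id[ord[-length(ord)]]
  }

  # trial length: everyone reaches the far destination area plus margin
  dist <- abs(ifelse(ped$dir > 0, L + geometry$buffer_length + 1 - ped$x0,
                     ped$x0 + geometry$buffer_length + 1))
  t_end_ped <- dist / ped$speed
  rate <- cfg$sample_rate
  nt <- ceiling(max(t_end_ped) * rate) + 1L
  tt <- (seq_len(nt) - 1L) / rate
  dt <- 1 / rate
  np <- nrow(ped)

  x <- outer(tt, ped$dir * ped$speed) + rep(ped$x0, each = nt)

  # transverse dynamics: relaxation to lane centre + OU noise + avoidance
  y <- matrix(NA_real_, nt, np)
  y[1, ] <- ped$y0
  relax <- cfg$lateral_relax_time
  nsd <- cfg$lateral_noise_sd * sqrt(2 * dt / relax)
  ymin <- 0.15; ymax <- W - 0.15
  rot_active <- matrix(FALSE, nt, np)  # close pass: shoulder rotation
  ycur <- ped$y0
  for (m in 2:nt) {
    dy <- (ped$lane_centre - ycur) * dt / relax
    if (nsd > 0) dy <- dy + stats::rnorm(np, 0, nsd)
    # oncoming pedestrian within 2 m ahead and |dy| < 0.5 m -> deflect away
    xm <- x[m - 1L, ]
    ahead <- outer(xm, xm, function(a, b) b - a) * ped$dir  # [i, j]: how far j is ahead of i
    cross <- outer(ped$dir, ped$dir, "!=")
    dyy <- abs(outer(ycur, ycur, "-"))
    near <- cross & ahead > 0 & ahead < 2 & dyy < 0.5
    has <- rowSums(near) > 0
    if (any(has)) {
      for (i in which(has)) {
        j <- which(near[i, ])[which.min(ahead[i, near[i, ]])]
        s <- sign(ycur[i] - ycur[j]); if (s == 0) s <- 1
        dy[i] <- dy[i] + s * cfg$avoidance_gain * dt
      }
    }
    # a pass closer than the combined shoulder clearance (0.8 m) makes the
    # pedestrian rotate its trunk even when no deflection is needed
    rot_active[m, ] <- rowSums(cross & ahead > 0 & ahead < 2 & dyy < 0.8) > 0
    ycur <- ycur + dy
    ycur <- ifelse(ycur < ymin, 2 * ymin - ycur, ycur)
    ycur <- ifelse(ycur > ymax, 2 * ymax - ycur, ycur)
    y[m, ] <- ycur
  }

  # shoulders: trunk faces the travel direction; close passes rotate it
  sh <- shoulder_tracks(tt, x, y, rot_active, dt)

  # gait: heel strikes per foot
  stride_nominal <- cfg$tempo / 60 / 2  # per-foot stride frequency, Hz
  if (cfg$cue_mode == "metronome_locked") {
    period <- 1 / stride_nominal
    parity <- stats::rbinom(np, 1, 0.5)
    ped$stride_freq <- stride_nominal
    ped$phase <- parity * period / 2
  } else {
    draw <- pmax(0.3, stats::rnorm(np, stride_nominal, cfg$freq_sd))
    freq <- draw
    cpl <- cfg$duration_coupling
    for (l in unique(ped$lane)) {          # front to back along each lane
      sel <- which(ped$lane == l)
      d <- ped$dir[sel[1]]
      ord <- sel[order(-d * ped$x0[sel])]
      if (length(ord) > 1)
        for (k in 2:length(ord))
          freq[ord[k]] <- (1 - cpl) * draw[ord[k]] + cpl * freq[ord[k - 1]]
    }
    ped$stride_freq <- freq
    ped$phase <- stats::runif(np, 0, 1 / freq)
  }

  instrumented <- switch(cfg$instrument,
                         rightward = ped$group == "rightward",
                         leftward = ped$group == "leftward",
                         both = rep(TRUE, np))
  steps <- list()
  for (i in seq_len(np)) {
    if (!instrumented[i]) next
    Ti <- t_end_ped[i]
    per <- 1 / ped$stride_freq[i]
    for (foot in c("right", "left")) {
      off <- ped$phase[i] + if (foot == "left") per / 2 else 0
      ticks <- seq(off, Ti, by = per)
      if (cfg$phase_jitter_sd > 0)
        ticks <- ticks + stats::rnorm(length(ticks), 0, cfg$phase_jitter_sd)
      ticks <- sort(ticks)
      ticks <- ticks[c(TRUE, diff(ticks) > 1e-6)]
      steps[[length(steps) + 1L]] <- step_series(ped$ped_id[i], foot, ticks)
    }
  }

  tracks <- lapply(seq_len(np), function(i)
    pedestrian_track(ped$ped_id[i], ped$group[i], tt, x[, i], y[, i],
                     sample_rate = rate, shoulders = sh[[i]]))
  meta <- lapply(seq_len(np), function(i)
    list(start_row = ped$row[i] + 1L, start_col = ped$col[i] + 1L))
  names(meta) <- ped$ped_id

  ds <- trial_dataset(trial_id, condition, geometry, tracks, steps,
                      order_index = order_index, meta = meta)
  truth <- data.frame(ped_id = ped$ped_id, group = ped$group, lane = ped$lane,
                      lane_centre = ped$lane_centre, speed = ped$speed,
                      stride_freq_hz = ped$stride_freq,
                      phase_offset_s = ped$phase,
                      intended_predecessor = ped$pred,
                      start_row = ped$row + 1L, start_col = ped$col + 1L,
                      stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth)
}

# shoulder marker positions: the trunk faces the travel direction (the
# shoulder axis sits on the y-axis), rotates toward a 0.35 rad yaw while an
# oncoming pedestrian passes within shoulder clearance, and carries a small
# postural jitter
shoulder_tracks <- function(tt, x, y, rot_active, dt, halfwidth = 0.2,
                            yaw = 0.35, relax = 0.3, jitter_sd = 0.03) {
  nt <- length(tt); np <- ncol(x)
  out <- vector("list", np)
  for (i in seq_len(np)) {
    rho <- numeric(nt)
    for (m in 2:nt) {
      target <- if (rot_active[m, i]) yaw else 0
      rho[m] <- rho[m - 1] + (target - rho[m - 1]) * dt / relax
    }
    a <- rho + stats::rnorm(nt, 0, jitter_sd)  # angle from the y-axis
    sx <- sin(a); sy <- cos(a)
    out[[i]] <- data.frame(t = tt,
                           lx = x[, i] - halfwidth * sx,
                           ly = y[, i] - halfwidth * sy,
                           rx = x[, i] + halfwidth * sx,
                           ry = y[, i] + halfwidth * sy)
  }
  out
}

#' Simulate a batch of trials for one condition
#'
#' Per-trial seeds are drawn from `seed` so the whole batch is reproducible.
#'
#' @param n_trials Number of trials.
#' @param condition `"NO_CUE"` or `"CUE"`.
#' @param seed Master integer seed.
#' @param geometry A [corridor_geometry()].
#' @param ... Overrides passed to [condition_preset()].
#' @return List of [trial_dataset()]s (ground truths attached as attribute
#'   `"truth"` on each element).
#' @export
simulate_condition <- function(n_trials, condition = c("NO_CUE", "CUE"),
                               seed = 1L, geometry = corridor_geometry(), ...) {
  condition <- match.arg(condition)
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  lapply(seq_len(n_trials), function(i) {
    cfg <- condition_preset(condition, seed = trial_seeds[i], ...)
    sim <- simulate_trial(cfg, geometry,
                          trial_id = sprintf("%s_%02d", condition, i),
                          order_index = i)
    attr(sim$dataset, "truth") <- sim$truth
    sim$dataset
  })
}

#' Synthesize an IMU trace from a heel-strike series
#'
#' Builds a surrogate medio-lateral angular-velocity trace: a unit-height
#' Gaussian bump (60 ms full width at half maximum) at each heel strike, a
#' negative bump at each toe-off (placed 60% of the way through the stride,
#' at the start of the swing phase), plus white sample noise. The returned
#' trace carries `events_hint` intervals (toe-off to next heel strike) usable
#' to gate detection.
#'
#' @param steps A [step_series()] with at least one strike.
#' @param cfg A [sim_config()] (supplies `imu_noise_sd`).
#' @param t_start,t_end Trace span (s); defaults pad the strikes by 0.3 s.
#' @param sample_rate Sampling rate (Hz, default 100).
#' @return An [imu_trace()].
#' @export
synthesize_imu <- function(steps, cfg = sim_config(), t_start = NULL,
                           t_end = NULL, sample_rate = 100) {
  stopifnot(inherits(steps, "step_series"))
  s <- steps$strikes
  if (length(s) == 0) stop("step series is empty")
  if (is.null(t_start)) t_start <- s[1] - 0.3
  if (is.null(t_end)) t_end <- s[length(s)] + 0.3
  nt <- floor((t_end - t_start) * sample_rate) + 1L
  fwhm <- 0.06
  sdb <- fwhm / (2 * sqrt(2 * log(2)))
  if (nt < ceiling(fwhm * sample_rate) + 1L)
    stop("requested trace is shorter than one heel-strike bump")
  tt <- t_start + (seq_len(nt) - 1L) / sample_rate
  omega <- numeric(nt)
  for (tk in s) omega <- omega + exp(-0.5 * ((tt - tk) / sdb)^2)
  toe <- if (length(s) > 1) s[-length(s)] + 0.6 * diff(s) else numeric(0)
  for (tk in toe) omega <- omega - exp(-0.5 * ((tt - tk) / sdb)^2)
  if (cfg$imu_noise_sd > 0)
    omega <- omega + stats::rnorm(nt, 0, cfg$imu_noise_sd)
  # swing intervals bounding each strike; the first strike's toe-off is
  # placed one nominal swing (40% of the median stride) before it
  swing0 <- s[1] - 0.4 * (if (length(s) > 1) stats::median(diff(s)) else 0.6)
  hint <- data.frame(toe_off_t = c(max(swing0, t_start), toe),
                     heel_strike_t = s)
  imu_trace(steps$ped_id, steps$foot, omega, sample_rate = sample_rate,
            t0 = t_start, events_hint = hint)
}
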