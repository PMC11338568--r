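#' Collision-risk parameters
#'
#' @param tau_step Extrapolation grid step (s, default 0.03 - one video
#'   frame).
#' @param tau_max Largest extrapolation time (s, default 9).
#' @param delta_c Collision detection threshold (m, default 0.6).
#' @return Object of class `risk_params` with the extrapolation grid
#'   `tau_grid = {0.03, 0.06, ..., 9.0}`.
#' @export
risk_params <- function(tau_step = 0.03, tau_max = 9, delta_c = 0.6) {
  if (tau_step <= 0 || tau_max <= tau_step) stop("invalid tau grid")
  if (delta_c <= 0) stop("delta_c must be > 0")
  grid <- tau_step * seq_len(floor(tau_max / tau_step + 1e-9))
  structure(list(tau_grid = grid, tau_step = tau_step, tau_max = tau_max,
                 delta_c = delta_c), class = "risk_params")
}

# index into tau_grid of the smallest grid value at which the linearly
# extrapolated pair comes within delta_c; NA when no grid value qualifies.
# Vectorized over pairs.
collision_grid_index <- function(d0x, d0y, dvx, dvy, params) {
  step <- params$tau_step
  ngrid <- length(params$tau_grid)
  a <- dvx^2 + dvy^2
  b <- 2 * (d0x * dvx + d0y * dvy)
  cc <- d0x^2 + d0y^2 - params$delta_c^2
  k <- rep(NA_integer_, length(d0x))
  # already within the threshold: the first grid value qualifies
  k[cc <= 0] <- 1L
  todo <- which(cc > 0 & a > 0)
  if (length(todo)) {
    disc <- b[todo]^2 - 4 * a[todo] * cc[todo]
    ok <- disc >= 0
    todo <- todo[ok]; disc <- disc[ok]
    if (length(todo)) {
      sq <- sqrt(disc)
      r1 <- (-b[todo] - sq) / (2 * a[todo])
      r2 <- (-b[todo] + sq) / (2 * a[todo])
      kk <- pmax(1L, as.integer(ceiling(r1 / step - 1e-9)))
      good <- kk <= ngrid & kk * step <= r2 + 1e-12 & r2 > 0
      k[todo[good]] <- kk[good]
    }
  }
  k
}

#' Time to potential collision for one cross-group pair
#'
#' Both pedestrians are extrapolated linearly at their current velocities
#' (backward difference over `vel_dt`); the time to collision is the smallest
#' value of the extrapolation grid at which they come within `delta_c`.
#'
#' @param ds A [trial_dataset()].
#' @param t Evaluation time (s).
#' @param i,j Pedestrian ids in different groups.
#' @param params A [risk_params()].
#' @param vel_dt Velocity differencing interval (s, default 1).
#' @return A list `(tau, lambda)` - `lambda = tau * (|v_i| + |v_j|) / 2` is
#'   the mean distance travelled in `tau` - or `NULL` when no grid value
#'   qualifies or the velocity is undefined.
#' @export
time_to_collision <- function(ds, t, i, j, params = risk_params(),
                              vel_dt = 1) {
  gr <- ped_groups(ds)
  if (gr[[i]] == gr[[j]])
    stop("time to collision is defined for cross-group pairs only")
  p1 <- track_position_at(ds$tracks[[i]], c(t - vel_dt, t))
  p2 <- track_position_at(ds$tracks[[j]], c(t - vel_dt, t))
  if (any(is.na(p1)) || any(is.na(p2))) return(NULL)
  v1 <- (p1[2, ] - p1[1, ]) / vel_dt
  v2 <- (p2[2, ] - p2[1, ]) / vel_dt
  k <- collision_grid_index(p1[2, "x"] - p2[2, "x"], p1[2, "y"] - p2[2, "y"],
                            v1["x"] - v2["x"], v1["y"] - v2["y"], params)
  if (is.na(k)) return(NULL)
  tau <- params$tau_grid[k]
  list(tau = tau,
       lambda = tau * (sqrt(sum(v1^2)) + sqrt(sum(v2^2))) / 2)
}

#' Trial-level collision-risk records and means
#'
#' Evaluates [time_to_collision()] for every cross-group pair at every sample
#' time at which both pedestrians are inside the measurement area with
#' defined velocity, and averages the finite records. Pairs with no
#' qualifying grid value contribute nothing.
#'
#' @param ds A [trial_dataset()].
#' @param params A [risk_params()].
#' @param vel_dt Velocity differencing interval (s, default 1).
#' @param mean_mode `"records"` (default) averages all finite pair-time
#'   records; `"ped_min"` averages each pedestrian's minimum tau (and the
#'   corresponding lambda) over the trial.
#' @return Object of class `risk_series`: `records` (data frame `t`, `i`,
#'   `j`, `tau`, `lambda`), `mean_tau`, `mean_lambda` (`NA` when no record
#'   qualifies).
#' @export
trial_risk_means <- function(ds, params = risk_params(), vel_dt = 1,
                             mean_mode = c("records", "ped_min")) {
  mean_mode <- match.arg(mean_mode)
  al <- aligned_positions(ds)
  lag <- round(vel_dt * al$rate)
  nt <- length(al$t)
  right <- which(al$groups == "rightward")
  left <- which(al$groups == "leftward")
  if (!length(right) || !length(left)) stop("no cross-group pairs exist")
  if (nt <= lag) stop("trial shorter than the velocity differencing interval")
  recs <- vector("list", nt)
  for (m in seq.int(lag + 1L, nt)) {
    x <- al$x[m, ]; y <- al$y[m, ]
    vx <- (x - al$x[m - lag, ]) / vel_dt
    vy <- (y - al$y[m - lag, ]) / vel_dt
    ok <- !is.na(x) & !is.na(vx) & in_measurement_area(x, y, ds$geometry)
    ri <- right[ok[right]]; li <- left[ok[left]]
    if (!length(ri) || !length(li)) next
    d0x <- outer(x[ri], x[li], "-"); d0y <- outer(y[ri], y[li], "-")
    dvx <- outer(vx[ri], vx[li], "-"); dvy <- outer(vy[ri], vy[li], "-")
    k <- collision_grid_index(as.vector(d0x), as.vector(d0y),
                              as.vector(dvx), as.vector(dvy), params)
    hit <- which(!is.na(k))
    if (!length(hit)) next
    ii <- ri[(hit - 1L) %% length(ri) + 1L]
    jj <- li[(hit - 1L) %/% length(ri) + 1L]
    tau <- params$tau_grid[k[hit]]
    sp <- sqrt(vx^2 + vy^2)
    recs[[m]] <- data.frame(t = al$t[m], i = al$ids[ii], j = al$ids[jj],
                            tau = tau,
                            lambda = tau * (sp[ii] + sp[jj]) / 2,
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(t = numeric(0), i = character(0), j = character(0),
                          tau = numeric(0), lambda = numeric(0))
  if (!nrow(records)) {
    mt <- NA_real_; ml <- NA_real_
  } else if (mean_mode == "records") {
    mt <- mean(records$tau); ml <- mean(records$lambda)
  } else {
    ids <- unique(c(records$i, records$j))
    mins <- vapply(ids, function(id) {
      r <- records[records$i == id | records$j == id, ]
      m <- which.min(r$tau)
      c(r$tau[m], r$lambda[m])
    }, numeric(2))
    mt <- mean(mins[1, ]); ml <- mean(mins[2, ])
  }
  structure(list(trial_id = ds$trial_id, records = records,
                 mean_tau = mt, mean_lambda = ml, mean_mode = mean_mode),
            class = "risk_series")
}

#' @export
print.risk_series <- function(x, ...) {
  cat(sprintf("collision risk [%s]: %d records, mean tau = %.3f s, mean lambda = %.3f m\n",
              x$trial_id, nrow(x$records), x$mean_tau, x$mean_lambda))
  invisible(x)
}

#' Trajectory curvature series
#'
#' `kappa(t) = |e(t + dt) - e(t)| / dt` with `e = v / |v|` and
#' `v(t) = r(t) - r(t - dt)`: the per-second change of the unit velocity
#' vector, a measure of lateral deviation from a straight path. Evaluated on
#' a `dt`-spaced grid; evaluation points where either velocity vanishes are
#' skipped.
#'
#' @param track A [pedestrian_track()].
#' @param dt Differencing interval (s, default 1).
#' @return Data frame `t`, `kappa` (1/s); zero rows when the track spans
#'   less than `2 * dt`.
#' @export
curvature <- function(track, dt = 1) {
  stopifnot(inherits(track, "pedestrian_track"))
  t0 <- track$t[1]; t1 <- track$t[length(track$t)]
  if (t1 - t0 < 2 * dt)
    return(data.frame(t = numeric(0), kappa = numeric(0)))
  te <- seq(t0 + dt, t1 - dt, by = dt)
  p_prev <- track_position_at(track, te - dt)
  p_cur <- track_position_at(track, te)
  p_next <- track_position_at(track, te + dt)
  v1x <- p_cur[, 1] - p_prev[, 1]; v1y <- p_cur[, 2] - p_prev[, 2]
  v2x <- p_next[, 1] - p_cur[, 1]; v2y <- p_next[, 2] - p_cur[, 2]
  n1 <- sqrt(v1x^2 + v1y^2); n2 <- sqrt(v2x^2 + v2y^2)
  ok <- !is.na(n1) & !is.na(n2) & n1 > 0 & n2 > 0
  kappa <- sqrt((v2x[ok] / n2[ok] - v1x[ok] / n1[ok])^2 +
                  (v2y[ok] / n2[ok] - v1y[ok] / n1[ok])^2) / dt
  data.frame(t = te[ok], kappa = kappa)
}

#' Mean curvature per trial stage
#'
#' @param ds A [trial_dataset()].
#' @param stages A [stage_boundaries()]; computed when `NULL`.
#' @param dt Curvature differencing interval (s, default 1).
#' @return Named numeric vector of mean curvature (1/s) over all pedestrians'
#'   samples in each defined stage (`NA` for stages containing no samples);
#'   stage 3 is omitted when undefined.
#' @export
stage_mean_curvature <- function(ds, stages = NULL, dt = 1) {
  if (is.null(stages)) stages <- stage_boundaries(ds)
  samples <- do.call(rbind, lapply(ds$tracks, curvature, dt = dt))
  vapply(stages$intervals, function(iv) {
    sel <- samples$t >= iv[1] & samples$t < iv[2]
    if (!any(sel)) NA_real_ else mean(samples$kappa[sel])
  }, numeric(1))
}

#' Transverse mean squared displacement
#'
#' Each pedestrian's clock is zeroed at its measurement-area entry;
#' `D(t) = <(y(t) - y(0))^2>` averages over all pedestrians of all supplied
#' trials, reported up to the shortest in-area duration so every pedestrian
#' contributes to every reported lag.
#'
#' @param trials A [trial_dataset()] or list of them.
#' @return Data frame `t`, `D` (m^2), `n` (pedestrians averaged).
#' @export
transverse_msd <- function(trials) {
  if (inherits(trials, "trial_dataset")) trials <- list(trials)
  ys <- list()
  for (ds in trials) {
    for (tr in ds$tracks) {
      ee <- entry_exit_times(tr, ds$geometry)
      if (any(is.na(ee))) next
      sel <- tr$t >= ee["t_enter"] & tr$t <= ee["t_exit"]
      ys[[length(ys) + 1L]] <- list(y = tr$y[sel],
                                    t = tr$t[sel] - ee["t_enter"],
                                    rate = tr$sample_rate)
    }
  }
  if (!length(ys)) stop("no pedestrian enters the measurement area")
  rate <- ys[[1]]$rate
  common <- min(vapply(ys, function(z) z$t[length(z$t)], numeric(1)))
  grid <- seq(0, common, by = 1 / rate)
  sq <- vapply(ys, function(z) {
    idx <- pmin(round(grid * z$rate) + 1L, length(z$y))
    (z$y[idx] - z$y[1])^2
  }, numeric(length(grid)))
  sq <- matrix(sq, nrow = length(grid))
  data.frame(t = grid, D = rowMeans(sq), n = length(ys))
}

#' Shoulder rotation from marker positions
#'
#' Per frame, the angle between the left-to-right shoulder segment and the
#' y-axis (perpendicular to the corridor long axis), folded into
#' `[0, pi/2]`; per-pedestrian means are averaged into a trial mean.
#'
#' @param ds A [trial_dataset()] whose tracks carry shoulder markers.
#' @return List with `per_ped` (data frame `ped_id`, `mean_angle` in
#'   radians) and `trial_mean`.
#' @export
shoulder_rotation <- function(ds) {
  missing <- names(ds$tracks)[vapply(ds$tracks, function(tr)
    is.null(tr$shoulders), logical(1))]
  if (length(missing))
    stop(sprintf("shoulder markers missing for: %s",
                 paste(missing, collapse = ", ")))
  per <- do.call(rbind, lapply(ds$tracks, function(tr) {
    sh <- tr$shoulders
    vx <- sh$rx - sh$lx; vy <- sh$ry - sh$ly
    data.frame(ped_id = tr$ped_id,
               mean_angle = mean(atan2(abs(vx), abs(vy))),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_ped = per, trial_mean = mean(per$mean_angle))
}
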