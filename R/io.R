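#' Read a trial from disk
#'
#' Reads the trajectory/step/IMU CSV files and the YAML manifest of one trial
#' and returns a validated [trial_dataset()]. Coordinates are expected in
#' metres with x along the corridor long axis and the origin at the
#' measurement-area entrance used by the rightward group.
#'
#' @param paths Either a directory containing `trajectory.csv`,
#'   `manifest.yaml` and optionally `steps.csv` / `imu.csv`, or a named list
#'   with elements `trajectory`, `manifest`, and optionally `steps`, `imu`.
#' @param geometry Optional [corridor_geometry()] overriding the manifest's.
#' @return A [trial_dataset()].
#' @seealso [write_trial()]
#' @export
read_trial <- function(paths, geometry = NULL) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    d <- paths
    paths <- list(trajectory = file.path(d, "trajectory.csv"),
                  manifest = file.path(d, "manifest.yaml"))
    if (file.exists(file.path(d, "steps.csv")))
      paths$steps <- file.path(d, "steps.csv")
    if (file.exists(file.path(d, "imu.csv")))
      paths$imu <- file.path(d, "imu.csv")
  }
  for (nm in c("trajectory", "manifest"))
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]]))
      stop(sprintf("missing %s file", nm))

  man <- yaml::read_yaml(paths$manifest)
  if (is.null(geometry)) {
    g <- man$geometry
    geometry <- if (is.null(g)) corridor_geometry() else
      corridor_geometry(meas_length = g$meas_length_m,
                        meas_width = g$meas_width_m,
                        central_window = c(g$central_window_x_m,
                                           g$central_window_y_m),
                        buffer_length = g$buffer_length_m,
                        waiting_length = g$waiting_length_m)
  }
  roster <- man$pedestrians
  if (is.null(roster)) stop("manifest lists no pedestrians")
  roster_ids <- vapply(roster, function(p) as.character(p$id), character(1))
  roster_grp <- vapply(roster, function(p) as.character(p$group), character(1))

  traj <- utils::read.csv(paths$trajectory, stringsAsFactors = FALSE)
  need <- c("trial_id", "ped_id", "group", "t_s", "x_m", "y_m")
  if (!all(need %in% names(traj)))
    stop(sprintf("%s: missing columns %s", paths$trajectory,
                 paste(setdiff(need, names(traj)), collapse = ", ")))
  bad <- which(!is.finite(traj$t_s) | !is.finite(traj$x_m) | !is.finite(traj$y_m))
  if (length(bad))
    stop(sprintf("%s: malformed row %d (non-numeric or missing value)",
                 paths$trajectory, bad[1] + 1L))
  traj$ped_id <- as.character(traj$ped_id)
  if (anyDuplicated(traj[c("ped_id", "t_s")]))
    stop(sprintf("%s: duplicate (ped_id, t) sample", paths$trajectory))
  unknown <- setdiff(unique(traj$ped_id), roster_ids)
  if (length(unknown))
    stop(sprintf("%s: pedestrian %s absent from manifest", paths$trajectory,
                 unknown[1]))

  has_sh <- all(c("lshoulder_x_m", "lshoulder_y_m",
                  "rshoulder_x_m", "rshoulder_y_m") %in% names(traj))
  rate <- if (!is.null(man$trial$sample_rate_hz)) man$trial$sample_rate_hz else 30
  tracks <- lapply(unique(traj$ped_id), function(id) {
    rows <- traj[traj$ped_id == id, , drop = FALSE]  # file order: validation
    sh <- NULL                                       # catches non-monotonic t
    if (has_sh && any(is.finite(rows$lshoulder_x_m))) {
      keep <- is.finite(rows$lshoulder_x_m)
      sh <- data.frame(t = rows$t_s[keep],
                       lx = rows$lshoulder_x_m[keep], ly = rows$lshoulder_y_m[keep],
                       rx = rows$rshoulder_x_m[keep], ry = rows$rshoulder_y_m[keep])
    }
    pedestrian_track(id, roster_grp[match(id, roster_ids)],
                     rows$t_s, rows$x_m, rows$y_m, sample_rate = rate,
                     shoulders = sh)
  })

  steps <- list()
  if (!is.null(paths$steps)) {
    st <- utils::read.csv(paths$steps, stringsAsFactors = FALSE)
    need <- c("trial_id", "ped_id", "foot", "strike_t_s")
    if (!all(need %in% names(st)))
      stop(sprintf("%s: missing columns", paths$steps))
    st$ped_id <- as.character(st$ped_id)
    key <- interaction(st$ped_id, st$foot, drop = TRUE)
    steps <- lapply(levels(key), function(k) {
      rows <- st[key == k, , drop = FALSE]
      step_series(rows$ped_id[1], rows$foot[1], sort(rows$strike_t_s))
    })
  }

  imu <- list()
  if (!is.null(paths$imu)) {
    im <- utils::read.csv(paths$imu, stringsAsFactors = FALSE)
    need <- c("trial_id", "ped_id", "foot", "t_s", "omega_ml_dps")
    if (!all(need %in% names(im)))
      stop(sprintf("%s: missing columns", paths$imu))
    im$ped_id <- as.character(im$ped_id)
    key <- interaction(im$ped_id, im$foot, drop = TRUE)
    imu <- lapply(levels(key), function(k) {
      rows <- im[key == k, , drop = FALSE]
      rows <- rows[order(rows$t_s), , drop = FALSE]
      sr <- 1 / stats::median(diff(rows$t_s))
      imu_trace(rows$ped_id[1], rows$foot[1], rows$omega_ml_dps,
                sample_rate = round(sr), t0 = rows$t_s[1])
    })
  }

  meta <- lapply(roster, function(p) p[setdiff(names(p), c("id", "group"))])
  names(meta) <- roster_ids
  trial_dataset(trial_id = if (!is.null(man$trial$trial_id)) man$trial$trial_id
                           else as.character(traj$trial_id[1]),
                condition = man$trial$condition,
                geometry = geometry, tracks = tracks, steps = steps, imu = imu,
                order_index = if (!is.null(man$trial$order_index))
                  man$trial$order_index else NA_integer_,
                meta = meta)
}

#' Write a trial to disk
#'
#' Writes `trajectory.csv`, `manifest.yaml` and, when present, `steps.csv` and
#' `imu.csv` into `out_dir` so that [read_trial()] reproduces the dataset to
#' numeric tolerance 1e-9.
#'
#' @param ds A [trial_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named character vector of files written.
#' @export
write_trial <- function(ds, out_dir) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (length(ds$tracks) == 0) stop("refusing to write a trial with no tracks")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(v) formatC(v, format = "g", digits = 15)

  has_sh <- any(vapply(ds$tracks, function(tr) !is.null(tr$shoulders), logical(1)))
  rows <- lapply(ds$tracks, function(tr) {
    df <- data.frame(trial_id = ds$trial_id, ped_id = tr$ped_id,
                     group = tr$group, t_s = fmt(tr$t),
                     x_m = fmt(tr$x), y_m = fmt(tr$y),
                     stringsAsFactors = FALSE)
    if (has_sh) {
      sh <- tr$shoulders
      blank <- rep(NA_character_, nrow(df))
      df$lshoulder_x_m <- blank; df$lshoulder_y_m <- blank
      df$rshoulder_x_m <- blank; df$rshoulder_y_m <- blank
      if (!is.null(sh)) {
        i <- match(round(sh$t * 1e9), round(tr$t * 1e9))
        df$lshoulder_x_m[i] <- fmt(sh$lx); df$lshoulder_y_m[i] <- fmt(sh$ly)
        df$rshoulder_x_m[i] <- fmt(sh$rx); df$rshoulder_y_m[i] <- fmt(sh$ry)
      }
    }
    df
  })
  traj <- do.call(rbind, rows)
  files <- c(trajectory = file.path(out_dir, "trajectory.csv"))
  utils::write.csv(traj, files["trajectory"], row.names = FALSE, quote = FALSE,
                   na = "")

  if (length(ds$steps)) {
    st <- do.call(rbind, lapply(ds$steps, function(ss)
      data.frame(trial_id = ds$trial_id, ped_id = ss$ped_id, foot = ss$foot,
                 strike_t_s = fmt(ss$strikes), stringsAsFactors = FALSE)))
    files["steps"] <- file.path(out_dir, "steps.csv")
    utils::write.csv(st, files["steps"], row.names = FALSE, quote = FALSE)
  }
  if (length(ds$imu)) {
    im <- do.call(rbind, lapply(ds$imu, function(tr)
      data.frame(trial_id = ds$trial_id, ped_id = tr$ped_id, foot = tr$foot,
                 t_s = fmt(imu_times(tr)), omega_ml_dps = fmt(tr$omega),
                 stringsAsFactors = FALSE)))
    files["imu"] <- file.path(out_dir, "imu.csv")
    utils::write.csv(im, files["imu"], row.names = FALSE, quote = FALSE)
  }

  g <- ds$geometry
  instrumented <- unique(vapply(ds$steps, `[[`, character(1), "ped_id"))
  man <- list(
    trial = list(trial_id = ds$trial_id, condition = ds$condition,
                 order_index = if (is.na(ds$order_index)) NULL else ds$order_index,
                 sample_rate_hz = ds$tracks[[1]]$sample_rate),
    geometry = list(meas_length_m = g$meas_length, meas_width_m = g$meas_width,
                    central_window_x_m = g$central_window[1],
                    central_window_y_m = g$central_window[2],
                    buffer_length_m = g$buffer_length,
                    waiting_length_m = g$waiting_length),
    pedestrians = lapply(ds$tracks, function(tr) {
      p <- list(id = tr$ped_id, group = tr$group,
                instrumented = tr$ped_id %in% instrumented)
      extra <- ds$meta[[tr$ped_id]]
      if (!is.null(extra)) p <- c(p, extra)
      p
    })
  )
  names(man$pedestrians) <- NULL
  files["manifest"] <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(man, files["manifest"])
  invisible(files)
}

#' Entry and exit times of the measurement area
#'
#' @param track A [pedestrian_track()].
#' @param geometry A [corridor_geometry()].
#' @return Named numeric `c(t_enter=, t_exit=)`: the first and last sample
#'   times with the position inside the measurement area, or both `NA` when
#'   the track never enters it (no-crossing sentinel).
#' @export
entry_exit_times <- function(track, geometry) {
  inside <- in_measurement_area(track$x, track$y, geometry)
  if (!any(inside)) return(c(t_enter = NA_real_, t_exit = NA_real_))
  c(t_enter = track$t[which(inside)[1]],
    t_exit = track$t[which(inside)[sum(inside)]])
}
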