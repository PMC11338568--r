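#' Following-relation parameters
#'
#' Pedestrian i follows j at time t when i's position at t is within `dr` of
#' j's position at `t - dt`.
#'
#' @param dt Time lag (s, default 1).
#' @param dr Distance threshold (m, default 0.7).
#' @param same_group_only Restrict the relation to pedestrians travelling in
#'   the same direction (default `TRUE`): lanes are unidirectional, and a
#'   head-on "following" at closing speed is physically spurious.
#' @param foot_rule How a predecessor foot is paired with a follower foot for
#'   strike matching: `"same_side"` (default) pairs left with left and right
#'   with right, which preserves anti-phase structure (a follower striding on
#'   the opposite half-cycle); `"nearest_offset"` picks the follower foot
#'   minimizing the mean absolute nearest-strike offset, which biases offsets
#'   into the inner half-cycle and so under-represents anti-phase stepping.
#' @return Object of class `follow_params`.
#' @export
follow_params <- function(dt = 1, dr = 0.7, same_group_only = TRUE,
                          foot_rule = c("same_side", "nearest_offset")) {
  if (dt <= 0 || dr <= 0) stop("dt and dr must be > 0")
  foot_rule <- match.arg(foot_rule)
  structure(list(dt = dt, dr = dr, same_group_only = same_group_only,
                 foot_rule = foot_rule),
            class = "follow_params")
}

# squared distances between current positions (rows) and lagged positions
# (cols); NA where either is missing
follow_edge_matrix <- function(xc, yc, xl, yl, groups, params) {
  d2 <- outer(xc, xl, "-")^2 + outer(yc, yl, "-")^2
  e <- d2 < params$dr^2
  e[is.na(e)] <- FALSE
  diag(e) <- FALSE
  if (params$same_group_only) e <- e & outer(groups, groups, "==")
  e
}

#' Following relation at one time
#'
#' @param ds A [trial_dataset()].
#' @param t Evaluation time (s).
#' @param params A [follow_params()].
#' @return A data frame with columns `follower`, `predecessor` (one row per
#'   directed edge) and attribute `time`. Positions are taken at the nearest
#'   sample times; a `t - dt` before the trial start yields an empty graph
#'   with a warning.
#' @export
following <- function(ds, t, params = follow_params()) {
  stopifnot(inherits(ds, "trial_dataset"))
  t0 <- min(vapply(ds$tracks, function(tr) tr$t[1], numeric(1)))
  empty <- data.frame(follower = character(0), predecessor = character(0),
                      stringsAsFactors = FALSE)
  if (t - params$dt < t0 - 1e-9) {
    warning("t - dt precedes the trial start; empty follow graph")
    attr(empty, "time") <- t
    return(empty)
  }
  ids <- names(ds$tracks)
  cur <- t(vapply(ds$tracks, function(tr) track_position_at(tr, t)[1, ],
                  numeric(2)))
  lag <- t(vapply(ds$tracks, function(tr)
    track_position_at(tr, t - params$dt)[1, ], numeric(2)))
  e <- follow_edge_matrix(cur[, 1], cur[, 2], lag[, 1], lag[, 2],
                          unname(ped_groups(ds)), params)
  idx <- which(e, arr.ind = TRUE)
  out <- data.frame(follower = ids[idx[, 1]], predecessor = ids[idx[, 2]],
                    stringsAsFactors = FALSE)
  attr(out, "time") <- t
  out
}

# duration at each strike: backward difference, with the first strike taking
# the duration of its adjacent (first) stride; NULL when < 2 strikes
duration_at_strikes <- function(strikes) {
  if (length(strikes) < 2) return(NULL)
  d <- diff(strikes)
  c(d[1], d)
}

# index of the strike in `pool` nearest to each time in `q` (ties -> earlier)
nearest_strike_index <- function(q, pool) {
  lo <- pmax(findInterval(q, pool), 1L)
  hi <- pmin(lo + 1L, length(pool))
  ifelse(abs(pool[hi] - q) < abs(pool[lo] - q), hi, lo)
}

# per-follower follow time accumulated over the whole trial [seconds]
follow_time_matrix <- function(ds, params, al = aligned_positions(ds)) {
  lag <- round(params$dt * al$rate)
  nt <- length(al$t)
  np <- length(al$ids)
  acc <- matrix(0, np, np, dimnames = list(al$ids, al$ids))
  if (nt <= lag) return(acc)
  for (m in (lag + 1L):nt) {
    e <- follow_edge_matrix(al$x[m, ], al$y[m, ], al$x[m - lag, ],
                            al$y[m - lag, ], al$groups, params)
    acc <- acc + e
  }
  acc / al$rate
}

#' Identify follower-predecessor pairs and match their heel strikes
#'
#' For each instrumented follower, the predecessor is the pedestrian it
#' followed for the longest total time during the trial (ties broken toward
#' the lower pedestrian id). Each predecessor foot is mapped to the follower
#' foot minimizing the mean absolute nearest-strike offset, and every
#' predecessor strike - from the predecessor's first to last strike inside
#' the measurement area - is matched with the nearest strike of the mapped
#' follower foot. Step durations attached to a match are backward
#' differences (the first strike of a series takes its adjacent stride's
#' duration). Followers that never follow anyone, or whose predecessor
#' carries no step data, are excluded.
#'
#' @param ds A [trial_dataset()].
#' @param params A [follow_params()].
#' @return A list of `pair_assignment` objects: `follower`, `predecessor`,
#'   `followed_duration` (s), `foot_map`, and `matches` - a data frame with
#'   one row per matched predecessor strike (`foot_p`, `t_p`, `t_f`, `dt_p`,
#'   `dt_f`).
#' @export
identify_pairs <- function(ds, params = follow_params()) {
  stopifnot(inherits(ds, "trial_dataset"))
  sp <- steps_by_ped(ds)
  followers <- intersect(names(ds$tracks), names(sp))
  if (!length(followers)) return(list())
  acc <- follow_time_matrix(ds, params)
  out <- list()
  for (f in followers) {
    times <- acc[f, ]
    times <- times[order(names(times))]  # lower ped_id wins ties
    best <- names(times)[which.max(times)]
    if (times[best] <= 0) next           # never follows anyone: excluded
    if (is.null(sp[[best]])) next        # predecessor not instrumented
    pr <- match_pair_steps(sp[[best]], sp[[f]],
                           entry_exit_times(ds$tracks[[best]], ds$geometry),
                           params$foot_rule)
    if (is.null(pr)) next
    out[[length(out) + 1L]] <-
      structure(list(follower = f, predecessor = best,
                     followed_duration = unname(times[best]),
                     foot_map = pr$foot_map, matches = pr$matches),
                class = "pair_assignment")
  }
  out
}

# strikes + backward durations of one pedestrian's feet, in the follower
# role (all strikes) or the predecessor role (restricted to `window`)
prep_feet <- function(steps_ped, window = NULL) {
  out <- list()
  for (foot in sort(names(steps_ped))) {
    s <- steps_ped[[foot]]$strikes
    d <- duration_at_strikes(s)
    if (is.null(d)) next
    if (!is.null(window) && !any(is.na(window))) {
      keep <- s >= window["t_enter"] - 1e-9 & s <= window["t_exit"] + 1e-9
      s <- s[keep]; d <- d[keep]
    }
    if (length(s)) out[[foot]] <- list(s = s, d = d)
  }
  if (length(out)) out else NULL
}

# core matcher on prepped feet; returns list(foot_map, feet (per-foot match
# matrices t_p, t_f, dt_p, dt_f)) or NULL
match_core <- function(pred, foll, foot_rule = "same_side") {
  if (is.null(pred) || is.null(foll)) return(NULL)
  foot_map <- character(0)
  feet <- list()
  for (foot in names(pred)) {
    s <- pred[[foot]]$s
    if (foot_rule == "same_side") {
      best <- if (!is.null(foll[[foot]])) foot else names(foll)[1]
      best_idx <- nearest_strike_index(s, foll[[best]]$s)
    } else {
      best <- ""; best_cost <- Inf; best_idx <- NULL
      for (fn in names(foll)) {  # names sorted: left wins cost ties
        ff <- foll[[fn]]
        idx <- nearest_strike_index(s, ff$s)
        cost <- mean(abs(ff$s[idx] - s))
        if (cost < best_cost) { best <- fn; best_cost <- cost; best_idx <- idx }
      }
    }
    foot_map[foot] <- best
    ff <- foll[[best]]
    feet[[foot]] <- cbind(t_p = s, t_f = ff$s[best_idx],
                          dt_p = pred[[foot]]$d, dt_f = ff$d[best_idx])
  }
  if (!length(feet)) return(NULL)
  list(foot_map = foot_map, feet = feet)
}

# match predecessor strikes (inside [window]) to follower strikes; returns
# list(foot_map, matches data frame) or NULL when either side lacks strikes
match_pair_steps <- function(pred_steps, foll_steps, window,
                             foot_rule = "same_side") {
  mc <- match_core(prep_feet(pred_steps, window), prep_feet(foll_steps),
                   foot_rule)
  if (is.null(mc)) return(NULL)
  matches <- do.call(rbind, lapply(names(mc$feet), function(foot) {
    m <- mc$feet[[foot]]
    data.frame(foot_p = foot, t_p = m[, "t_p"], t_f = m[, "t_f"],
               dt_p = m[, "dt_p"], dt_f = m[, "dt_f"],
               stringsAsFactors = FALSE)
  }))
  list(foot_map = mc$foot_map, matches = matches)
}

#' @export
print.pair_assignment <- function(x, ...) {
  cat(sprintf("pair %s -> %s: followed %.2f s, %d matched strikes\n",
              x$follower, x$predecessor, x$followed_duration, nrow(x$matches)))
  invisible(x)
}

# union-find over n nodes given an edge index matrix (two columns)
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (length(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, integer(1))
}

# lane partition at one aligned-grid frame; returns list(clusters, central)
lane_partition_frame <- function(al, m, lag, params, geometry) {
  x <- al$x[m, ]; y <- al$y[m, ]
  present <- which(!is.na(x) & in_measurement_area(x, y, geometry))
  if (!length(present))
    return(list(clusters = list(), lane_count_central = 0L))
  e <- follow_edge_matrix(x[present], y[present],
                          al$x[m - lag, present], al$y[m - lag, present],
                          al$groups[present], params)
  e <- e | t(e)  # undirected closure
  comp <- uf_components(length(present), which(e, arr.ind = TRUE))
  central <- in_central_window(x[present], y[present], geometry)
  clusters <- split(al$ids[present], comp)
  names(clusters) <- NULL
  list(clusters = clusters,
       lane_count_central = length(unique(comp[central])))
}

#' Lane partition at one time
#'
#' Lanes are the connected components of the undirected closure of the
#' following relation over pedestrians currently inside the measurement area.
#'
#' @param ds A [trial_dataset()].
#' @param t Evaluation time (s).
#' @param params A [follow_params()].
#' @return A list with `time`, `clusters` (list of pedestrian-id vectors) and
#'   `lane_count_central` - the number of clusters with at least one member
#'   inside the central counting window.
#' @export
lane_partition <- function(ds, t, params = follow_params()) {
  al <- aligned_positions(ds)
  lag <- round(params$dt * al$rate)
  m <- grid_index(al, t)
  if (is.na(m) || m <= lag) stop("t (minus dt) outside the sampled range")
  out <- lane_partition_frame(al, m, lag, params, ds$geometry)
  c(list(time = al$t[m]), out)
}

#' Trial stage boundaries
#'
#' Computes the six stage instants of a bidirectional-flow trial: `t0` first
#' entry into the measurement area, `t1` first crossing of the two groups'
#' front-most pedestrians, `t2` first exit, `t3` last entry, `t4` last
#' crossing of any cross-group pair, `t5` last exit. Crossings are detected
#' as sign changes of the x-gap on the sampling grid. When `t2 > t3`
#' (first exit after last entry) stage 3 - full bidirectional flow - is
#' undefined and only four stage intervals are returned.
#'
#' @param ds A [trial_dataset()].
#' @return Object of class `stage_boundaries`: numeric `t` (named t0..t5),
#'   flag `stage3_defined`, and `intervals`, a named list of `c(start, end)`
#'   half-open stage intervals.
#' @export
stage_boundaries <- function(ds) {
  al <- aligned_positions(ds)
  geometry <- ds$geometry
  inside <- !is.na(al$x) & in_measurement_area(al$x, al$y, geometry)
  right <- which(al$groups == "rightward")
  left <- which(al$groups == "leftward")
  if (!any(inside[, right]) || !any(inside[, left]))
    stop("both groups must traverse the measurement area")

  enter_i <- apply(inside, 2, function(z) if (any(z)) which(z)[1] else NA)
  exit_i <- apply(inside, 2, function(z) if (any(z)) max(which(z)) else NA)
  t0 <- al$t[min(enter_i, na.rm = TRUE)]
  t2 <- al$t[min(exit_i, na.rm = TRUE)]
  t3 <- al$t[max(enter_i, na.rm = TRUE)]
  t5 <- al$t[max(exit_i, na.rm = TRUE)]

  # front-most gap: rightward lead minus leftward lead
  fr <- apply(al$x[, right, drop = FALSE], 1,
              function(v) if (all(is.na(v))) NA else max(v, na.rm = TRUE))
  fl <- apply(al$x[, left, drop = FALSE], 1,
              function(v) if (all(is.na(v))) NA else min(v, na.rm = TRUE))
  cross1 <- which(!is.na(fr) & !is.na(fl) & fr - fl >= 0)
  if (!length(cross1)) stop("the two groups never cross")
  t1 <- al$t[cross1[1]]

  # last crossing over all cross-group pairs
  t4 <- t1
  for (i in right) {
    gap <- al$x[, i] - al$x[, left, drop = FALSE]
    first_cross <- apply(gap >= 0, 2, function(z) {
      z[is.na(z)] <- FALSE
      if (any(z)) which(z)[1] else NA
    })
    if (any(!is.na(first_cross)))
      t4 <- max(t4, al$t[max(first_cross, na.rm = TRUE)])
  }

  stage3_defined <- t2 <= t3
  intervals <- list(stage1 = c(t0, t1), stage2 = c(t1, t2))
  if (stage3_defined) intervals$stage3 <- c(t2, t3)
  intervals$stage4 <- c(t3, t4)
  intervals$stage5 <- c(t4, t5)
  structure(list(t = c(t0 = t0, t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5),
                 stage3_defined = stage3_defined, intervals = intervals),
            class = "stage_boundaries")
}

#' @export
print.stage_boundaries <- function(x, ...) {
  cat("stage instants (s):\n")
  print(round(x$t, 3))
  if (!x$stage3_defined)
    cat("stage 3 undefined (first exit after last entry)\n")
  invisible(x)
}

#' Mean lane count over stages 2-4
#'
#' Averages the central-window cluster count over all sample times falling in
#' stages 2 to 4 (the lane development, full bidirectional flow, and lane
#' dissolution phases), skipping stage 3 when undefined. Overlapping stage
#' intervals contribute each sample time once.
#'
#' @param ds A [trial_dataset()].
#' @param stages A [stage_boundaries()]; computed when `NULL`.
#' @param params A [follow_params()].
#' @return Mean number of lanes (real), or `NA` when the stage span contains
#'   no sample times.
#' @export
mean_lane_count <- function(ds, stages = NULL, params = follow_params()) {
  if (is.null(stages)) stages <- stage_boundaries(ds)
  al <- aligned_positions(ds)
  lag <- round(params$dt * al$rate)
  keep <- rep(FALSE, length(al$t))
  for (nm in intersect(c("stage2", "stage3", "stage4"),
                       names(stages$intervals))) {
    iv <- stages$intervals[[nm]]
    keep <- keep | (al$t >= iv[1] - 1e-9 & al$t < iv[2] - 1e-9)
  }
  frames <- which(keep)
  frames <- frames[frames > lag]
  if (!length(frames)) return(NA_real_)
  counts <- vapply(frames, function(m)
    lane_partition_frame(al, m, lag, params, ds$geometry)$lane_count_central,
    integer(1))
  mean(counts)
}
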