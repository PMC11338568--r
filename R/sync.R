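#' Synchronization parameters
#'
#' @param K Relaxation time for heel-strike coincidence (s, default 0.1).
#'   The duration-conformity threshold is not free: it is
#'   `(dt_f + dt_p) / 8` by definition.
#' @param n_shuffles Number of virtual trials in the permutation null
#'   (default 1000).
#' @param delta_k_max Largest neighbour order for the strike-discrepancy
#'   series (default 5).
#' @param n_phase_bins Number of equal bins of the phase-shift histogram over
#'   `(-pi, pi]` (default 24).
#' @param seed Integer seed for the shuffling null.
#' @return Object of class `sync_params`.
#' @export
sync_params <- function(K = 0.1, n_shuffles = 1000, delta_k_max = 5,
                        n_phase_bins = 24, seed = 1L) {
  if (K <= 0) stop("K must be > 0")
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  structure(list(K = K, n_shuffles = as.integer(n_shuffles),
                 delta_k_max = as.integer(delta_k_max),
                 n_phase_bins = as.integer(n_phase_bins),
                 seed = as.integer(seed)),
            class = "sync_params")
}

# wrap angles into (-pi, pi]
wrap_pi <- function(x) {
  w <- x - 2 * pi * floor(x / (2 * pi))   # [0, 2*pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Classify one (or many) matched footstep(s)
#'
#' A match is *in-phase* when `|t_f - t_p| <= K`, *anti-phase* when the
#' offset is within `K` of plus or minus a quarter of the summed durations
#' (`|t_f - t_p -/+ (dt_f + dt_p)/4| <= K`), and either label additionally
#' requires duration conformity `|dt_f - dt_p| <= (dt_f + dt_p)/8`;
#' otherwise the match is *unsynchronized*. The phase shift is the offset
#' normalized by the mean single-foot duration,
#' `wrap(2*pi*(t_f - t_p) / ((dt_f + dt_p)/2))`, wrapped into `(-pi, pi]`,
#' so in-phase matches map near 0 and anti-phase matches near plus/minus pi.
#'
#' @param t_f,t_p Heel-strike times of follower and predecessor (s).
#' @param dt_f,dt_p Step durations of follower and predecessor (s), > 0.
#' @param params A [sync_params()].
#' @return Data frame with one row per match: `t_f`, `t_p`, `dt_f`, `dt_p`,
#'   `phase_shift`, `duration_ok`, `label` (one of `"in_phase"`,
#'   `"anti_phase"`, `"unsynchronized"`).
#' @examples
#' classify_step(1.0, 1.0, 1.0, 1.0)$label      # in_phase
#' classify_step(1.5, 1.0, 1.0, 1.0)$label      # anti_phase
#' classify_step(1.25, 1.0, 1.0, 1.0)$label     # unsynchronized
#' @export
classify_step <- function(t_f, t_p, dt_f, dt_p, params = sync_params()) {
  if (any(dt_f <= 0) || any(dt_p <= 0))
    stop("step durations must be > 0")
  off <- t_f - t_p
  quarter <- (dt_f + dt_p) / 4
  duration_ok <- abs(dt_f - dt_p) <= (dt_f + dt_p) / 8
  in_phase <- abs(off) <= params$K
  anti <- abs(off + quarter) <= params$K | abs(off - quarter) <= params$K
  label <- ifelse(duration_ok & in_phase, "in_phase",
                  ifelse(duration_ok & anti, "anti_phase", "unsynchronized"))
  phase <- wrap_pi(2 * pi * off / ((dt_f + dt_p) / 2))
  data.frame(t_f = t_f, t_p = t_p, dt_f = dt_f, dt_p = dt_p,
             phase_shift = phase, duration_ok = duration_ok, label = label,
             stringsAsFactors = FALSE)
}

#' Trial-level synchronization summary
#'
#' @param pairs List of pair assignments from [identify_pairs()] (or
#'   re-matched null pairs).
#' @param params A [sync_params()].
#' @param trial_id Optional label.
#' @param is_null Flag marking permutation-null summaries.
#' @return Object of class `sync_summary`: `prop_sync` (fraction of matches
#'   labelled in- or anti-phase), `mean_duration_diff` (mean `|dt_f - dt_p|`,
#'   s), `phase_hist` (counts in `n_phase_bins` equal bins over `(-pi, pi]`),
#'   `n_matches`, and per-label counts. With zero matches all statistics are
#'   `NA`.
#' @export
trial_sync_summary <- function(pairs, params = sync_params(), trial_id = NULL,
                               is_null = FALSE) {
  col <- function(nm) unlist(lapply(pairs, function(p) p$matches[, nm]),
                             use.names = FALSE)
  summary_from_matches(col("t_f"), col("t_p"), col("dt_f"), col("dt_p"),
                       params, trial_id, is_null)
}

# summary from flat match vectors (shared by trial and null paths)
summary_from_matches <- function(t_f, t_p, dt_f, dt_p, params, trial_id,
                                 is_null) {
  breaks <- seq(-pi, pi, length.out = params$n_phase_bins + 1)
  if (!length(t_f)) {
    return(structure(list(trial_id = trial_id, prop_sync = NA_real_,
                          mean_duration_diff = NA_real_,
                          phase_hist = rep(NA_integer_, params$n_phase_bins),
                          phase_breaks = breaks, n_matches = 0L,
                          n_in_phase = 0L, n_anti_phase = 0L,
                          is_null = is_null),
                     class = "sync_summary"))
  }
  cl <- classify_step(t_f, t_p, dt_f, dt_p, params)
  bin <- pmin(pmax(ceiling((cl$phase_shift + pi) / (2 * pi) *
                             params$n_phase_bins), 1L), params$n_phase_bins)
  structure(list(
    trial_id = trial_id,
    prop_sync = mean(cl$label != "unsynchronized"),
    mean_duration_diff = mean(abs(dt_f - dt_p)),
    phase_hist = tabulate(bin, nbins = params$n_phase_bins),
    phase_breaks = breaks,
    phase_shifts = cl$phase_shift,
    n_matches = length(t_f),
    n_in_phase = sum(cl$label == "in_phase"),
    n_anti_phase = sum(cl$label == "anti_phase"),
    is_null = is_null), class = "sync_summary")
}

#' @export
print.sync_summary <- function(x, ...) {
  cat(sprintf("sync summary%s: prop_sync = %.3f, mean duration diff = %.4f s, %d matches%s\n",
              if (!is.null(x$trial_id)) paste0(" [", x$trial_id, "]") else "",
              x$prop_sync, x$mean_duration_diff, x$n_matches,
              if (x$is_null) " (null)" else ""))
  invisible(x)
}

#' Pair-shuffling permutation null
#'
#' Generates `n_shuffles` virtual datasets for one condition. For every pair
#' in every trial the follower is kept and the predecessor is replaced by:
#' (i) uniformly choosing another trial of the same condition, then (ii)
#' uniformly choosing a pair there whose members do not include either member
#' of the original pair, and taking its predecessor. The replacement
#' predecessor's strikes (restricted to its own measurement-area window, on
#' the shared trial-start clock) are re-matched to the follower's feet
#' exactly as in [identify_pairs()], and each virtual dataset is summarized
#' with [trial_sync_summary()]. One master seed spawns per-shuffle
#' substreams, so results do not depend on evaluation order.
#'
#' @param trials List of at least two [trial_dataset()]s from one condition.
#' @param params A [sync_params()].
#' @param follow A [follow_params()] used to identify the original pairs.
#' @param pairs_list Optional precomputed `identify_pairs()` output per
#'   trial (in the order of `trials`).
#' @return List of `n_shuffles` `sync_summary` objects with `is_null = TRUE`.
#' @export
shuffle_null <- function(trials, params = sync_params(),
                         follow = follow_params(), pairs_list = NULL) {
  if (length(trials) < 2)
    stop("the permutation null needs at least two trials in the condition")
  conds <- vapply(trials, `[[`, character(1), "condition")
  if (length(unique(conds)) > 1)
    stop("all trials must share one condition")
  if (is.null(pairs_list))
    pairs_list <- lapply(trials, identify_pairs, params = follow)
  sp <- lapply(trials, steps_by_ped)
  # prepped feet: follower role (all strikes) and predecessor role (windowed)
  foll_prep <- lapply(seq_along(trials), function(i)
    lapply(sp[[i]], prep_feet))
  pred_prep <- lapply(seq_along(trials), function(i) {
    ds <- trials[[i]]
    out <- lapply(names(sp[[i]]), function(id)
      prep_feet(sp[[i]][[id]], entry_exit_times(ds$tracks[[id]], ds$geometry)))
    names(out) <- names(sp[[i]])
    out
  })
  folv <- lapply(pairs_list, vapply, `[[`, character(1), "follower")
  prev <- lapply(pairs_list, vapply, `[[`, character(1), "predecessor")
  n_trials <- length(trials)

  set.seed(params$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, params$n_shuffles)
  lapply(seq_len(params$n_shuffles), function(s) {
    set.seed(sub_seeds[s])
    acc <- list()
    for (i in seq_len(n_trials)) {
      for (p in seq_along(pairs_list[[i]])) {
        f <- folv[[i]][p]
        members <- c(f, prev[[i]][p])
        j <- if (n_trials == 2) 3L - i else {
          pool <- seq_len(n_trials)[-i]
          pool[sample.int(n_trials - 1L, 1L)]
        }
        cand <- which(!(folv[[j]] %in% members) & !(prev[[j]] %in% members))
        if (!length(cand)) next
        q <- prev[[j]][cand[sample.int(length(cand), 1L)]]
        mc <- match_core(pred_prep[[j]][[q]], foll_prep[[i]][[f]],
                         follow$foot_rule)
        if (is.null(mc)) next
        acc[[length(acc) + 1L]] <- mc$feet
      }
    }
    flat <- unlist(acc, recursive = FALSE, use.names = FALSE)
    col <- function(nm) unlist(lapply(flat, function(m) m[, nm]),
                               use.names = FALSE)
    out <- summary_from_matches(col("t_f"), col("t_p"), col("dt_f"),
                                col("dt_p"), params,
                                trial_id = sprintf("null_%04d", s),
                                is_null = TRUE)
    out$shuffle_seed <- sub_seeds[s]
    out
  })
}

#' Heel-strike discrepancy with the kth same-lane neighbour
#'
#' At each evaluation time (a 1 Hz grid by default), for every instrumented
#' pedestrian with at least `k` same-lane neighbours carrying step data, the
#' kth nearest neighbour by Euclidean distance is found; the contribution is
#' `|t_i - t_jk|` where `t_i` is the focal pedestrian's strike nearest to the
#' evaluation time and `t_jk` the neighbour's strike nearest to `t_i`.
#' Contributions are averaged over pedestrians at each time.
#'
#' @param ds A [trial_dataset()].
#' @param k Neighbour order (>= 1).
#' @param follow A [follow_params()] for the lane clustering.
#' @param times Optional evaluation times (s); default 1 Hz over the span
#'   where the following relation is defined.
#' @return Data frame with columns `t`, `delta` (s) and `n` (number of
#'   contributing pedestrians); zero rows when no pedestrian ever has `k`
#'   same-lane instrumented neighbours.
#' @export
neighbour_discrepancy <- function(ds, k, follow = follow_params(),
                                  times = NULL) {
  stopifnot(k >= 1)
  al <- aligned_positions(ds)
  lag <- round(follow$dt * al$rate)
  if (is.null(times)) {
    lo <- ceiling(al$t[lag + 1])
    hi <- floor(al$t[length(al$t)])
    if (hi < lo) return(data.frame(t = numeric(0), delta = numeric(0),
                                   n = integer(0)))
    times <- seq(lo, hi, by = 1)
  }
  sp <- steps_by_ped(ds)
  instrumented <- names(sp)
  ms <- lapply(instrumented, function(id)
    sort(c(if (!is.null(sp[[id]]$left)) sp[[id]]$left$strikes,
           if (!is.null(sp[[id]]$right)) sp[[id]]$right$strikes)))
  names(ms) <- instrumented
  out <- lapply(times, function(tv) {
    m <- grid_index(al, tv)
    if (is.na(m) || m <= lag) return(NULL)
    part <- lane_partition_frame(al, m, lag, follow, ds$geometry)
    contrib <- numeric(0)
    for (cl in part$clusters) {
      for (i in intersect(cl, instrumented)) {
        nb <- setdiff(intersect(cl, instrumented), i)
        if (length(nb) < k) next
        xi <- al$x[m, i]; yi <- al$y[m, i]
        d <- sqrt((al$x[m, nb] - xi)^2 + (al$y[m, nb] - yi)^2)
        jk <- nb[order(d)][k]
        si <- ms[[i]]
        sj <- ms[[jk]]
        if (!length(si) || !length(sj)) next
        ti <- si[nearest_strike_index(tv, si)]
        tj <- sj[nearest_strike_index(ti, sj)]
        contrib <- c(contrib, abs(ti - tj))
      }
    }
    if (!length(contrib)) return(NULL)
    data.frame(t = tv, delta = mean(contrib), n = length(contrib))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(t = numeric(0), delta = numeric(0),
                               n = integer(0)) else out
}
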