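#' Summarize one trial
#'
#' Runs the full per-trial pipeline: stage segmentation, pair identification,
#' synchronization summary, lane counting, collision risk, per-stage
#' curvature, the kth-neighbour strike discrepancy, shoulder rotation (when
#' markers are present), and per-pedestrian metric means for stratified
#' comparisons.
#'
#' @param ds A [trial_dataset()].
#' @param follow A [follow_params()].
#' @param sync A [sync_params()].
#' @param risk A [risk_params()].
#' @param delta_k Compute the neighbour-discrepancy series for
#'   `k = 1..delta_k_max` (default `TRUE`; the series costs a lane
#'   clustering per second of trial).
#' @return Object of class `trial_summary` with the per-trial scalar metrics
#'   and intermediate objects (`pairs`, `stages`, `sync`, `risk`).
#' @export
trial_summary <- function(ds, follow = follow_params(), sync = sync_params(),
                          risk = risk_params(), delta_k = TRUE) {
  stopifnot(inherits(ds, "trial_dataset"))
  stages <- stage_boundaries(ds)
  pairs <- identify_pairs(ds, follow)
  ssum <- trial_sync_summary(pairs, sync, trial_id = ds$trial_id)
  lanes <- mean_lane_count(ds, stages, follow)
  rser <- trial_risk_means(ds, risk)
  kappa <- stage_mean_curvature(ds, stages)
  dk <- NULL
  if (delta_k) {
    dk <- lapply(seq_len(sync$delta_k_max), function(k)
      neighbour_discrepancy(ds, k, follow))
    names(dk) <- paste0("k", seq_len(sync$delta_k_max))
  }
  sh <- NULL
  if (all(vapply(ds$tracks, function(tr) !is.null(tr$shoulders), logical(1))))
    sh <- shoulder_rotation(ds)

  per_ped <- per_ped_metrics(ds, rser)
  structure(list(
    trial_id = ds$trial_id, condition = ds$condition,
    order_index = ds$order_index,
    stages = stages, pairs = pairs, sync = ssum, risk = rser,
    prop_sync = ssum$prop_sync,
    mean_duration_diff = ssum$mean_duration_diff,
    mean_lane_count = lanes,
    mean_tau = rser$mean_tau, mean_lambda = rser$mean_lambda,
    stage_kappa = kappa,
    delta_k = dk,
    shoulder = sh,
    shoulder_rotation = if (is.null(sh)) NA_real_ else sh$trial_mean,
    per_ped = per_ped), class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("trial %s (%s): prop_sync = %.3f, lanes = %.2f, tau = %.2f s, lambda = %.2f m\n",
              x$trial_id, x$condition, x$prop_sync, x$mean_lane_count,
              x$mean_tau, x$mean_lambda))
  invisible(x)
}

# per-pedestrian means (tau, lambda, kappa) with start-position strata tags
per_ped_metrics <- function(ds, rser) {
  ids <- names(ds$tracks)
  kap <- vapply(ids, function(id) {
    k <- curvature(ds$tracks[[id]])
    if (nrow(k)) mean(k$kappa) else NA_real_
  }, numeric(1))
  tau <- lam <- rep(NA_real_, length(ids))
  if (nrow(rser$records)) {
    for (q in seq_along(ids)) {
      sel <- rser$records$i == ids[q] | rser$records$j == ids[q]
      if (any(sel)) {
        tau[q] <- mean(rser$records$tau[sel])
        lam[q] <- mean(rser$records$lambda[sel])
      }
    }
  }
  row <- vapply(ids, function(id) {
    v <- ds$meta[[id]]$start_row
    if (is.null(v)) NA_integer_ else as.integer(v)
  }, integer(1))
  col <- vapply(ids, function(id) {
    v <- ds$meta[[id]]$start_col
    if (is.null(v)) NA_integer_ else as.integer(v)
  }, integer(1))
  data.frame(ped_id = ids, group = unname(ped_groups(ds)),
             start_row = row, start_col = col,
             mean_tau = tau, mean_lambda = lam, mean_kappa = unname(kap),
             stringsAsFactors = FALSE)
}

#' Welch two-sample comparison with Cohen's d
#'
#' Welch's t-test (unequal variances, Welch-Satterthwaite degrees of
#' freedom) via [stats::t.test()], plus Cohen's d computed with the pooled
#' standard deviation (n-1 weights); `hedges = TRUE` applies the small-sample
#' correction factor `1 - 3 / (4 (n_a + n_b) - 9)`.
#'
#' @param a,b Numeric samples (each >= 2 finite values).
#' @param labels Length-2 character group labels.
#' @param hedges Apply Hedges' correction to d (default `FALSE`).
#' @return Object of class `comparison_result`: `t`, `df`, `p`, `d`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`, `direction`. `d` is `NA` when both
#'   samples have zero variance.
#' @export
welch_compare <- function(a, b, labels = c("a", "b"), hedges = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 finite values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = na + nb - 2),
                 p.value = 1)
      d <- NA_real_
    } else stop("zero variance in both samples with different means")
  } else {
    ht <- stats::t.test(a, b)
    tt <- list(statistic = ht$statistic, parameter = ht$parameter,
               p.value = ht$p.value)
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
    d <- (mean(a) - mean(b)) / sp
    if (hedges) d <- d * (1 - 3 / (4 * (na + nb) - 9))
  }
  structure(list(labels = labels, n_a = na, n_b = nb,
                 mean_a = mean(a), mean_b = mean(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = d,
                 direction = sign(mean(a) - mean(b))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (n=%d, mean %.4g) vs %s (n=%d, mean %.4g): t = %.3f, df = %.1f, p = %.3g, d = %.3f\n",
              x$labels[1], x$n_a, x$mean_a, x$labels[2], x$n_b, x$mean_b,
              x$t, x$df, x$p, x$d))
  invisible(x)
}

#' Pearson trend of a metric against trial order
#'
#' @param metric Per-trial metric values.
#' @param order_index Trial order within the condition.
#' @return List `r`, `p`, `n` (`r = NA` for a constant metric).
#' @export
order_trend <- function(metric, order_index) {
  keep <- is.finite(metric) & is.finite(order_index)
  metric <- metric[keep]; order_index <- order_index[keep]
  if (length(metric) < 3) stop("trend needs at least 3 trials")
  if (stats::var(metric) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(metric)))
  ct <- stats::cor.test(metric, order_index, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(metric))
}

# pull a scalar metric across summaries of one condition
pull_metric <- function(summaries, condition, field, sub = NULL) {
  vals <- vapply(summaries, function(s) {
    if (s$condition != condition) return(NA_real_)
    v <- s[[field]]
    if (!is.null(sub)) v <- v[sub]
    if (is.null(v) || !length(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  vals[!is.na(vals)]
}

comparison_to_list <- function(cmp) {
  cmp <- unclass(cmp)
  cmp[c("labels", "n_a", "n_b", "mean_a", "mean_b", "t", "df", "p", "d")]
}

#' Build a condition-level report
#'
#' Assembles every condition-level comparison into a machine-readable JSON
#' report plus (optionally) a PDF of summary figures: NO_CUE vs CUE Welch
#' comparisons of lane count, time/distance to potential collision, per-stage
#' curvature, shoulder rotation, synchronization proportion and duration
#' difference; actual-vs-null comparisons when shuffle ensembles are
#' supplied; order trends of the lane count; and leader/follower and
#' wall/centre strata comparisons when start positions are tagged. Metrics
#' that cannot be computed are listed under `absent` rather than fabricated.
#'
#' @param summaries List of [trial_summary()] objects (both conditions).
#' @param nulls Optional named list (by condition) of [shuffle_null()]
#'   ensembles.
#' @param out_dir Output directory.
#' @param make_figures Also render `report_figures.pdf` (default `TRUE`).
#' @return Invisibly, the report list (written to `report.json`).
#' @export
build_report <- function(summaries, nulls = NULL, out_dir,
                         make_figures = TRUE) {
  if (!length(summaries)) stop("no trial summaries supplied")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- unique(vapply(summaries, `[[`, character(1), "condition"))
  report <- list(conditions = conds, n_trials = length(summaries),
                 comparisons = list(), trends = list(), absent = character(0))

  add_cmp <- function(name, a, b, labels) {
    if (length(a) >= 2 && length(b) >= 2) {
      report$comparisons[[name]] <<-
        comparison_to_list(welch_compare(a, b, labels))
    } else {
      report$absent <<- c(report$absent,
                          sprintf("%s (insufficient n: %d vs %d)",
                                  name, length(a), length(b)))
    }
  }

  if (all(c("NO_CUE", "CUE") %in% conds)) {
    two <- function(field, sub = NULL)
      list(no_cue = pull_metric(summaries, "NO_CUE", field, sub),
           cue = pull_metric(summaries, "CUE", field, sub))
    lab <- c("NO_CUE", "CUE")
    v <- two("mean_lane_count")
    add_cmp("lane_count_no_cue_vs_cue", v$no_cue, v$cue, lab)
    v <- two("mean_tau")
    add_cmp("tau_no_cue_vs_cue", v$no_cue, v$cue, lab)
    v <- two("mean_lambda")
    add_cmp("lambda_no_cue_vs_cue", v$no_cue, v$cue, lab)
    v <- two("prop_sync")
    add_cmp("prop_sync_no_cue_vs_cue", v$no_cue, v$cue, lab)
    v <- two("mean_duration_diff")
    add_cmp("duration_diff_no_cue_vs_cue", v$no_cue, v$cue, lab)
    v <- two("shoulder_rotation")
    add_cmp("shoulder_rotation_no_cue_vs_cue", v$no_cue, v$cue, lab)
    for (st in paste0("stage", 1:5)) {
      v <- two("stage_kappa", st)
      add_cmp(paste0("kappa_", st, "_no_cue_vs_cue"), v$no_cue, v$cue, lab)
    }
  }

  if (!is.null(nulls)) {
    for (cond in names(nulls)) {
      act_p <- pull_metric(summaries, cond, "prop_sync")
      nul_p <- vapply(nulls[[cond]], `[[`, numeric(1), "prop_sync")
      add_cmp(paste0("prop_sync_actual_vs_null_", cond), act_p,
              nul_p[is.finite(nul_p)], c("actual", "null"))
      act_d <- pull_metric(summaries, cond, "mean_duration_diff")
      nul_d <- vapply(nulls[[cond]], `[[`, numeric(1), "mean_duration_diff")
      add_cmp(paste0("duration_diff_actual_vs_null_", cond), act_d,
              nul_d[is.finite(nul_d)], c("actual", "null"))
    }
  } else {
    report$absent <- c(report$absent,
                       "actual-vs-null comparisons (no shuffle ensemble supplied)")
  }

  for (cond in conds) {
    lanes <- pull_metric(summaries, cond, "mean_lane_count")
    ord <- vapply(summaries, function(s)
      if (s$condition == cond) as.numeric(s$order_index) else NA_real_,
      numeric(1))
    ord <- ord[!is.na(ord)]
    if (length(lanes) >= 3 && length(ord) == length(lanes))
      report$trends[[paste0("lane_count_vs_order_", cond)]] <-
        order_trend(lanes, ord)
  }

  report$strata <- strata_comparisons(summaries)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (make_figures) report_figures(summaries, nulls,
                                   file.path(out_dir, "report_figures.pdf"))
  invisible(report)
}

# leader/follower (front vs back start rows) and wall/centre (outer vs middle
# start column) Welch comparisons of per-pedestrian tau, lambda, kappa
strata_comparisons <- function(summaries) {
  out <- list()
  per <- do.call(rbind, lapply(summaries, function(s) {
    df <- s$per_ped
    df$condition <- s$condition
    df$trial_id <- s$trial_id
    df
  }))
  if (is.null(per) || all(is.na(per$start_row))) return(out)
  half <- stats::median(per$start_row, na.rm = TRUE)
  per$role <- ifelse(per$start_row <= half, "leader", "follower")
  cols <- range(per$start_col, na.rm = TRUE)
  per$wall <- ifelse(per$start_col %in% cols, "wall", "centre")
  for (cond in unique(per$condition)) {
    sub <- per[per$condition == cond, ]
    trial_mean <- function(flag_col, flag, metric) {
      v <- tapply(sub[[metric]][sub[[flag_col]] == flag],
                  sub$trial_id[sub[[flag_col]] == flag],
                  mean, na.rm = TRUE)
      v[is.finite(v)]
    }
    for (metric in c("mean_tau", "mean_lambda", "mean_kappa")) {
      a <- trial_mean("role", "leader", metric)
      b <- trial_mean("role", "follower", metric)
      if (length(a) >= 2 && length(b) >= 2)
        out[[paste(metric, "leader_vs_follower", cond, sep = "_")]] <-
          comparison_to_list(welch_compare(a, b, c("leader", "follower")))
      a <- trial_mean("wall", "wall", metric)
      b <- trial_mean("wall", "centre", metric)
      if (length(a) >= 2 && length(b) >= 2)
        out[[paste(metric, "wall_vs_centre", cond, sep = "_")]] <-
          comparison_to_list(welch_compare(a, b, c("wall", "centre")))
    }
  }
  out
}

# summary figures: phase histograms, lane/tau/lambda boxplots, delta_k series
report_figures <- function(summaries, nulls, path) {
  grDevices::pdf(path, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  conds <- unique(vapply(summaries, `[[`, character(1), "condition"))
  graphics::par(mfrow = c(1, length(conds)))
  for (cond in conds) {
    hsum <- Reduce(`+`, lapply(Filter(function(s) s$condition == cond,
                                      summaries),
                               function(s) s$sync$phase_hist))
    breaks <- summaries[[1]]$sync$phase_breaks
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    graphics::barplot(hsum / sum(hsum), names.arg = round(mids, 2),
                      las = 2, main = sprintf("phase shift (%s)", cond),
                      ylab = "proportion of matched steps")
  }
  graphics::par(mfrow = c(1, 3))
  for (field in c("mean_lane_count", "mean_tau", "mean_lambda")) {
    vals <- lapply(conds, function(cond) pull_metric(summaries, cond, field))
    names(vals) <- conds
    graphics::boxplot(vals, main = field,
                      ylab = switch(field, mean_lane_count = "lanes",
                                    mean_tau = "tau (s)",
                                    mean_lambda = "lambda (m)"))
  }
  has_dk <- Filter(function(s) !is.null(s$delta_k), summaries)
  if (length(has_dk)) {
    graphics::par(mfrow = c(1, length(conds)))
    for (cond in conds) {
      sel <- Filter(function(s) s$condition == cond, has_dk)
      if (!length(sel)) next
      graphics::plot(NULL, xlim = c(0, max(vapply(sel, function(s)
        max(c(0, s$delta_k$k1$t)), numeric(1)))),
        ylim = c(0, 0.6), xlab = "time (s)", ylab = "delta_k (s)",
        main = sprintf("strike discrepancy (%s)", cond))
      for (k in seq_along(sel[[1]]$delta_k)) {
        dk <- do.call(rbind, lapply(sel, function(s) s$delta_k[[k]]))
        if (is.null(dk) || !nrow(dk)) next
        agg <- stats::aggregate(delta ~ t, dk, mean)
        graphics::lines(agg$t, agg$delta, col = k)
        graphics::points(agg$t, agg$delta, col = k, pch = 16, cex = 0.5)
      }
      graphics::legend("topright", legend = paste0("k=", seq_along(sel[[1]]$delta_k)),
                       col = seq_along(sel[[1]]$delta_k), lty = 1, cex = 0.7)
    }
  }
  invisible(path)
}
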