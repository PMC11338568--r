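# Internal helpers to evaluate all tracks on a common regular time grid.
# Tracks keep their own clocks; lookups use the nearest sample, with NA when
# the requested time falls outside a track's span by more than half a sample
# interval. No interpolation is performed anywhere in the pipeline.

# nearest-sample position of a single track at times tt (vectorised)
track_position_at <- function(track, tt) {
  n <- length(track$t)
  idx <- findInterval(tt, track$t, all.inside = FALSE)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, n)
  use_hi <- abs(track$t[hi] - tt) < abs(track$t[lo] - tt)
  pick <- ifelse(use_hi, hi, lo)
  tol <- 0.5 / track$sample_rate + 1e-9
  bad <- abs(track$t[pick] - tt) > tol
  x <- track$x[pick]; y <- track$y[pick]
  x[bad] <- NA_real_; y[bad] <- NA_real_
  cbind(x = x, y = y)
}

# aligned position arrays for a trial:
# list(t = grid, x = matrix [time x ped], y = matrix, ids, groups, rate)
aligned_positions <- function(ds) {
  rates <- vapply(ds$tracks, `[[`, numeric(1), "sample_rate")
  rate <- max(rates)
  t0 <- min(vapply(ds$tracks, function(tr) tr$t[1], numeric(1)))
  t1 <- max(vapply(ds$tracks, function(tr) tr$t[length(tr$t)], numeric(1)))
  grid <- seq(0, round((t1 - t0) * rate)) / rate + t0
  ids <- names(ds$tracks)
  x <- matrix(NA_real_, length(grid), length(ids), dimnames = list(NULL, ids))
  y <- x
  for (j in seq_along(ids)) {
    p <- track_position_at(ds$tracks[[j]], grid)
    x[, j] <- p[, "x"]; y[, j] <- p[, "y"]
  }
  list(t = grid, x = x, y = y, ids = ids,
       groups = unname(ped_groups(ds)), rate = rate)
}

# index of the grid time nearest to t (NA if outside grid span)
grid_index <- function(al, t) {
  if (t < al$t[1] - 0.5 / al$rate || t > al$t[length(al$t)] + 0.5 / al$rate)
    return(NA_integer_)
  i <- round((t - al$t[1]) * al$rate) + 1L
  min(max(i, 1L), length(al$t))
}
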