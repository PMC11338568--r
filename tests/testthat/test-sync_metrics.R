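test_that("step classification follows the coincidence windows", {
  # identical strikes: in-phase at zero phase
  r <- classify_step(1.0, 1.0, 1.0, 1.0)
  expect_equal(r$label, "in_phase")
  expect_equal(r$phase_shift, 0)

  # half-period offset: anti-phase at pi
  r <- classify_step(1.5, 1.0, 1.0, 1.0)
  expect_equal(r$label, "anti_phase")
  expect_equal(r$phase_shift, pi)

  # quarter-period offset misses both windows
  expect_equal(classify_step(1.25, 1.0, 1.0, 1.0)$label, "unsynchronized")

  # coincident strikes but non-conforming durations: |0.3| > 1.7/8
  r <- classify_step(1.0, 1.0, 1.0, 0.7)
  expect_false(r$duration_ok)
  expect_equal(r$label, "unsynchronized")

  expect_error(classify_step(1, 1, 0, 1), "> 0")
})

test_that("classification agrees with a brute-force inequality oracle", {
  set.seed(7)
  n <- 2000
  off <- stats::runif(n, -1.2, 1.2)
  dtf <- stats::runif(n, 0.6, 1.4)
  dtp <- stats::runif(n, 0.6, 1.4)
  got <- classify_step(off, rep(0, n), dtf, dtp)$label
  K <- 0.1
  want <- mapply(function(o, df_, dp) {
    dur <- abs(df_ - dp) <= (df_ + dp) / 8
    if (dur && abs(o) <= K) "in_phase"
    else if (dur && (abs(o + (df_ + dp) / 4) <= K ||
                     abs(o - (df_ + dp) / 4) <= K)) "anti_phase"
    else "unsynchronized"
  }, off, dtf, dtp)
  expect_identical(got, unname(want))
})

test_that("in- and anti-phase windows are disjoint when K is below the conformity bound", {
  set.seed(8)
  off <- stats::runif(5000, -1, 1)
  dtf <- stats::runif(5000, 0.8, 1.2)
  dtp <- stats::runif(5000, 0.8, 1.2)
  keep <- 0.1 < (dtf + dtp) / 8
  inw <- abs(off) <= 0.1
  anti <- abs(off + (dtf + dtp) / 4) <= 0.1 | abs(off - (dtf + dtp) / 4) <= 0.1
  expect_false(any(inw[keep] & anti[keep]))
})

test_that("summaries degrade gracefully and detect perfect coincidence", {
  empty <- trial_sync_summary(list())
  expect_true(is.na(empty$prop_sync))
  expect_equal(empty$n_matches, 0L)

  pair <- structure(list(
    follower = "F", predecessor = "P", followed_duration = 5,
    foot_map = c(right = "right"),
    matches = data.frame(foot_p = "right", t_p = 1:5, t_f = 1:5,
                         dt_p = 1, dt_f = 1)), class = "pair_assignment")
  s <- trial_sync_summary(list(pair))
  expect_equal(s$prop_sync, 1)
  expect_equal(s$mean_duration_diff, 0)
  expect_equal(sum(s$phase_hist), 5)
})

test_that("prop_sync is invariant under a global time shift", {
  sim <- small_sim(seed = 13)
  ds <- sim$dataset
  s0 <- trial_sync_summary(identify_pairs(ds))
  shift <- 7.5
  ds2 <- ds
  ds2$tracks <- lapply(ds$tracks, function(tr) {
    tr$t <- tr$t + shift
    if (!is.null(tr$shoulders)) tr$shoulders$t <- tr$shoulders$t + shift
    tr
  })
  ds2$steps <- lapply(ds$steps, function(ss) {
    ss$strikes <- ss$strikes + shift
    ss
  })
  s1 <- trial_sync_summary(identify_pairs(ds2))
  expect_equal(s1$prop_sync, s0$prop_sync)
  expect_equal(s1$mean_duration_diff, s0$mean_duration_diff)
})

test_that("the shuffling null is seeded, reproducible and needs two trials", {
  trials <- lapply(1:3, function(s) small_sim(seed = 50 + s)$dataset)
  expect_error(shuffle_null(trials[1]), "at least two")
  pl <- lapply(trials, identify_pairs)
  n1 <- shuffle_null(trials, sync_params(n_shuffles = 8, seed = 5),
                     pairs_list = pl)
  n2 <- shuffle_null(trials, sync_params(n_shuffles = 8, seed = 5),
                     pairs_list = pl)
  expect_identical(vapply(n1, `[[`, numeric(1), "prop_sync"),
                   vapply(n2, `[[`, numeric(1), "prop_sync"))
  n3 <- shuffle_null(trials, sync_params(n_shuffles = 8, seed = 6),
                     pairs_list = pl)
  expect_false(identical(vapply(n1, `[[`, numeric(1), "prop_sync"),
                         vapply(n3, `[[`, numeric(1), "prop_sync")))
})

test_that("shuffling a metronome-locked condition preserves synchrony", {
  # a shared external clock makes the null phase-preserving
  trials <- lapply(1:3, function(s)
    small_sim(seed = 70 + s, condition = "CUE", phase_jitter_sd = 0.01)$dataset)
  pl <- lapply(trials, identify_pairs)
  actual <- mean(vapply(seq_along(trials), function(i)
    trial_sync_summary(pl[[i]])$prop_sync, numeric(1)))
  nulls <- shuffle_null(trials, sync_params(n_shuffles = 40, seed = 2),
                        pairs_list = pl)
  null_mean <- mean(vapply(nulls, `[[`, numeric(1), "prop_sync"))
  expect_gt(actual, 0.9)
  expect_lt(abs(null_mean - actual), 0.1)
})

test_that("neighbour discrepancy follows nearest-strike arithmetic", {
  g <- corridor_geometry()
  base <- list(
    straight_track("A", "rightward", 2, 1.3, 1.5, t_end = 6),
    straight_track("B", "rightward", 3.2, 1.3, 1.5, t_end = 6),
    straight_track("Z", "leftward", 40, -1.3, 2.9, t_end = 6))

  # identical strike trains: zero discrepancy at k = 1
  ds <- trial_dataset("T", "NO_CUE", g, base,
                      steps = c(regular_steps("A", t_end = 6),
                                regular_steps("B", t_end = 6)))
  dk <- neighbour_discrepancy(ds, 1)
  expect_gt(nrow(dk), 0)
  expect_equal(max(dk$delta), 0)

  # trains offset by 0.2 s with period 1 s per foot: delta = 0.2 everywhere
  ds2 <- trial_dataset("T", "NO_CUE", g, base,
                       steps = c(regular_steps("A", t_end = 6),
                                 regular_steps("B", phase = 0.2, t_end = 6)))
  dk2 <- neighbour_discrepancy(ds2, 1)
  expect_equal(unique(round(dk2$delta, 9)), 0.2)

  # k exceeding the lane size: empty series
  dk3 <- neighbour_discrepancy(ds, 3)
  expect_equal(nrow(dk3), 0)
})
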