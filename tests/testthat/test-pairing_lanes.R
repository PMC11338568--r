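test_that("the following relation applies the dt/dr definition", {
  g <- corridor_geometry()
  # j's position 1 s ago is 0.3 m from i now: edge
  tr_i <- straight_track("I", "rightward", 5.0 - 1.3 * 3, 1.3, 1.5, t_end = 6)
  tr_j <- straight_track("J", "rightward", 5.3 + 1.3 - 1.3 * 3, 1.3, 1.5,
                         t_end = 6)
  tr_far <- straight_track("K", "rightward", 5.0 - 1.3 * 3, 1.3, 2.3,
                           t_end = 6)
  dummy <- straight_track("Z", "leftward", 30, -1.3, 2.9, t_end = 6)
  ds <- trial_dataset("T", "NO_CUE", g, list(tr_i, tr_j, tr_far, dummy))
  fg <- following(ds, 3)
  expect_true(any(fg$follower == "I" & fg$predecessor == "J"))
  # 0.8 m transverse offset: no edge; and never a self-edge
  expect_false(any(fg$follower == "I" & fg$predecessor == "K"))
  expect_false(any(fg$follower == fg$predecessor))
  # t - dt before the trial start: empty graph with warning
  expect_warning(fg0 <- following(ds, 0.5), "precedes")
  expect_equal(nrow(fg0), 0)
})

test_that("following is invariant under translation and relabelling", {
  g <- corridor_geometry()
  mk <- function(shift, ids) {
    trial_dataset("T", "NO_CUE", g, list(
      straight_track(ids[1], "rightward", 2 + shift, 1.3, 1.2, t_end = 5),
      straight_track(ids[2], "rightward", 3.2 + shift, 1.3, 1.2, t_end = 5),
      straight_track(ids[3], "leftward", 9 + shift, -1.3, 2.4, t_end = 5)))
  }
  a <- following(mk(0, c("A", "B", "C")), 3)
  b <- following(mk(1.7, c("A", "B", "C")), 3)
  expect_equal(a[order(a$follower), ], b[order(b$follower), ],
               ignore_attr = TRUE)
  relab <- following(mk(0, c("X", "Y", "Z")), 3)
  map <- c(A = "X", B = "Y", C = "Z")
  expect_setequal(paste(map[a$follower], map[a$predecessor]),
                  paste(relab$follower, relab$predecessor))
})

test_that("the longest-followed pedestrian becomes the predecessor", {
  g <- corridor_geometry()
  tt <- seq(0, 12, by = 1 / 30)
  xi <- 1.3 * tt; xj <- 1.3 * tt + 1.3
  # J shares I's lane until t = 9, K only from t = 9
  yj <- ifelse(tt < 9, 1.5, 2.9)
  yk <- ifelse(tt < 9, 2.9, 1.5)
  ds <- trial_dataset("T", "NO_CUE", g, list(
    pedestrian_track("I", "rightward", tt, xi, rep(1.5, length(tt))),
    pedestrian_track("J", "rightward", tt, xj, yj),
    pedestrian_track("K", "rightward", tt, xj, yk),
    straight_track("Z", "leftward", 40, -1.3, 2.9, t_end = 12)),
    steps = c(regular_steps("I"), regular_steps("J"), regular_steps("K")))
  pairs <- identify_pairs(ds)
  pi_ <- Filter(function(p) p$follower == "I", pairs)
  expect_length(pi_, 1)
  expect_equal(pi_[[1]]$predecessor, "J")
  expect_gt(pi_[[1]]$followed_duration, 6)
})

test_that("follow-duration ties break toward the lower pedestrian id", {
  g <- corridor_geometry()
  co <- function(id) straight_track(id, "rightward", 4.3, 1.3, 1.5, t_end = 6)
  ds <- trial_dataset("T", "NO_CUE", g, list(
    straight_track("C", "rightward", 3, 1.3, 1.5, t_end = 6),
    co("A"), co("B"),
    straight_track("Z", "leftward", 40, -1.3, 2.9, t_end = 6)),
    steps = c(regular_steps("C"), regular_steps("A"), regular_steps("B")))
  pairs <- identify_pairs(ds)
  pc <- Filter(function(p) p$follower == "C", pairs)
  expect_equal(pc[[1]]$predecessor, "A")
})

test_that("foot mapping follows the configured rule", {
  g <- corridor_geometry()
  ds <- trial_dataset("T", "NO_CUE", g, list(
    straight_track("F", "rightward", 0, 1.3, 1.5, t_end = 6),
    straight_track("P", "rightward", 1.3, 1.3, 1.5, t_end = 6),
    straight_track("Z", "leftward", 40, -1.3, 2.9, t_end = 6)),
    steps = list(step_series("P", "right", c(1.0, 2.0)),
                 step_series("F", "left", c(1.05, 2.05)),
                 step_series("F", "right", c(1.5, 2.5))))
  # offset-minimizing rule: predecessor right foot maps to follower left
  pr <- identify_pairs(ds, follow_params(foot_rule = "nearest_offset"))
  pf <- Filter(function(p) p$follower == "F", pr)[[1]]
  expect_equal(unname(pf$foot_map["right"]), "left")
  expect_equal(pf$matches$t_f - pf$matches$t_p, c(0.05, 0.05))
  # same-side rule: right maps to right (half-cycle offset retained)
  pr2 <- identify_pairs(ds, follow_params(foot_rule = "same_side"))
  pf2 <- Filter(function(p) p$follower == "F", pr2)[[1]]
  expect_equal(unname(pf2$foot_map["right"]), "right")
  # half-cycle offsets retained (equidistant neighbours resolve earlier)
  expect_equal(abs(pf2$matches$t_f - pf2$matches$t_p), c(0.5, 0.5))
})

test_that("lane clustering finds the scripted files", {
  g <- corridor_geometry()
  file_of_three <- function(ids, y) lapply(seq_along(ids), function(k)
    straight_track(ids[k], "rightward", 3 - 1.2 * (k - 1), 1.3, y, t_end = 6))
  ds <- trial_dataset("T", "NO_CUE", g, c(
    file_of_three(c("A1", "A2", "A3"), 1.0),
    file_of_three(c("B1", "B2", "B3"), 2.0),
    list(straight_track("Z", "leftward", 40, -1.3, 2.9, t_end = 6))))
  lp <- lane_partition(ds, 2.5)
  sizes <- sort(vapply(lp$clusters, length, integer(1)))
  expect_equal(sizes, c(3L, 3L))
  expect_equal(lp$lane_count_central, 2L)

  # no edges: every pedestrian its own cluster
  spread <- trial_dataset("T", "NO_CUE", g, c(
    list(straight_track("A", "rightward", 3, 1.3, 0.5, t_end = 6),
         straight_track("B", "rightward", 3, 1.3, 1.5, t_end = 6),
         straight_track("C", "rightward", 3, 1.3, 2.5, t_end = 6),
         straight_track("Z", "leftward", 40, -1.3, 2.9, t_end = 6))))
  lp2 <- lane_partition(spread, 2.5)
  expect_length(lp2$clusters, 3)

  # one long chain: a single cluster among pedestrians in the area
  chain <- trial_dataset("T", "NO_CUE", g, c(
    lapply(1:10, function(k)
      straight_track(sprintf("C%02d", k), "rightward", 9 - 1.2 * (k - 1),
                     1.3, 1.5, t_end = 6)),
    list(straight_track("Z", "leftward", 40, -1.3, 2.9, t_end = 6))))
  lp3 <- lane_partition(chain, 2)
  expect_length(lp3$clusters, 1)
})

test_that("clustering matches a brute-force oracle on small instances", {
  # exhaustive over all graphs on 4 nodes
  pairs4 <- t(utils::combn(4, 2))
  for (mask in 0:(2^nrow(pairs4) - 1)) {
    edges <- pairs4[bitwAnd(mask, 2^(seq_len(nrow(pairs4)) - 1)) > 0, ,
                    drop = FALSE]
    got <- crowdstep:::uf_components(4, edges)
    want <- oracle_components(4, edges)
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
  # random graphs on 5..10 nodes
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(5:10, 1)
    all_pairs <- t(utils::combn(n, 2))
    m <- sample(0:nrow(all_pairs), 1)
    edges <- all_pairs[sample(nrow(all_pairs), m), , drop = FALSE]
    got <- crowdstep:::uf_components(n, edges)
    want <- oracle_components(n, edges)
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("stage boundaries follow their definitions on scripted trials", {
  # heads meet after closing 10 m at 2.5 m/s: t1 = 4.0 on the grid
  ds <- head_on_trial(speed = 1.25, gap = 10)
  st <- stage_boundaries(ds)
  expect_equal(unname(st$t["t1"]), 4.0)
  expect_equal(unname(st$t["t4"]), 4.0)
  # both start inside: last entry (t3 = 0) precedes first exit -> no stage 3
  expect_false(st$stage3_defined)
  expect_length(st$intervals, 4)
  expect_named(st$intervals, c("stage1", "stage2", "stage4", "stage5"))

  # single-group trial: error
  g <- corridor_geometry()
  suppressWarnings(solo <- trial_dataset("T", "NO_CUE", g, list(
    straight_track("A", "rightward", -1, 1.3, 1.5, t_end = 10))))
  expect_error(stage_boundaries(solo), "both groups")
})

test_that("a single unidirectional file counts as one lane", {
  g <- corridor_geometry()
  ds <- trial_dataset("T", "NO_CUE", g, c(
    lapply(1:3, function(k)
      straight_track(sprintf("A%d", k), "rightward", 3 - 1.2 * (k - 1), 1.3,
                     1.5, t_end = 6)),
    list(straight_track("Z", "leftward", 40, -1.3, 2.9, t_end = 6))))
  stages <- structure(list(
    t = c(t0 = 0, t1 = 1.5, t2 = 3, t3 = 3, t4 = 4.5, t5 = 6),
    stage3_defined = FALSE,
    intervals = list(stage1 = c(0, 1.5), stage2 = c(1.5, 3),
                     stage4 = c(3, 4.5), stage5 = c(4.5, 6))),
    class = "stage_boundaries")
  expect_equal(mean_lane_count(ds, stages), 1.0)
})

test_that("mean lane count recovers the configured lanes and their ordering", {
  m2 <- mean_lane_count(simulate_trial(
    condition_preset("NO_CUE", seed = 31, n_lanes = 2,
                     lateral_noise_sd = 0))$dataset)
  m4 <- mean_lane_count(simulate_trial(
    condition_preset("NO_CUE", seed = 31, n_lanes = 4,
                     lateral_noise_sd = 0))$dataset)
  expect_lt(abs(m2 - 2), 0.3)
  expect_lt(abs(m4 - 4), 0.3)
  expect_lt(m2, m4)
})
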