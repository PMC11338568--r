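# scripted fixtures used across test files; everything is built in code

# straight constant-velocity track sampled at `rate`
straight_track <- function(ped_id, group, x0, vx, y0, vy = 0,
                           t_end = 10, rate = 30) {
  tt <- seq(0, t_end, by = 1 / rate)
  pedestrian_track(ped_id, group, tt, x0 + vx * tt, y0 + vy * tt,
                   sample_rate = rate)
}

# minimal two-pedestrian head-on trial
head_on_trial <- function(speed = 1.25, gap = 10, y = 1.5, t_end = 12,
                          trial_id = "HEADON") {
  g <- corridor_geometry()
  x_mid <- g$meas_length / 2
  trial_dataset(trial_id, "NO_CUE", g,
                list(straight_track("R01", "rightward",
                                    x_mid - gap / 2, speed, y, t_end = t_end),
                     straight_track("L01", "leftward",
                                    x_mid + gap / 2, -speed, y, t_end = t_end)))
}

# regular alternating-foot step series pair for one pedestrian
regular_steps <- function(ped_id, period = 1, phase = 0, t_end = 15) {
  list(step_series(ped_id, "right", seq(phase, t_end, by = period)),
       step_series(ped_id, "left",
                   seq(phase + period / 2, t_end, by = period)))
}

# small fast simulated trial (6 per group, 2 start rows)
small_sim <- function(seed = 1, condition = "NO_CUE", ...) {
  simulate_trial(condition_preset(condition, seed = seed, n_per_group = 6,
                                  rows = 2, ...))
}

# brute-force connected components by transitive closure of reachability;
# independent oracle for the union-find clustering
oracle_components <- function(n, edges) {
  adj <- diag(TRUE, n)
  if (length(edges)) for (k in seq_len(nrow(edges))) {
    adj[edges[k, 1], edges[k, 2]] <- TRUE
    adj[edges[k, 2], edges[k, 1]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- integer(n)
  for (i in seq_len(n)) comp[i] <- which(adj[i, ])[1]
  match(comp, unique(comp))
}
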