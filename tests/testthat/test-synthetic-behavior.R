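test_that("cue placement follows per-side Poisson counts with the refractory bound", {
  cfg <- maze_config()
  set.seed(5)
  n <- 3000
  maj <- minc <- numeric(n)
  min_gap <- Inf
  for (i in seq_len(n)) {
    cs <- place_cues(cfg, "R")
    maj[i] <- length(cs$R); minc[i] <- length(cs$L)
    gaps <- c(diff(cs$R), diff(cs$L))
    if (length(gaps)) min_gap <- min(min_gap, gaps)
    expect_true(all(cs$R >= cfg$L_pre & cs$R <= cfg$L_pre + cfg$L_cue))
  }
  expect_gt(min_gap, cfg$refractory - 1e-12)
  # sample means within 4 standard errors of the configured Poisson means
  expect_lt(abs(mean(maj) - 7.7), 4 * sqrt(7.7 / n))
  expect_lt(abs(mean(minc) - 2.3), 4 * sqrt(2.3 / n))
})

test_that("degenerate and infeasible cue configurations are handled", {
  cfg0 <- maze_config(mean_count_minority = 0, mean_count_majority = 7.7)
  set.seed(1)
  cs <- place_cues(cfg0, "R")
  expect_identical(cs$L, numeric(0))
  cfg_bad <- maze_config(L_cue = 40, mean_count_majority = 7.7,
                         mean_count_minority = 2.3)
  expect_error(place_cues(cfg_bad, "R"), "unplaceable")
})

test_that("deterministic kinematics give constant speed and exact duration", {
  cfg <- maze_config()
  ag <- agent_params(speed_sd = 0, theta_noise_sd = 0)
  set.seed(1)
  tr <- simulate_kinematics(cfg, ag, "R")
  expect_true(all(tr$v == ag$speed_mean))
  L <- cfg$L_pre + cfg$L_cue + cfg$L_delay
  expect_equal(max(tr$t), L / ag$speed_mean, tolerance = 2 / 85)
  expect_true(all(diff(tr$y) > 0))
})

test_that("stochastic kinematics track the configured mean speed", {
  cfg <- maze_config(); ag <- agent_params()
  set.seed(2)
  vbar <- replicate(100, {
    tr <- simulate_kinematics(cfg, ag, "R")
    in_cue <- tr$y >= cfg$L_pre & tr$y <= cfg$L_pre + cfg$L_cue
    mean(tr$v[in_cue])
  })
  expect_lt(abs(mean(vbar) - ag$speed_mean) / ag$speed_mean, 0.1)
})

test_that("theta-controlled sessions clamp the view angle through the cue region", {
  cfg <- maze_config(theta_controlled = TRUE)
  set.seed(3)
  tr <- simulate_kinematics(cfg, agent_params(), "L")
  y_mid_delay <- cfg$L_pre + cfg$L_cue + cfg$L_delay / 2
  expect_true(all(tr$theta[tr$y < y_mid_delay] == 0))
  expect_lt(min(tr$theta), -10) # ramps toward the left arm afterwards
})

test_that("cue onsets occur at the visibility distance with the expected visual angle", {
  cfg <- maze_config()
  ag <- agent_params(speed_sd = 0, theta_noise_sd = 0)
  set.seed(4)
  tr <- simulate_kinematics(cfg, ag, "R")
  on <- detect_cue_onsets(tr, list(R = c(80, 150), L = 120), cfg)
  expect_true(all(on$seen))
  # onset distance in (10 - v/display_rate, 10]
  d <- on$y - on$y_on
  expect_true(all(d <= cfg$visibility_distance + 1e-9))
  expect_true(all(d > cfg$visibility_distance - ag$speed_mean / cfg$display_rate))
  # visual angle: atan2(+-4, onset distance) at zero view angle, ~ +-22 deg
  for (i in seq_len(nrow(on))) {
    dx <- if (on$side[i] == "R") cfg$lateral_offset else -cfg$lateral_offset
    expect_equal(on$phi[i], atan2(dx, d[i]) * 180 / pi, tolerance = 1e-9)
  }
  expect_equal(round(atan2(4, 10) * 180 / pi), 22)
  expect_true(all(abs(on$t_off - on$t_on - 0.2) < 1e-9))
  # unseen cue: beyond a truncated trajectory
  short <- lapply(tr, function(z) z[tr$y < 100])
  on2 <- detect_cue_onsets(short, list(R = 300, L = numeric(0)), cfg)
  expect_false(on2$seen[1])
})

test_that("running evidence counts cues with onset at or before t", {
  trial <- data.frame(side = c("R", "L", "R"), t_on = c(1, 2, 3),
                      seen = TRUE)
  ev <- running_evidence(trial, c(0.5, 1, 2, 3, 10))
  expect_equal(ev$delta, c(0, 1, 0, 1, 1))
  expect_equal(ev$n_right[1], 0)
  expect_equal(ev$n_left[5], 1)
})

test_that("choice simulation respects lapse and evidence weights", {
  cfg <- maze_config()
  # no cues, no bias: P(right) = 0.5
  ag <- agent_params()
  set.seed(6)
  ch <- replicate(1000, simulate_choice(list(R = numeric(0), L = numeric(0)),
                                        ag, cfg))
  expect_lt(abs(mean(ch == "R") - 0.5), 0.05)
  # full lapse: choices ignore even decisive evidence
  ag_lapse <- agent_params(lapse_rate = 0.499)
  cues <- list(R = seq(40, 200, by = 20), L = numeric(0))
  ch2 <- replicate(1000, simulate_choice(cues, ag_lapse, cfg))
  expect_lt(abs(mean(ch2 == "R") - 0.5), 0.06)
  # lapse-free agent with strong evidence chooses the cue side
  ch3 <- replicate(200, simulate_choice(cues, agent_params(lapse_rate = 0), cfg))
  expect_gt(mean(ch3 == "R"), 0.95)
})

test_that("sessions are reproducible from their seed", {
  cfg <- maze_config(); ag <- agent_params()
  s1 <- generate_session(cfg, ag, 6, seed = 123)
  s2 <- generate_session(cfg, ag, 6, seed = 123)
  expect_identical(s1$trials[[4]]$cues, s2$trials[[4]]$cues)
  expect_identical(s1$trials[[6]]$traj$y, s2$trials[[6]]$traj$y)
  expect_identical(vapply(s1$trials, `[[`, character(1), "choice"),
                   vapply(s2$trials, `[[`, character(1), "choice"))
})

test_that("de-biasing shifts rewarded-side sampling away from a biased agent's side", {
  cfg <- maze_config()
  ag <- agent_params(side_bias = 6, lapse_rate = 0) # near-always right
  s <- generate_session(cfg, ag, 250, seed = 9, kinematics = FALSE)
  rewarded <- vapply(s$trials, `[[`, character(1), "rewarded_side")
  expect_gt(mean(rewarded == "L"), 0.6)
})

test_that("trial filters exclude backtracking and outlier-duration trials", {
  s <- shared_session(n_trials = 12, seed = 31)
  expect_true(all(filter_trials(s))) # generator produces clean trials
  s2 <- s
  # inject a -0.25 cm backtracking displacement between two iterations
  s2$trials[[3]]$traj$y[51] <- s2$trials[[3]]$traj$y[50] - 0.25
  mask <- filter_trials(s2)
  expect_false(mask[3])
  s3 <- s
  s3$trials[[5]]$duration <- 2 * median(vapply(s$trials, `[[`, numeric(1),
                                               "duration"))
  expect_false(filter_trials(s3)[5])
  expect_true(sum(filter_trials(s3)) >= 10)
})
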