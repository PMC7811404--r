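test_that("polar decomposition yields orthonormal modes closest to the variables", {
  set.seed(10)
  X <- matrix(rnorm(200 * 4), 200, 4) %*%
    (diag(4) + 0.4) # correlated columns
  colnames(X) <- c("theta", "v", "delta", "choice")
  um <- uncorrelated_modes(X)
  expect_lt(max(abs(crossprod(um$Y) - diag(4))), 1e-8)
  expect_equal(um$H, t(um$H), tolerance = 1e-10)
  expect_true(all(um$correlations > 0.5))
  # already-orthonormal (zero-mean) input is returned unchanged
  M <- matrix(rnorm(100 * 3), 100, 3)
  Qc <- qr.Q(qr(scale(M, center = TRUE, scale = FALSE)))
  colnames(Qc) <- c("a", "b", "c")
  expect_equal(unname(uncorrelated_modes(Qc)$Y), unname(Qc),
               tolerance = 1e-8)
  # optimality: closer in Frobenius norm than random orthonormal competitors
  Xs <- scale(X, center = TRUE, scale = FALSE)
  Xs <- sweep(Xs, 2, sqrt(colSums(Xs^2)), "/")
  d_polar <- norm(um$Y - Xs, "F")
  worse <- replicate(300, {
    Qr <- qr.Q(qr(matrix(rnorm(200 * 4), 200, 4)))
    norm(Qr - Xs, "F") >= d_polar
  })
  expect_true(all(worse))
  # collinear columns are reported by name
  Xbad <- cbind(X, dup = X[, 1])
  expect_error(uncorrelated_modes(Xbad), "collinear")
})

test_that("Benjamini-Hochberg matches a brute-force oracle", {
  expect_identical(bh_correct(c(0.01, 0.02, 0.2)), c(TRUE, TRUE, FALSE))
  expect_identical(bh_correct(rep(1, 5)), rep(FALSE, 5))
  expect_identical(bh_correct(rep(0.05 / 6, 6)), rep(TRUE, 6))
  set.seed(11)
  for (i in 1:300) {
    n <- sample(1:6, 1)
    p <- sample(seq(0.001, 1, by = 0.001), n, replace = TRUE)
    expect_identical(bh_correct(p), oracle_bh(p, 0.05))
  }
  # the literal first-rank variant is never more permissive
  for (i in 1:50) {
    p <- runif(6, 0.001, 1)
    expect_true(all(bh_correct(p, literal_first_rank = TRUE) |
                      !bh_correct(p, literal_first_rank = TRUE) ==
                      !bh_correct(p)))
    expect_lte(sum(bh_correct(p, literal_first_rank = TRUE)),
               sum(bh_correct(p)))
  }
})

test_that("trial-level permutation preserves per-cell amplitude multisets", {
  set.seed(12)
  trial_ids <- rep(1:10, times = sample(3:8, 10, replace = TRUE))
  states <- matrix(rnorm(length(trial_ids) * 4), ncol = 4)
  perm <- with_seed(5, pulsecue:::permute_trial_blocks(states, trial_ids))
  expect_false(identical(perm, states))
  for (j in 1:4) expect_identical(sort(perm[, j]), sort(states[, j]))
})

test_that("the decoder is calibrated on unrelated labels and detects planted signal", {
  set.seed(13)
  n_trials <- 40
  trial_ids <- rep(seq_len(n_trials), each = 5)
  n <- length(trial_ids)
  states <- matrix(rgamma(n * 6, 4, 2), n, 6)
  noise_labels <- rnorm(n)
  r0 <- decode_variable(states, noise_labels, trial_ids, seed = 2)$r
  expect_lt(abs(r0), 2 / sqrt(n) + 0.1)
  # planted binary signal: amplitudes shift with the trial's label
  lab <- rep(sample(c(-1, 1), n_trials, replace = TRUE), each = 5)
  states2 <- states + outer(lab, c(1, -1, 1, 0, 0, -1)) * 0.8
  res <- permutation_pvalue(states2, lab, trial_ids, n_null = 50, seed = 3)
  expect_gt(res$r_obs, quantile(res$r_null, 0.95))
  expect_lt(res$p, 0.05)
  # observed below every null gives the add-one floor... and above every
  # null gives the add-one minimum
  expect_equal(min(res$p), 1 / 51, tolerance = 1e-12)
  # duplicating an informative column does not hurt performance much
  r_dup <- decode_variable(cbind(states2, states2[, 1]), lab, trial_ids,
                           seed = 2)$r
  r_base <- decode_variable(states2, lab, trial_ids, seed = 2)$r
  expect_gt(r_dup, r_base - 0.1)
  # degenerate labels are flagged
  expect_warning(decode_variable(states, rep(1, n), trial_ids),
                 "single-class")
})

test_that("neural state tables contain contralateral cue-locked cells only", {
  s <- shared_session(n_trials = 10, seed = 61)
  events <- cue_events(s)
  # synthetic amplitude table: 3 R cells, 1 L cell
  mk <- function(id, side) {
    ev <- events[events$side == side, ]
    data.frame(cell_id = id, side = side, trial_id = ev$trial_id,
               cue_index = ev$cue_index, t = ev$t, y = ev$y, phi = ev$phi,
               v = ev$v, theta = ev$theta, delta = ev$delta,
               choice = ev$choice, prev_choice = ev$prev_choice,
               prev_reward = ev$prev_reward,
               A = rgamma(nrow(ev), 4, 2), jitter = 0)
  }
  set.seed(14)
  amp <- rbind(mk(1, "R"), mk(2, "R"), mk(3, "R"), mk(4, "L"))
  locked <- c(`1` = TRUE, `2` = TRUE, `3` = FALSE, `4` = TRUE)
  ns <- build_neural_states(amp, locked, s, contra_side = "R")
  expect_equal(ns$cells, c(1, 2))
  expect_equal(ncol(ns$states), 2)
  expect_equal(nrow(ns$states), sum(events$side == "R"))
  expect_true(all(ns$meta$third %in% 1:3))
  # third assignment is by position within equal thirds of the cue region
  cfg <- s$config
  y_rel <- ns$meta$y - cfg$L_pre
  expect_identical(ns$meta$third,
                   pmin(3, pmax(1, ceiling(y_rel / (cfg$L_cue / 3)))))
  # no qualifying cells raises the dedicated condition
  expect_error(build_neural_states(amp, c(`1` = FALSE, `2` = FALSE,
                                          `3` = FALSE, `4` = FALSE), s),
               class = "pulsecue_no_cells")
})

test_that("meta-regression recovers a planted cell-count dependence", {
  set.seed(15)
  n_sessions <- 40
  pred <- data.frame(V1 = rbinom(n_sessions, 1, 0.5),
                     AM = rbinom(n_sessions, 1, 0.5),
                     layer5 = rbinom(n_sessions, 1, 0.5),
                     n_cells = rpois(n_sessions, 6))
  acc <- 0.1 + 0.06 * pred$n_cells + rnorm(n_sessions, 0, 0.05)
  mr <- decoding_meta_regression(acc, pred, n_boot = 200, seed = 4)
  expect_gt(mr$weights[["n_cells"]], 0)
  expect_gt(mr$ci["n_cells", "lower"], 0)
  # area indicators carry no signal: intervals cover zero
  expect_true(mr$ci["V1", "lower"] < 0 && mr$ci["V1", "upper"] > 0)
  # deterministic given the seed
  mr2 <- decoding_meta_regression(acc, pred, n_boot = 200, seed = 4)
  expect_identical(mr$weights, mr2$weights)
  expect_identical(mr$ci, mr2$ci)
  expect_error(decoding_meta_regression(acc[1:5], pred[1:5, ]), ">= 10")
})
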