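test_that("calcium kernel is normalized to peak 1 at its analytic argmax", {
  ck <- calcium_kernel()
  t_star <- ck$tau_on * log((ck$tau_on + ck$tau_off) / ck$tau_on)
  expect_equal(t_star, 0.0790574, tolerance = 1e-6)
  expect_identical(calcium_kernel_eval(ck, 0), 0)
  expect_equal(calcium_kernel_eval(ck, t_star), 1, tolerance = 1e-12)
  # the argmax is a maximum: neighbours are smaller
  expect_lt(calcium_kernel_eval(ck, t_star - 1e-3), 1)
  expect_lt(calcium_kernel_eval(ck, t_star + 1e-3), 1)
  expect_lt(calcium_kernel_eval(ck, 10), 1e-10)
  expect_identical(calcium_kernel_eval(ck, -0.5), 0)
  expect_error(calcium_kernel(tau_on = -1), "positive")
  expect_error(calcium_kernel(tau_on = 0.4, tau_off = 0.3), "smaller")
})

test_that("two-sided Gaussian response shape is symmetric when rise equals fall", {
  ik <- impulse_kernel(0, 0.1, 0.1)
  tt <- seq(0.01, 0.4, by = 0.01)
  expect_equal(pulsecue:::two_sided_gaussian(ik, tt),
               pulsecue:::two_sided_gaussian(ik, -tt))
})

test_that("discrete impulse-response integral matches quadrature at 1 ms resolution", {
  ik <- impulse_kernel(0.1, 0.08, 0.15)
  ck <- calcium_kernel()
  tab <- pulsecue:::impulse_response_table(ik, ck, dt = 1e-3, t_max = 4)
  # integral of the convolution = product of the factors' integrals
  b_area <- 2 / (sqrt(pi) * (0.08 + 0.15)) *
    (0.08 + 0.15) * sqrt(pi / 2) # = sqrt(2)
  ca_area <- integrate(function(t) calcium_kernel_eval(ck, t), 0, 20,
                       rel.tol = 1e-10)$value
  expect_equal(sum(tab$g) * tab$dt, b_area * ca_area, tolerance = 0.01)
})

test_that("near-instantaneous calcium kernel leaves the response shape unchanged", {
  ik <- impulse_kernel(0, 0.08, 0.15)
  ck_fast <- calcium_kernel(tau_on = 2e-4, tau_off = 2e-3)
  tt <- seq(-0.3, 0.5, by = 0.01)
  g <- impulse_response_eval(ik, ck_fast, tt, dt = 1e-4)
  b <- pulsecue:::two_sided_gaussian(ik, tt)
  # delta-like indicator kernel: convolution ~ original shape scaled by the
  # indicator area; compare after peak normalization
  expect_equal(g / max(g), b / max(b), tolerance = 0.05)
})

test_that("rendered traces superpose and match a direct-summation oracle", {
  s <- shared_session(n_trials = 5, seed = 31)
  events <- cue_events(s, include = rep(TRUE, 5))
  nrn <- ground_truth_neuron(preferred_side = "R", noise_sd = 0,
                             jitter_sd = 0)
  ev_p <- events[events$side == "R", ]
  m <- nrow(ev_p)
  amps <- rep(0, m); amps[1] <- 1.3
  jit <- rep(0, m)
  tr1 <- render_trace(nrn, s, amps, events = events, jitters = jit,
                      noise = FALSE)
  amps2 <- rep(0, m); amps2[m] <- 0.7
  tr2 <- render_trace(nrn, s, amps2, events = events, jitters = jit,
                      noise = FALSE)
  tr12 <- render_trace(nrn, s, amps + amps2, events = events, jitters = jit,
                       noise = FALSE)
  expect_equal(tr12$dff, tr1$dff + tr2$dff, tolerance = 1e-10)
  # all-zero amplitudes with no noise: identically zero trace
  tr0 <- render_trace(nrn, s, rep(0, m), events = events, jitters = jit,
                      noise = FALSE)
  expect_true(all(tr0$dff == 0))
  # single-cue peak matches the kernel maximum up to frame discretization
  tab <- pulsecue:::impulse_response_table(nrn$kernel, nrn$calcium)
  expect_equal(max(tr1$dff), 1.3 * max(tab$g), tolerance = 0.05)

  # independent oracle: per-fine-sample direct summation, then box-average
  oversample <- 64
  frame_rate <- s$config$frame_rate
  dtf <- 1 / (frame_rate * oversample)
  nf <- length(tr12$frame_times)
  tfine <- (seq_len(nf * oversample) - 0.5) * dtf
  amps_all <- amps + amps2
  fine <- numeric(length(tfine))
  for (i in seq_len(m)) {
    if (amps_all[i] == 0) next
    td <- tfine - ev_p$t[i] - nrn$kernel$tau_lag
    sel <- td >= tab$t[1] & td <= tab$t[length(tab$t)]
    fine[sel] <- fine[sel] +
      amps_all[i] * approx(tab$t, tab$g, td[sel], yleft = 0, yright = 0)$y
  }
  oracle <- colMeans(matrix(fine, nrow = oversample))
  expect_lt(max(abs(oracle - tr12$dff)), 1e-6)
})

test_that("amplitude sampling matches the Gamma moments", {
  s <- shared_session(n_trials = 5, seed = 31)
  events <- cue_events(s, include = rep(TRUE, 5))
  ev_p <- events[events$side == "R", ][1, , drop = FALSE]
  nrn <- ground_truth_neuron(modulation = list(type = "null",
                                               rf = default_rf("R"),
                                               speed_coef = 0,
                                               amp_scale = 2 /
                                                 (1 - exp(-1 / 0.1^2))),
                             gamma_shape = 4)
  set.seed(7)
  ev_rep <- ev_p[rep(1, 1e5), ]
  ev_rep$phi <- 22 # at the RF centre so mu = 2 exactly
  samp <- sample_amplitudes(nrn, ev_rep,
                            speed_q = c(q10 = 50, q50 = ev_p$v, q90 = 70))
  expect_equal(mean(samp$mu), 2, tolerance = 1e-6)
  expect_equal(mean(samp$amplitudes), 2, tolerance = 0.02)
  expect_equal(var(samp$amplitudes), 1, tolerance = 0.03) # mu^2 / k = 1
  # large shape: draws concentrate on the mean
  nrn_hi <- nrn; nrn_hi$gamma_shape <- 1e6
  samp_hi <- sample_amplitudes(nrn_hi, ev_rep[1:100, ],
                               speed_q = c(q10 = 50, q50 = ev_p$v, q90 = 70))
  expect_lt(max(abs(samp_hi$amplitudes - samp_hi$mu)), 0.02)
})

test_that("population generation is reproducible and labels ground truth", {
  s <- shared_session(n_trials = 8, seed = 32)
  spec <- population_spec(n_null = 1, n_ssa = 1, n_choice = 1, n_counts = 1,
                          n_distractor = 2)
  p1 <- generate_population(s, spec, seed = 5)
  p2 <- generate_population(s, spec, seed = 5)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$traces[[2]]$dff, p2$traces[[2]]$dff)
  expect_equal(p1$types,
               c("null", "ssa", "choice", "counts", "distractor",
                 "distractor"))
  expect_equal(length(p1$traces), 6)
  # distractor traces carry no per-cue ground truth
  expect_false(any(p1$truth$cell_id > 4))
})
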