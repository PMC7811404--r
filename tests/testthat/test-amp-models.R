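test_that("skew-Gaussian receptive field matches its closed forms and clips", {
  rf <- list(form = "skew_gaussian", phi0 = 10, sigma = 30, zeta = 0.4)
  expect_equal(angular_rf_eval(rf, 10), 1 - exp(-1 / 0.4^2))
  # zeta = 0 degenerates to a symmetric Gaussian
  rf0 <- list(form = "skew_gaussian", phi0 = -5, sigma = 25, zeta = 0)
  phis <- seq(-90, 90, by = 5)
  expect_equal(angular_rf_eval(rf0, phis), exp(-(phis + 5)^2 / (2 * 25^2)))
  # width term crosses zero at phi0 - sigma/zeta = -65: clipped to 0, finite
  vals <- angular_rf_eval(rf, c(-200, -100, -65.0001, -65))
  expect_true(all(is.finite(vals)))
  expect_true(all(vals >= 0))
  expect_identical(vals[4], 0)
})

test_that("sigmoid receptive field has the printed finite asymptotes", {
  rf <- list(form = "sigmoid", phi0 = 0, zeta = 15, rho0 = 0.8, nu = 2)
  hi <- angular_rf_eval(rf, 1e6)
  lo <- angular_rf_eval(rf, -1e6)
  expect_equal(hi, 1 - 0.8 / 2 + 0.8)   # logistic term -> 1
  expect_equal(lo, 1 - 0.8 / 2)         # logistic term -> 0 (nu > 0)
  expect_true(all(is.finite(angular_rf_eval(rf, seq(-180, 180, by = 1)))))
})

test_that("speed standardization follows the quantile formula exactly", {
  expect_identical(standardize_speed(50, 40, 50, 65), 0)
  expect_equal(standardize_speed(65, 40, 50, 65), 15 / 25)
  # symmetric quantiles put Q90 at +0.5
  expect_equal(standardize_speed(70, 50, 60, 70), 0.5)
  expect_error(standardize_speed(1, 10, 10, 10), "exceed")
})

test_that("adaptation recursion has the stated fixed points and limits", {
  tt <- c(0, 0.3, 0.8, 1.1, 5)
  base <- c(0.9, 1.1, 0.8, 1.2, 1.0)
  # literal recursion with unit history: xi = 1 gives h identically 1
  mu_unit <- ssa_mean_sequence(tt, rep(1, 5), xi = 1, lam = 0.5)
  expect_equal(mu_unit, rep(1, 5))
  # state-recursion variant: xi = 1 means no adaptation for any base means
  mu_state <- ssa_mean_sequence(tt, base, xi = 1, lam = 0.5,
                                variant = "state")
  expect_equal(mu_state, base)
  # literal variant fixes the first mean at 1 regardless of its base
  mu <- ssa_mean_sequence(tt, base, xi = 0.6, lam = 0.5)
  expect_identical(mu[1], 1)
  # infinite gap: full recovery toward 1
  mu2 <- ssa_mean_sequence(c(0, 1e6), c(1, 1), xi = 0.3, lam = 0.5)
  expect_equal(mu2[2], 1)
  # zero gap after a unit response: h equals xi
  mu3 <- ssa_mean_sequence(c(0, 1e-12), c(1, 1), xi = 0.4, lam = 0.5)
  expect_equal(mu3[2], 0.4, tolerance = 1e-9)
  expect_error(ssa_mean_sequence(c(1, 0), c(1, 1), 0.5, 0.5), "sorted")
})

test_that("natural cubic spline agrees with an independent tridiagonal oracle", {
  set.seed(8)
  cx <- c(0, 1.5, 2, 4, 7)
  cv <- rnorm(5)
  xs <- runif(100, -2, 9) # includes extrapolation on both sides
  expect_equal(spline_eval(cx, cv, xs), oracle_natural_spline(cx, cv, xs),
               tolerance = 1e-10)
  expect_equal(spline_eval(cx, cv, cx), cv, tolerance = 1e-12)
  expect_true(all(spline_eval(cx, rep(3, 5), xs) == 3))
  expect_error(spline_eval(c(0, 0, 1), 1:3, 0.5), "duplicate")
  expect_error(spline_eval(c(0, 1), 1:2, 0.5), ">= 3")
})

test_that("Gamma negative log-likelihood equals the exact mean-parameterized density", {
  # exponential special case: k = 1, A = mu -> ln(mu) + 1 per observation
  expect_equal(gamma_negloglik(2, 2, 1), log(2) + 1)
  set.seed(9)
  for (i in 1:20) {
    A <- rgamma(7, 2, 1) + 0.01
    mu <- rgamma(7, 3, 2) + 0.01
    k <- runif(1, 0.2, 20)
    oracle <- -sum(dgamma(A, shape = k, scale = mu / k, log = TRUE))
    expect_equal(gamma_negloglik(A, mu, k), oracle, tolerance = 1e-10)
  }
  # MLE of the mean with one observation is the observation itself
  A <- 1.7
  muhat <- optimize(function(m) gamma_negloglik(A, m, 3), c(0.01, 50))$minimum
  expect_equal(muhat, A, tolerance = 1e-4)
  expect_error(gamma_negloglik(c(1, 0), 1, 1), "positive")
  expect_error(gamma_negloglik(1, -1, 1), "positive")
  expect_error(gamma_negloglik(1, 1, 0), "positive")
})

test_that("zero-amplitude substitution yields positive noise-scaled draws", {
  s <- shared_session(n_trials = 15, seed = 51)
  spec <- population_spec(n_null = 1, n_ssa = 0, n_choice = 0, n_counts = 0,
                          noise_frac = 0.3)
  pop <- generate_population(s, spec, seed = 52)
  fit <- fit_impulse_model(pop$traces[[1]], s)
  a1 <- substitute_zero_amplitudes(fit, sigma_f = 0.1, seed = 3)
  expect_true(all(a1 > 0))
  # without zeros the operation is a no-op
  if (all(fit$amplitudes > 0)) expect_identical(a1, fit$amplitudes)
  zeros <- which(fit$amplitudes == 0)
  if (length(zeros) >= 3) {
    a2 <- substitute_zero_amplitudes(fit, sigma_f = 0.2, seed = 3)
    # replacement scale is proportional to the noise level
    expect_equal(median(a2[zeros]) / median(a1[zeros]), 2, tolerance = 0.3)
  }
})

test_that("Akaike weights are normalized, order-equivariant, and dominance-sensitive", {
  mk <- function(aicc) structure(list(aicc = aicc, side = "R", L_cue = 200),
                                 class = "amp_model_fit")
  fits <- list(null = mk(110), ssa = mk(90), choice = mk(112),
               counts = mk(111))
  ens <- select_and_average(fits)
  expect_equal(sum(ens$weights), 1)
  expect_gt(ens$weights[["ssa"]], 0.9999) # 20-unit dominance
  expect_identical(ens$best_model, "ssa")
  # permuting branch order permutes the weights identically
  ens2 <- select_and_average(fits[c("counts", "null", "choice", "ssa")])
  expect_equal(ens2$weights[names(ens$weights)], ens$weights)
  # equal AICc: uniform weights and the null default
  ens3 <- select_and_average(list(null = mk(100), ssa = mk(100),
                                  choice = mk(100), counts = mk(100)))
  expect_equal(unname(ens3$weights), rep(0.25, 4))
  expect_identical(ens3$best_model, "null")
})

test_that("the null-default selection rule switches at relative likelihood 0.05", {
  mk <- function(aicc) structure(list(aicc = aicc, side = "R", L_cue = 200),
                                 class = "amp_model_fit")
  gap_boundary <- -2 * log(0.05) # ~ 5.9915
  just_in <- select_and_average(list(null = mk(100 + gap_boundary + 1e-6),
                                     ssa = mk(100), choice = mk(150),
                                     counts = mk(150)))
  expect_identical(just_in$best_model, "ssa")
  just_out <- select_and_average(list(null = mk(100 + gap_boundary - 1e-6),
                                      ssa = mk(100), choice = mk(150),
                                      counts = mk(150)))
  expect_identical(just_out$best_model, "null")
})

test_that("modulation models are recovered from model-generated amplitudes", {
  s <- cached("amp_session", generate_session(maze_config(), agent_params(),
                                              60, seed = 21))
  spec <- population_spec(n_null = 1, n_ssa = 1, n_choice = 1, n_counts = 1)
  pop <- generate_population(s, spec, seed = 22)
  events <- cue_events(s, include = rep(TRUE, length(s$trials)))
  fit4 <- function(cell) {
    amp <- amp_from_truth(pop, events, cell)
    fits <- lapply(setNames(c("null", "ssa", "choice", "counts"),
                            c("null", "ssa", "choice", "counts")),
                   function(mt) fit_amp_model(amp, s$config, mt,
                                              seed = cell * 7))
    select_and_average(fits)
  }
  ens_ssa <- fit4(which(pop$types == "ssa"))
  expect_identical(ens_ssa$best_model, "ssa")
  xi_hat <- exp(ens_ssa$fits$ssa$params$log_xi)
  lam_hat <- exp(ens_ssa$fits$ssa$params$log_lambda)
  expect_gt(xi_hat, 0.3); expect_lt(xi_hat, 0.7)       # truth 0.5
  expect_gt(lam_hat, 0.4); expect_lt(lam_hat, 1.6)     # truth 0.8 s
  ens_choice <- fit4(which(pop$types == "choice"))
  expect_identical(ens_choice$best_model, "choice")
  # recovered choice preference matches the planted direction
  nrn <- pop$neurons[[which(pop$types == "choice")]]
  pref_gain <- nrn$modulation$gain[[nrn$preferred_side]]
  anti_gain <- nrn$modulation$gain[[setdiff(c("R", "L"),
                                            nrn$preferred_side)]]
  cm <- choice_modulation_strength(ens_choice, sigma_f = 0.05)
  expect_identical(sign(mean(cm$delta_a)), sign(pref_gain - anti_gain))
})

test_that("choice-modulation strength is invariant to global amplitude rescaling", {
  s <- cached("amp_session", generate_session(maze_config(), agent_params(),
                                              60, seed = 21))
  spec <- population_spec(n_null = 0, n_ssa = 0, n_choice = 1, n_counts = 0)
  pop <- generate_population(s, spec, seed = 23)
  events <- cue_events(s, include = rep(TRUE, length(s$trials)))
  amp <- amp_from_truth(pop, events, 1)
  ens_of <- function(a) {
    fits <- lapply(setNames(c("null", "ssa", "choice", "counts"),
                            c("null", "ssa", "choice", "counts")),
                   function(mt) fit_amp_model(a, s$config, mt, seed = 5))
    select_and_average(fits)
  }
  e1 <- ens_of(amp)
  amp3 <- amp; amp3$A <- amp3$A * 3
  e3 <- ens_of(amp3)
  cm1 <- choice_modulation_strength(e1, sigma_f = 0.02)
  cm3 <- choice_modulation_strength(e3, sigma_f = 0.06) # noise scales too
  expect_equal(cm3$delta_a, cm1$delta_a, tolerance = 0.05)
  expect_equal(cm3$mean_amplitude / cm1$mean_amplitude, 3, tolerance = 0.05)
  # identical per-choice predictions give identically zero modulation
  cm_same <- cm1
  expect_equal(choice_modulation_strength(
    structure(list(fits = e1$fits["null"], weights = c(null = 1),
                   best_model = "null", side = "R", L_cue = 200),
              class = "amp_model_ensemble"), sigma_f = 0.02)$delta_a,
    rep(0, length(cm_same$y)))
})

test_that("too few filtered amplitudes is a flagged failure", {
  s <- shared_session(n_trials = 5, seed = 31)
  events <- cue_events(s, include = rep(TRUE, 5))
  spec <- population_spec(n_null = 1, n_ssa = 0, n_choice = 0, n_counts = 0)
  pop <- generate_population(s, spec, seed = 3)
  amp <- amp_from_truth(pop, events, 1)
  amp <- amp[seq_len(min(25, nrow(amp))), ]
  expect_error(fit_amp_model(amp, s$config, "null"), "fewer than 30")
})
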