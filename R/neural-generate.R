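#' Ground-truth mean amplitudes for a neuron given cue contexts
#'
#' Evaluates the neuron's amplitude-modulation model at each cue event:
#' an angular receptive field times a speed factor times a model-specific
#' term (adaptation recursion, choice-dependent spatial ramp, or cue-count
#' dependence). Means are floored at a small positive value since the Gamma
#' observation model requires positive means.
#'
#' @param neuron A [ground_truth_neuron()].
#' @param events Cue-event rows (one per preferred-side cue, in onset order)
#'   as from [cue_events()].
#' @param speed_q Optional named vector `c(q10, q50, q90)` of speed
#'   quantiles; computed from `events$v` if omitted.
#' @return Vector of positive means, one per event row.
#' @export
true_mean_amplitudes <- function(neuron, events, speed_q = NULL) {
  mod <- neuron$modulation
  if (is.null(speed_q)) {
    q <- quantile(events$v, c(0.1, 0.5, 0.9), names = FALSE)
    speed_q <- c(q10 = q[1], q50 = q[2], q90 = q[3])
  }
  vt <- standardize_speed(events$v, speed_q["q10"], speed_q["q50"],
                          speed_q["q90"])
  rho <- angular_rf_eval(mod$rf, events$phi)
  scale <- if (is.null(mod$amp_scale)) 1 else mod$amp_scale
  sc <- if (is.null(mod$speed_coef)) 0 else mod$speed_coef
  mu <- switch(mod$type,
    null = {
      # null cells carry a speed *function*; a spline when supplied (the
      # model family's own parameterization), else a linear factor
      sv <- if (!is.null(mod$v_values))
        spline_eval(mod$v_knots, mod$v_values, events$v)
      else 1 + sc * vt
      scale * rho * pmax(sv, 0.05)
    },
    ssa = {
      base <- rho * (1 + sc * vt)
      ssa_mean_sequence(events$t, pmax(base, 1e-6), mod$xi, mod$lambda)
    },
    choice = {
      gain <- mod$gain[events$choice]
      slope <- mod$slope[events$choice]
      y_rel <- (events$y - mod$L_pre) / mod$L_cue
      scale * rho * (1 + sc * vt) * (gain + slope * (y_rel - 0.5))
    },
    counts = {
      dpref <- if (neuron$preferred_side == "R") events$delta else -events$delta
      scale * rho * (1 + sc * vt) * (1 + mod$count_coef * dpref)
    },
    stop("true_mean_amplitudes: unknown modulation type ", mod$type))
  pmax(mu, 1e-3)
}

#' Sample per-cue response amplitudes from the Gamma observation model
#'
#' `A_i ~ Gamma(shape = k, scale = mu_i / k)`, so `E[A_i] = mu_i` and
#' `Var[A_i] = mu_i^2 / k`. For choice-modulated neurons with per-choice
#' shapes, k is indexed by the trial's choice.
#'
#' @inheritParams true_mean_amplitudes
#' @return List with `amplitudes` and the underlying `mu`. Draws from the
#'   current RNG stream.
#' @export
sample_amplitudes <- function(neuron, events, speed_q = NULL) {
  mu <- true_mean_amplitudes(neuron, events, speed_q)
  if (any(mu <= 0)) stop("sample_amplitudes: non-positive mean amplitude")
  k <- neuron$gamma_shape
  kk <- if (length(k) > 1) unname(k[events$choice]) else rep_len(k, length(mu))
  list(amplitudes = rgamma(length(mu), shape = kk, scale = mu / kk), mu = mu)
}

# session frame grid at the imaging rate; frame f covers
# [(f-1), f] / frame_rate and is stamped at its midpoint
session_frames <- function(session, frame_rate = session$config$frame_rate) {
  last <- session$trials[[length(session$trials)]]
  t_end <- last$t_start + last$duration + last$iti
  n <- floor(t_end * frame_rate)
  (seq_len(n) - 0.5) / frame_rate
}

#' Render a fluorescence trace from the impulse-response forward model
#'
#' Superposes amplitude-scaled, jittered copies of the neuron's impulse
#' response at its preferred-side cue onsets (plus scaled-down secondary
#' responses at opposite-side onsets when present), on a fine internal grid
#' that is box-averaged to the imaging frame rate, then adds i.i.d. Gaussian
#' noise per frame.
#'
#' @param neuron A [ground_truth_neuron()].
#' @param session A `session_log` with kinematics.
#' @param amplitudes Amplitudes aligned to the neuron's preferred-side rows
#'   of `events` (all trials, onset order).
#' @param events Cue-event table for all trials
#'   (`cue_events(session, include = rep(TRUE, n))`); computed if omitted.
#' @param secondary_amplitudes Amplitudes for opposite-side cues when
#'   `neuron$has_secondary`.
#' @param jitters Per-cue onset jitters, s; drawn as
#'   `rnorm(m, 0, neuron$jitter_sd)` if `NULL`.
#' @param noise If `FALSE`, the noiseless model trace is returned.
#' @param oversample Fine-grid samples per imaging frame (default 64, i.e.
#'   ~1 ms resolution at 15 Hz).
#' @return Object of class `fluorescence_trace`: list with `frame_times`
#'   (midpoints, s), `dff`, `frame_rate`, `noise_sd`, and the realized
#'   `jitters`. Draws from the current RNG stream.
#' @export
render_trace <- function(neuron, session, amplitudes, events = NULL,
                         secondary_amplitudes = NULL, jitters = NULL,
                         noise = TRUE, oversample = 64) {
  frame_rate <- session$config$frame_rate
  if (is.null(events))
    events <- cue_events(session, include = rep(TRUE, length(session$trials)))
  ev_p <- events[events$side == neuron$preferred_side, , drop = FALSE]
  stopifnot(length(amplitudes) == nrow(ev_p))
  tab <- impulse_response_table(neuron$kernel, neuron$calcium)
  frame_times <- session_frames(session, frame_rate)
  nf <- length(frame_times)
  dtf <- 1 / (frame_rate * oversample)
  nfine <- nf * oversample
  tfine_0 <- dtf / 2 # fine sample j is at (j - 0.5) * dtf

  ev_s <- NULL
  if (isTRUE(neuron$has_secondary)) {
    ev_s <- events[events$side != neuron$preferred_side, , drop = FALSE]
    if (is.null(secondary_amplitudes))
      stop("render_trace: secondary amplitudes required for has_secondary")
    stopifnot(length(secondary_amplitudes) == nrow(ev_s))
  }
  m_total <- nrow(ev_p) + if (is.null(ev_s)) 0L else nrow(ev_s)
  if (is.null(jitters)) jitters <- rnorm(m_total, 0, neuron$jitter_sd)
  stopifnot(length(jitters) == m_total)

  fine <- numeric(nfine)
  add_events <- function(ev, amps, jit) {
    shifts <- ev$t + neuron$kernel$tau_lag + jit
    for (i in seq_along(shifts)) {
      if (amps[i] == 0) next
      s <- shifts[i]
      i0 <- max(1L, ceiling((s + tab$t[1] - tfine_0) / dtf) + 1L)
      i1 <- min(nfine, floor((s + tab$t[length(tab$t)] - tfine_0) / dtf) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      tt <- tfine_0 + (idx - 1) * dtf - s
      fine[idx] <<- fine[idx] + amps[i] * interp0(tab$t, tab$g, tt)
    }
  }
  jp <- jitters[seq_len(nrow(ev_p))]
  add_events(ev_p, amplitudes, jp)
  if (!is.null(ev_s))
    add_events(ev_s, secondary_amplitudes, jitters[nrow(ev_p) + seq_len(nrow(ev_s))])

  dff <- colMeans(matrix(fine, nrow = oversample))
  if (noise && neuron$noise_sd > 0)
    dff <- dff + rnorm(nf, 0, neuron$noise_sd)
  structure(list(frame_times = frame_times, dff = dff,
                 frame_rate = frame_rate, noise_sd = neuron$noise_sd,
                 jitters = jitters), class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("fluorescence_trace: %d frames at %g Hz, noise sd %.3g\n",
              length(x$dff), x$frame_rate, x$noise_sd))
  invisible(x)
}

#' Population specification for the synthetic forward model
#'
#' Counts of cells per amplitude-modulation type plus non-cue-locked
#' distractors (slow per-trial ramps and place-field-like bumps, providing
#' true negatives for the cue-locking test), and shared generation settings.
#'
#' @param n_null,n_ssa,n_choice,n_counts Cell counts per modulation type.
#' @param n_distractor Number of distractor cells.
#' @param gamma_shape Gamma shape k of amplitude noise.
#' @param noise_frac Gaussian trace noise as a fraction of each cell's
#'   peak single-cue response (used when `noise_sd` is `NULL`).
#' @param noise_sd Absolute trace noise SD; overrides `noise_frac`.
#' @param jitter_sd SD of per-cue onset jitters, s.
#' @param prop_left Proportion of left-preferring cells.
#' @param ssa_xi,ssa_lambda SSA parameters for SSA-type cells.
#' @param speed_coef Linear speed coefficient for all cells.
#' @param count_coef Count-dependence slope for counts-type cells.
#' @param choice_gap Contra/ipsi mean gain separation for choice cells
#'   (gains `1 +/- choice_gap/2`, sign randomized per cell).
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_null = 5, n_ssa = 5, n_choice = 5,
                            n_counts = 5, n_distractor = 0, gamma_shape = 4,
                            noise_frac = 0.2, noise_sd = NULL,
                            jitter_sd = 0.05, prop_left = 0.5,
                            ssa_xi = 0.5, ssa_lambda = 0.8,
                            speed_coef = 0.3, count_coef = 0.06,
                            choice_gap = 0.4) {
  structure(as.list(environment()), class = "population_spec")
}

# distractor trace: slow within-trial profile vs y (ramp or bump), not
# locked to cues, plus frame noise
render_distractor <- function(session, kind = c("ramp", "bump"),
                              noise_sd = 0.1) {
  kind <- match.arg(kind)
  frame_times <- session_frames(session)
  dff <- numeric(length(frame_times))
  L <- maze_length(session$config)
  amp <- abs(rnorm(1, 0.6, 0.2)) + 0.2
  y0 <- runif(1, 0.2, 0.8) * L
  w <- runif(1, 0.08, 0.2) * L
  for (tr in session$trials) {
    sel <- which(frame_times >= tr$t_start &
                   frame_times <= tr$t_start + tr$duration)
    if (length(sel) == 0) next
    yf <- approx(tr$t_start + tr$traj$t, tr$traj$y, frame_times[sel],
                 rule = 2)$y
    dff[sel] <- if (kind == "ramp") amp * yf / L
                else amp * exp(-(yf - y0)^2 / (2 * w^2))
  }
  structure(list(frame_times = frame_times,
                 dff = dff + rnorm(length(dff), 0, noise_sd),
                 frame_rate = session$config$frame_rate, noise_sd = noise_sd,
                 jitters = numeric(0)), class = "fluorescence_trace")
}

#' Generate a synthetic neural population with ground truth
#'
#' Draws per-cell kernels and modulation parameters per the population
#' specification, samples ground-truth amplitudes, renders fluorescence
#' traces for every cell, and returns the complete ground truth for recovery
#' testing. Reproducible from `seed`.
#'
#' @param session A `session_log` with kinematics.
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @param render If `FALSE`, skip trace rendering and return ground-truth
#'   amplitudes only (fast path for stages that consume amplitudes
#'   directly).
#' @return List with `traces` (list of `fluorescence_trace`, or `NULL`s
#'   when `render = FALSE`), `neurons` (list of [ground_truth_neuron()]
#'   plus distractor stubs), and `truth`, a data frame with one row per
#'   (cell, preferred-side cue) holding the true mean `mu`, amplitude `A`,
#'   and jitter.
#' @export
generate_population <- function(session, spec, seed = 1L, render = TRUE) {
  with_seed(seed, {
    events <- cue_events(session, include = rep(TRUE, length(session$trials)))
    q <- quantile(events$v, c(0.1, 0.5, 0.9), names = FALSE)
    speed_q <- c(q10 = q[1], q50 = q[2], q90 = q[3])
    types <- c(rep("null", spec$n_null), rep("ssa", spec$n_ssa),
               rep("choice", spec$n_choice), rep("counts", spec$n_counts))
    n_cells <- length(types)
    traces <- vector("list", n_cells + spec$n_distractor)
    neurons <- vector("list", n_cells + spec$n_distractor)
    truth <- vector("list", n_cells)
    for (j in seq_len(n_cells)) {
      side <- if (runif(1) < spec$prop_left) "L" else "R"
      kern <- impulse_kernel(tau_lag = runif(1, 0.03, 0.2),
                             sigma_rise = runif(1, 0.05, 0.12),
                             sigma_fall = runif(1, 0.10, 0.25))
      rf <- default_rf(side, sigma = runif(1, 25, 45), zeta = runif(1, 0.05, 0.2))
      ev_side <- events[events$side == side, , drop = FALSE]
      mod <- switch(types[j],
        null = {
          # saturating speed tuning drawn in the null model's own family
          # (natural cubic spline at speed quantiles)
          vk <- quantile(ev_side$v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
          b <- runif(1, 0.7, 1.4)
          list(type = "null", rf = rf,
               v_knots = vk,
               v_values = 1 + b * c(-0.35, -0.15, 0, 0.15, 0.22),
               amp_scale = 1)
        },
        ssa = list(type = "ssa", rf = rf, speed_coef = spec$speed_coef,
                   xi = spec$ssa_xi, lambda = spec$ssa_lambda),
        choice = {
          s <- sample(c(-1, 1), 1) # positively or negatively choice-modulated
          pref_gain <- 1 + s * spec$choice_gap / 2
          anti_gain <- 1 - s * spec$choice_gap / 2
          gains <- if (side == "R") c(R = pref_gain, L = anti_gain)
                   else c(R = anti_gain, L = pref_gain)
          slopes <- if (side == "R") c(R = s * 0.4, L = -s * 0.4)
                    else c(R = -s * 0.4, L = s * 0.4)
          list(type = "choice", rf = rf, speed_coef = spec$speed_coef,
               gain = gains, slope = slopes, amp_scale = 1,
               L_pre = session$config$L_pre, L_cue = session$config$L_cue)
        },
        counts = list(type = "counts", rf = rf, speed_coef = spec$speed_coef,
                      count_coef = spec$count_coef, amp_scale = 1))
      ev_p <- events[events$side == side, , drop = FALSE]
      nrn <- ground_truth_neuron(preferred_side = side, kernel = kern,
                                 modulation = mod,
                                 gamma_shape = spec$gamma_shape,
                                 noise_sd = 0, jitter_sd = spec$jitter_sd)
      if (is.null(spec$noise_sd)) {
        gpk <- max(impulse_response_table(kern, nrn$calcium)$g)
        nrn$noise_sd <- spec$noise_frac * gpk
      } else nrn$noise_sd <- spec$noise_sd
      samp <- sample_amplitudes(nrn, ev_p, speed_q)
      jit <- rnorm(nrow(ev_p), 0, spec$jitter_sd)
      if (render)
        traces[[j]] <- render_trace(nrn, session, samp$amplitudes,
                                    events = events, jitters = jit)
      neurons[[j]] <- nrn
      truth[[j]] <- data.frame(cell_id = j, type = types[j], side = side,
                               trial_id = ev_p$trial_id,
                               cue_index = ev_p$cue_index, t = ev_p$t,
                               mu = samp$mu, A = samp$amplitudes,
                               jitter = jit, stringsAsFactors = FALSE)
    }
    for (j in seq_len(spec$n_distractor)) {
      kind <- if (j %% 2 == 1) "ramp" else "bump"
      if (render) traces[[n_cells + j]] <- render_distractor(session, kind)
      neurons[[n_cells + j]] <- list(type = "distractor", kind = kind)
    }
    types_all <- c(types, rep("distractor", spec$n_distractor))
    list(traces = traces, neurons = neurons,
         truth = do.call(rbind, truth), types = types_all,
         speed_q = speed_q, seed = as.integer(seed))
  })
}
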