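#' Draw cue positions for one trial
#'
#' Per-side cue counts are Poisson with the configured majority/minority
#' means (majority on the rewarded side); positions are uniform over the cue
#' region conditional on consecutive same-side cues being at least
#' `refractory` cm apart. The constrained uniform sample is drawn exactly by
#' the order-statistics gap construction, which is distributionally identical
#' to rejection sampling at fixed counts.
#'
#' @param config A [maze_config()].
#' @param rewarded_side `"R"` or `"L"`; receives the majority mean.
#' @return List with numeric vectors `R` and `L` of absolute cue positions
#'   (cm from maze start, cue region spans `[L_pre, L_pre + L_cue]`), sorted
#'   ascending. Draws from the current RNG stream.
#' @export
place_cues <- function(config, rewarded_side = c("R", "L")) {
  rewarded_side <- match.arg(rewarded_side)
  n_max <- floor(config$L_cue / config$refractory) + 1L
  if (config$mean_count_majority * config$refractory > config$L_cue)
    stop("place_cues: mean cue count unplaceable under the refractory constraint")
  rpois_placeable <- function(lambda) {
    # redraw the (very rare) counts whose spacing cannot fit in the region,
    # i.e. a Poisson truncated at the geometric maximum
    repeat {
      n <- rpois(1, lambda)
      if (n <= n_max) return(n)
    }
  }
  n_maj <- rpois_placeable(config$mean_count_majority)
  n_min <- rpois_placeable(config$mean_count_minority)
  draw <- function(n) {
    if (n == 0) return(numeric(0))
    slack <- config$L_cue - (n - 1) * config$refractory
    config$L_pre + sort(runif(n, 0, slack)) + config$refractory * (0:(n - 1))
  }
  pos_maj <- draw(n_maj)
  pos_min <- draw(n_min)
  if (rewarded_side == "R") list(R = pos_maj, L = pos_min)
  else list(R = pos_min, L = pos_maj)
}

#' Simulate running kinematics for one trial
#'
#' Speed is a mean-reverting (AR(1)/Ornstein-Uhlenbeck) positive process
#' around `speed_mean` with stationary SD `speed_sd`; position integrates
#' speed from 0 to the T-arm entry. The view angle is smoothed noise during
#' the corridor plus a ramp toward the chosen arm over the second half of the
#' delay region; in theta-controlled sessions it is exactly zero until midway
#' through the delay region.
#'
#' @param config A [maze_config()].
#' @param agent An [agent_params()].
#' @param choice `"R"` or `"L"`; direction of the final view-angle ramp.
#' @return List with vectors `t` (s), `y` (cm), `v` (cm/s), `theta`
#'   (degrees), sampled at the display rate. Draws from the current RNG.
#' @export
simulate_kinematics <- function(config, agent, choice = "R") {
  dt <- 1 / config$display_rate
  L <- maze_length(config)
  v_floor <- max(1, 0.05 * agent$speed_mean)
  tau_v <- 0.5 # mean-reversion timescale, s
  a <- exp(-dt / tau_v)
  n_guess <- ceiling(L / (agent$speed_mean * dt) * 2) + 8L
  v <- numeric(0); y <- numeric(0)
  y_last <- 0; v_last <- NA
  while (y_last < L) {
    if (agent$speed_sd > 0) {
      innov <- rnorm(n_guess, 0, agent$speed_sd * sqrt(1 - a^2))
      init <- if (is.na(v_last)) rnorm(1, 0, agent$speed_sd) else v_last - agent$speed_mean
      dev <- as.numeric(filter(innov, a, method = "recursive", init = init))
      v_new <- pmax(agent$speed_mean + dev, v_floor)
    } else {
      v_new <- rep(agent$speed_mean, n_guess)
    }
    y_new <- y_last + cumsum(v_new) * dt
    v <- c(v, v_new); y <- c(y, y_new)
    y_last <- y[length(y)]; v_last <- v[length(v)] - agent$speed_mean
  }
  end <- which(y >= L)[1]
  v <- v[seq_len(end)]; y <- y[seq_len(end)]
  t <- seq_along(y) * dt
  n <- length(t)

  theta_max <- if (choice == "R") 60 else -60
  y_ramp0 <- config$L_pre + config$L_cue + config$L_delay / 2
  ramp <- pmax(0, (y - y_ramp0) / (L - y_ramp0)) * theta_max
  if (config$theta_controlled || agent$theta_noise_sd == 0) {
    theta <- ramp
  } else {
    b <- exp(-dt / 1.0) # ~1 s smoothing of view-angle wander
    noise <- as.numeric(filter(rnorm(n, 0, agent$theta_noise_sd * sqrt(1 - b^2)),
                               b, method = "recursive",
                               init = rnorm(1, 0, agent$theta_noise_sd)))
    w <- pmin(1, pmax(0, (y - y_ramp0) / (0.25 * config$L_delay)))
    theta <- noise * (1 - w) + ramp
  }
  list(t = t, y = y, v = v, theta = theta)
}

#' Detect cue onset/offset times and visual angles from a trajectory
#'
#' A cue turns on at the first display frame at which the subject is within
#' `visibility_distance` of the cue's maze position, and off `cue_duration`
#' ms later. The visual angle `phi` is the signed angle (positive rightward)
#' from the instantaneous heading to the cue center, located
#' `lateral_offset` cm off-axis at the cue position.
#'
#' @param traj Kinematics list from [simulate_kinematics()].
#' @param cues List with per-side position vectors as from [place_cues()].
#' @param config A [maze_config()].
#' @return Data frame with one row per cue, sorted by onset time: `side`,
#'   `y` (cue position), `t_on`, `t_off` (s from trial start), `phi`
#'   (degrees), `v_on`, `theta_on`, `y_on`, `seen`. Cues never reached are
#'   flagged `seen = FALSE` with `NA` timings.
#' @export
detect_cue_onsets <- function(traj, cues, config) {
  one_side <- function(pos, side) {
    if (length(pos) == 0) return(NULL)
    dx <- if (side == "R") config$lateral_offset else -config$lateral_offset
    idx <- vapply(pos, function(p) {
      j <- which(traj$y >= p - config$visibility_distance)[1]
      if (is.na(j)) NA_integer_ else j
    }, integer(1))
    seen <- !is.na(idx)
    t_on <- ifelse(seen, traj$t[idx], NA_real_)
    v_on <- ifelse(seen, traj$v[idx], NA_real_)
    th_on <- ifelse(seen, traj$theta[idx], NA_real_)
    y_on <- ifelse(seen, traj$y[idx], NA_real_)
    dy <- pos - y_on
    phi <- atan2(dx, dy) * 180 / pi - th_on
    data.frame(side = side, y = pos, t_on = t_on,
               t_off = t_on + config$cue_duration / 1000,
               phi = phi, v_on = v_on, theta_on = th_on, y_on = y_on,
               seen = seen, stringsAsFactors = FALSE)
  }
  out <- rbind(one_side(cues$R, "R"), one_side(cues$L, "L"))
  if (is.null(out)) {
    out <- data.frame(side = character(0), y = numeric(0), t_on = numeric(0),
                      t_off = numeric(0), phi = numeric(0), v_on = numeric(0),
                      theta_on = numeric(0), y_on = numeric(0),
                      seen = logical(0), stringsAsFactors = FALSE)
  }
  out <- out[order(!out$seen, out$t_on, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-third evidence differences (#R - #L) from cue positions
evidence_by_third <- function(cues, config) {
  third <- function(pos) {
    if (length(pos) == 0) return(integer(3))
    i <- pmin(3, pmax(1, ceiling((pos - config$L_pre) / (config$L_cue / 3))))
    tabulate(i, nbins = 3)
  }
  third(cues$R) - third(cues$L)
}

#' Simulate the agent's choice for one trial
#'
#' The probability of a rightward choice is a lapse-mixed logistic of the
#' weighted per-third evidence plus the side bias:
#' `P(R) = lapse + (1 - 2 lapse) * plogis(sum(w_i * Delta_i) + bias)`.
#'
#' @param cues Per-side cue position list as from [place_cues()].
#' @param agent An [agent_params()].
#' @param config A [maze_config()].
#' @return `"R"` or `"L"`. Draws from the current RNG stream.
#' @export
simulate_choice <- function(cues, agent, config) {
  delta <- evidence_by_third(cues, config)
  x <- sum(agent$evidence_weights * delta) + agent$side_bias
  p_right <- agent$lapse_rate + (1 - 2 * agent$lapse_rate) * plogis(x)
  if (runif(1) < p_right) "R" else "L"
}

#' Running evidence tally within a trial
#'
#' Counts of right and left cues with onset at or before `t`, and their
#' difference `Delta = #R - #L` (the running tally of evidence).
#'
#' @param trial A trial record from [generate_session()] (with detected
#'   onsets), or any data frame with `side`, `t_on`, `seen` columns.
#' @param t Time point(s) within the trial, s.
#' @return Data frame with columns `t`, `n_right`, `n_left`, `delta`.
#' @export
running_evidence <- function(trial, t) {
  cues <- if (is.data.frame(trial)) trial else trial$cues
  cues <- cues[cues$seen, , drop = FALSE]
  nr <- vapply(t, function(tt) sum(cues$side == "R" & cues$t_on <= tt), numeric(1))
  nl <- vapply(t, function(tt) sum(cues$side == "L" & cues$t_on <= tt), numeric(1))
  data.frame(t = t, n_right = nr, n_left = nl, delta = nr - nl)
}

# de-biasing of rewarded-side sampling: probability of drawing a
# right-rewarded trial next, from per-side error rates in a trailing window
# (Laplace-smoothed). Sides with more errors are sampled more.
debias_probability <- function(rewarded, correct, window = 40) {
  n <- length(rewarded)
  if (n == 0) return(0.5)
  keep <- max(1, n - window + 1):n
  rw <- rewarded[keep]; cr <- correct[keep]
  err_r <- (sum(rw == "R" & !cr) + 1) / (sum(rw == "R") + 2)
  err_l <- (sum(rw == "L" & !cr) + 1) / (sum(rw == "L") + 2)
  err_r / (err_r + err_l)
}

#' Generate a complete synthetic behavioral session
#'
#' Draws rewarded sides with error-rate de-biasing, places cues, simulates
#' the agent's choice and (optionally) running kinematics, detects cue
#' onsets, and applies the trial-inclusion filters. Fully reproducible from
#' `seed`.
#'
#' @param config A [maze_config()].
#' @param agent An [agent_params()].
#' @param n_trials Number of trials (> 0).
#' @param seed Integer seed; recorded in the session.
#' @param kinematics If `FALSE`, only cue positions, choices and outcomes are
#'   generated (fast path for large-scale cue statistics); trajectories and
#'   onset timings are omitted and all trials are marked included.
#' @return An object of class `session_log`: list with `config`, `agent`,
#'   `seed`, `trials` (list of per-trial records), and `included` (logical
#'   mask from [filter_trials()]). Each trial record carries `trial_id`,
#'   `rewarded_side`, `cues` (onset table), `choice`, `correct`, `duration`,
#'   `iti`, `t_start` (session clock, s), `prev_choice`, `prev_reward`, and
#'   `traj`.
#' @export
generate_session <- function(config, agent, n_trials, seed = 1L,
                             kinematics = TRUE) {
  stopifnot(n_trials > 0)
  with_seed(seed, {
    trials <- vector("list", n_trials)
    rewarded <- character(0); correct_hist <- logical(0)
    t_start <- 0
    prev_choice <- NA_character_; prev_reward <- NA
    for (k in seq_len(n_trials)) {
      p_r <- debias_probability(rewarded, correct_hist)
      side <- if (runif(1) < p_r) "R" else "L"
      cues <- place_cues(config, side)
      choice <- simulate_choice(cues, agent, config)
      correct <- (choice == side)
      if (kinematics) {
        traj <- simulate_kinematics(config, agent, choice)
        onsets <- detect_cue_onsets(traj, cues, config)
        duration <- traj$t[length(traj$t)]
      } else {
        traj <- NULL
        onsets <- data.frame(side = c(rep("R", length(cues$R)),
                                      rep("L", length(cues$L))),
                             y = c(cues$R, cues$L), stringsAsFactors = FALSE)
        duration <- maze_length(config) / agent$speed_mean
      }
      iti <- config$iti_correct + if (correct) 0 else config$iti_error_extra
      trials[[k]] <- list(trial_id = k, rewarded_side = side, cues = onsets,
                          choice = choice, correct = correct,
                          duration = duration, iti = iti, t_start = t_start,
                          prev_choice = prev_choice, prev_reward = prev_reward,
                          traj = traj)
      t_start <- t_start + duration + iti
      rewarded <- c(rewarded, side); correct_hist <- c(correct_hist, correct)
      prev_choice <- choice; prev_reward <- correct
    }
    session <- structure(list(config = config, agent = agent,
                              seed = as.integer(seed), trials = trials),
                         class = "session_log")
    session$included <- filter_trials(session)
    session
  })
}

#' @export
print.session_log <- function(x, ...) {
  acc <- mean(vapply(x$trials, `[[`, logical(1), "correct"))
  cat(sprintf("session_log: %d trials (%d included), accuracy %.1f%%, seed %d\n",
              length(x$trials), sum(x$included), 100 * acc, x$seed))
  invisible(x)
}

#' Trial-inclusion filter
#'
#' Excludes trials with any backtracking displacement of -0.2 cm or more
#' negative between consecutive behavioral iterations (up to the T-arm
#' entry), and trials whose duration (excluding the inter-trial interval)
#' differs from the session median by more than 50%.
#'
#' @param session A `session_log`.
#' @return Logical inclusion mask, one entry per trial.
#' @export
filter_trials <- function(session) {
  durations <- vapply(session$trials, `[[`, numeric(1), "duration")
  med <- median(durations)
  vapply(session$trials, function(tr) {
    if (!is.null(tr$traj) && length(tr$traj$y) > 1 &&
        any(diff(tr$traj$y) <= -0.2)) return(FALSE)
    abs(tr$duration - med) <= 0.5 * med
  }, logical(1))
}

#' Per-cue event table for a session
#'
#' Flattens a session into one row per seen cue on included trials, on the
#' session clock, carrying the behavioral context used by the impulse-fit,
#' amplitude-model and decoding stages.
#'
#' @param session A `session_log` generated with kinematics.
#' @param include Logical trial mask; defaults to the session's stored mask.
#' @return Data frame with columns `trial_id`, `cue_index` (onset order
#'   within trial), `side`, `t` (session clock, s), `t_trial` (s from trial
#'   start), `y`, `phi`, `v`, `theta`, `delta` (running #R - #L including
#'   the current cue), `choice`, `correct`, `prev_choice`, `prev_reward`.
#' @export
cue_events <- function(session, include = session$included) {
  rows <- lapply(session$trials[include], function(tr) {
    cues <- tr$cues[tr$cues$seen, , drop = FALSE]
    if (nrow(cues) == 0) return(NULL)
    cues <- cues[order(cues$t_on), , drop = FALSE]
    delta <- cumsum(ifelse(cues$side == "R", 1, -1))
    data.frame(trial_id = tr$trial_id, cue_index = seq_len(nrow(cues)),
               side = cues$side, t = tr$t_start + cues$t_on,
               t_trial = cues$t_on, y = cues$y, phi = cues$phi,
               v = cues$v_on, theta = cues$theta_on, delta = delta,
               choice = tr$choice, correct = tr$correct,
               prev_choice = if (is.na(tr$prev_choice)) NA_character_ else tr$prev_choice,
               prev_reward = tr$prev_reward, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("cue_events: no seen cues on included trials")
  rownames(out) <- NULL
  out
}

# per-trial fit/search windows on the session clock: trial span plus a pad
# for the response tail, and the cue-region traversal interval (for shuffles)
trial_windows <- function(session, include = session$included, pad = 2) {
  tr <- session$trials[include]
  data.frame(
    trial_id = vapply(tr, `[[`, numeric(1), "trial_id"),
    t0 = vapply(tr, `[[`, numeric(1), "t_start"),
    t1 = vapply(tr, function(x) x$t_start + x$duration + pad, numeric(1)),
    cue0 = vapply(tr, function(x) {
      j <- which(x$traj$y >= session$config$L_pre)[1]
      x$t_start + x$traj$t[j]
    }, numeric(1)),
    cue1 = vapply(tr, function(x) {
      j <- which(x$traj$y >= session$config$L_pre + session$config$L_cue)[1]
      if (is.na(j)) j <- length(x$traj$t)
      x$t_start + x$traj$t[j]
    }, numeric(1))
  )
}
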