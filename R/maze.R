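#' Maze configuration for the virtual T-maze task
#'
#' Geometry, cue statistics and timing constants of the Accumulating-Towers
#' style task: a pre-cue corridor, a cue region where tower cues appear along
#' both walls, and a cue-free delay region ending at the T-arm. Cue locations
#' are drawn per trial from a spatial Poisson process with a same-side
#' refractory period; a cue becomes visible when the subject approaches
#' within `visibility_distance` of its location and vanishes after
#' `cue_duration`.
#'
#' @param L_pre Pre-cue corridor length, cm.
#' @param L_cue Cue-region length, cm (200 for the standard maze, 250 for the
#'   long variant).
#' @param L_delay Delay-region length, cm.
#' @param refractory Minimum spacing between consecutive same-side cues, cm.
#' @param visibility_distance Approach distance at which a cue turns on, cm.
#' @param lateral_offset Lateral distance of the cue center from the maze
#'   axis, cm.
#' @param cue_duration Cue visibility duration, ms.
#' @param mean_count_majority,mean_count_minority Poisson means of per-trial
#'   cue counts on the rewarded (majority) and opposite (minority) walls.
#'   Defaults 7.7:2.3 for the 200 cm maze; use 8.5:2.5 with `L_cue = 250`.
#' @param display_rate Virtual-reality display refresh rate, Hz.
#' @param frame_rate Imaging frame rate, Hz.
#' @param iti_correct Inter-trial interval after correct trials, s.
#' @param iti_error_extra Additional time-out after error trials, s.
#' @param theta_controlled Logical; if `TRUE`, the view angle is clamped to
#'   zero until midway through the delay region.
#' @return An object of class `maze_config`.
#' @export
maze_config <- function(L_pre = 30, L_cue = 200, L_delay = 100,
                        refractory = 12, visibility_distance = 10,
                        lateral_offset = 4, cue_duration = 200,
                        mean_count_majority = 7.7, mean_count_minority = 2.3,
                        display_rate = 85, frame_rate = 15,
                        iti_correct = 3, iti_error_extra = 9,
                        theta_controlled = FALSE) {
  cfg <- list(L_pre = L_pre, L_cue = L_cue, L_delay = L_delay,
              refractory = refractory,
              visibility_distance = visibility_distance,
              lateral_offset = lateral_offset, cue_duration = cue_duration,
              mean_count_majority = mean_count_majority,
              mean_count_minority = mean_count_minority,
              display_rate = display_rate, frame_rate = frame_rate,
              iti_correct = iti_correct, iti_error_extra = iti_error_extra,
              theta_controlled = isTRUE(theta_controlled))
  lens <- c(cfg$L_pre, cfg$L_cue, cfg$L_delay, cfg$refractory,
            cfg$visibility_distance, cfg$display_rate, cfg$frame_rate)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("maze_config: all lengths and rates must be positive")
  if (cfg$refractory >= cfg$L_cue)
    stop("maze_config: refractory period must be smaller than the cue region")
  if (cfg$mean_count_majority <= cfg$mean_count_minority)
    stop("maze_config: majority mean count must exceed the minority mean")
  if (cfg$mean_count_minority < 0) stop("maze_config: negative mean count")
  structure(cfg, class = "maze_config")
}

#' Behavioral agent parameters for the synthetic task
#'
#' A logistic evidence-integrating agent with a small primacy effect (larger
#' weight on early cue-region thirds by default), a lapse rate, a side bias,
#' and simple locomotion statistics. Only the summary statistics of the
#' kinematics (speed scale, view-angle spread) matter downstream.
#'
#' @param evidence_weights Length-3 weights on the per-third evidence
#'   difference (#R - #L); the default decreasing profile gives primacy.
#' @param lapse_rate Probability mass of evidence-independent choices, in
#'   `[0, 0.5)`. `P(right) = lapse + (1 - 2 lapse) * plogis(x)`.
#' @param side_bias Additive log-odds bias toward rightward choices.
#' @param speed_mean,speed_sd Mean and stationary SD of running speed, cm/s.
#' @param theta_noise_sd SD of view-angle wander, degrees (ignored in
#'   theta-controlled sessions).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(evidence_weights = c(0.55, 0.45, 0.35),
                         lapse_rate = 0.1, side_bias = 0,
                         speed_mean = 60, speed_sd = 6,
                         theta_noise_sd = 4) {
  stopifnot(length(evidence_weights) == 3, all(is.finite(evidence_weights)),
            lapse_rate >= 0, lapse_rate < 0.5, is.finite(side_bias),
            speed_mean > 0, speed_sd >= 0, theta_noise_sd >= 0)
  structure(list(evidence_weights = evidence_weights,
                 lapse_rate = lapse_rate, side_bias = side_bias,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 theta_noise_sd = theta_noise_sd),
            class = "agent_params")
}

#' @export
print.maze_config <- function(x, ...) {
  cat(sprintf("T-maze: %g + %g + %g cm; cues %g:%g (refractory %g cm)%s\n",
              x$L_pre, x$L_cue, x$L_delay, x$mean_count_majority,
              x$mean_count_minority, x$refractory,
              if (x$theta_controlled) "; theta-controlled" else ""))
  invisible(x)
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("agent: weights [%s], lapse %g, bias %g, speed %g+/-%g cm/s\n",
              paste(signif(x$evidence_weights, 3), collapse = ", "),
              x$lapse_rate, x$side_bias, x$speed_mean, x$speed_sd))
  invisible(x)
}

# total corridor length up to the T-arm entry
maze_length <- function(config) config$L_pre + config$L_cue + config$L_delay
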