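#' Evaluate an angular receptive field function
#'
#' Two parametric families for the dependence of cue-response amplitude on
#' the cue's visual angle phi (degrees, positive rightward of heading):
#'
#' * `skew_gaussian`: `exp(-(phi - phi0)^2 / (2 * (sigma + zeta*(phi - phi0))^2))
#'   - exp(-1/zeta^2)`, an asymmetric bump whose width grows linearly away
#'   from the peak; where the width term `sigma + zeta*(phi - phi0)` crosses
#'   zero the expression is undefined and the field is clipped to its limit 0
#'   (and kept at 0 beyond the crossing).
#' * `sigmoid`: `1 - rho0/2 + rho0 / (1 + exp(-(phi - phi0)/zeta))^nu`, a
#'   saturating monotone dependence with finite asymptotes.
#'
#' With `zeta = 0` the skew form degenerates to a symmetric Gaussian (offset
#' term 0).
#'
#' @param rf List with `form` (`"skew_gaussian"` or `"sigmoid"`) and the
#'   relevant parameters `phi0`, `sigma`, `zeta`, `rho0`, `nu` (degrees for
#'   angles).
#' @param phi Visual angle(s), degrees.
#' @return Receptive-field values (unitless gain).
#' @export
angular_rf_eval <- function(rf, phi) {
  d <- phi - rf$phi0
  if (rf$form == "skew_gaussian") {
    z <- rf$zeta
    if (z == 0) return(exp(-d^2 / (2 * rf$sigma^2)))
    w <- rf$sigma + z * d
    out <- exp(-d^2 / (2 * w^2)) - exp(-1 / z^2)
    # beyond the width zero-crossing (w <= 0) the printed form is undefined;
    # clip to the limiting value 0
    bad <- w <= 0
    out[bad] <- 0
    pmax(out, 0)
  } else if (rf$form == "sigmoid") {
    1 - rf$rho0 / 2 + rf$rho0 * (1 + exp(-d / rf$zeta))^(-rf$nu)
  } else stop("angular_rf_eval: unknown form ", rf$form)
}

#' Standardize running speed by quantiles
#'
#' `v_tilde = (v - Q50) / (Q90 - Q10)`, so the median maps to 0 and the
#' 10-90% spread to 1.
#'
#' @param v Speeds, cm/s.
#' @param q10,q50,q90 Speed quantiles, cm/s.
#' @return Standardized speeds.
#' @export
standardize_speed <- function(v, q10, q50, q90) {
  if (q90 <= q10) stop("standardize_speed: Q90 must exceed Q10")
  (v - q50) / (q90 - q10)
}

#' Natural cubic spline through control points
#'
#' Piecewise third-order polynomial through the control values with natural
#' boundary conditions; evaluations beyond the control range extrapolate
#' linearly along the end segments.
#'
#' @param control_x Strictly increasing control abscissae (>= 3 points).
#' @param control_values Values at the control points.
#' @param x Evaluation points.
#' @return Spline values at `x`.
#' @export
spline_eval <- function(control_x, control_values, x) {
  if (anyDuplicated(control_x)) stop("spline_eval: duplicate control points")
  if (is.unsorted(control_x)) stop("spline_eval: control points must be increasing")
  if (length(control_x) < 3) stop("spline_eval: need >= 3 control points")
  f <- splinefun(control_x, control_values, method = "natural")
  f(x)
}

#' Stimulus-specific adaptation recursion for mean amplitudes
#'
#' Sequential gain for SSA/enhancement with exponential recovery:
#' `h[mu_(i-1), dt] = 1 + (xi * mu_(i-1) - 1) * exp(-dt / lambda)`, where
#' `xi > 1` is facilitation and `xi < 1` depression, recovering toward 1
#' between cues. The mean for cue i is `mu_i = base_i * h(mu_(i-1), t_i -
#' t_(i-1))`; the first cue of the session is fixed at `mu_1 = 1` by
#' convention, regardless of its base mean.
#'
#' @param onset_times Sorted ascending cue onset times, s (session clock).
#' @param base_means Per-cue base means (receptive field x speed factors).
#' @param xi Adaptation/facilitation scale factor (> 0).
#' @param lam Recovery timescale, s (> 0).
#' @param variant `"literal"` feeds the full previous mean (including
#'   receptive-field and speed factors) into `h`, with the first mean fixed
#'   at 1, exactly as printed. `"state"` tracks a dimensionless adaptation
#'   state through the same recursion and multiplies it onto the base means,
#'   so `xi = 1` leaves the means exactly at their base values.
#' @return Vector of means `mu_i`, same length as `onset_times`.
#' @export
ssa_mean_sequence <- function(onset_times, base_means, xi, lam,
                              variant = c("literal", "state")) {
  variant <- match.arg(variant)
  stopifnot(length(onset_times) == length(base_means), xi > 0, lam > 0)
  n <- length(onset_times)
  if (n == 0) return(numeric(0))
  if (is.unsorted(onset_times)) stop("ssa_mean_sequence: onsets must be sorted")
  mu <- numeric(n)
  if (n > 1) decay <- exp(-diff(onset_times) / lam)
  if (variant == "literal") {
    mu[1] <- 1
    for (i in seq_len(n)[-1]) {
      h <- 1 + (xi * mu[i - 1] - 1) * decay[i - 1]
      mu[i] <- base_means[i] * h
    }
  } else {
    a <- 1
    mu[1] <- base_means[1]
    for (i in seq_len(n)[-1]) {
      a <- 1 + (xi * a - 1) * decay[i - 1]
      mu[i] <- base_means[i] * a
    }
  }
  mu
}

#' Gamma negative log-likelihood in mean parameterization
#'
#' Exact negative log-density of the Gamma distribution with shape `k` and
#' mean `mu` (scale `mu/k`), summed over observations:
#' `sum((1 - k) log A + k A / mu + k log mu - k log k + log Gamma(k))`.
#'
#' @param amplitudes Positive observations.
#' @param means Positive means, recycled to the length of `amplitudes`.
#' @param k Gamma shape (> 0).
#' @return Scalar negative log-likelihood.
#' @export
gamma_negloglik <- function(amplitudes, means, k) {
  if (any(amplitudes <= 0)) stop("gamma_negloglik: amplitudes must be positive")
  if (any(means <= 0)) stop("gamma_negloglik: means must be positive")
  if (k <= 0) stop("gamma_negloglik: shape must be positive")
  means <- rep_len(means, length(amplitudes))
  sum((1 - k) * log(amplitudes) + k * amplitudes / means + k * log(means) -
        k * log(k) + lgamma(k))
}
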