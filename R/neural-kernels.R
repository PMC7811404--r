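#' Calcium indicator response kernel
#'
#' Difference-of-exponentials kernel for a GCaMP6f-like indicator,
#' `h(t) = (1 - exp(-t/tau_on)) * exp(-t/tau_off) / h0`, normalized so its
#' peak is exactly 1. The analytic argmax is
#' `t* = tau_on * log((tau_on + tau_off)/tau_on)`.
#'
#' @param tau_on Rise time constant, s (default 0.035).
#' @param tau_off Decay time constant, s (default 0.300).
#' @return Object of class `calcium_kernel` with fields `tau_on`, `tau_off`,
#'   `h0` (normalization), `t_peak`.
#' @export
calcium_kernel <- function(tau_on = 0.035, tau_off = 0.300) {
  if (tau_on <= 0 || tau_off <= 0)
    stop("calcium_kernel: time constants must be positive")
  if (tau_on >= tau_off)
    stop("calcium_kernel: tau_on must be smaller than tau_off")
  t_peak <- tau_on * log((tau_on + tau_off) / tau_on)
  h0 <- (1 - exp(-t_peak / tau_on)) * exp(-t_peak / tau_off)
  structure(list(tau_on = tau_on, tau_off = tau_off, h0 = h0,
                 t_peak = t_peak), class = "calcium_kernel")
}

#' Evaluate the normalized calcium kernel
#'
#' @param kernel A [calcium_kernel()].
#' @param t Times in s; the kernel is 0 for `t < 0`.
#' @return Unitless response values with maximum 1 at the analytic argmax.
#' @export
calcium_kernel_eval <- function(kernel, t) {
  out <- numeric(length(t))
  p <- t >= 0
  out[p] <- (1 - exp(-t[p] / kernel$tau_on)) * exp(-t[p] / kernel$tau_off) /
    kernel$h0
  out
}

#' Impulse-response kernel parameters for one neuron
#'
#' The per-cue response shape is a two-sided Gaussian (rise SD `sigma_rise`
#' before the peak, fall SD `sigma_fall` after, continuous at 0, with
#' prefactor `2 / (sqrt(pi) * (sigma_rise + sigma_fall))`) convolved with the
#' calcium indicator kernel, and shifted by the response lag `tau_lag`.
#'
#' @param tau_lag Response lag, s (>= 0).
#' @param sigma_rise,sigma_fall Rise/fall SDs of the two-sided Gaussian, s.
#' @return Object of class `impulse_kernel`.
#' @export
impulse_kernel <- function(tau_lag = 0.1, sigma_rise = 0.08,
                           sigma_fall = 0.15) {
  if (sigma_rise <= 0 || sigma_fall <= 0)
    stop("impulse_kernel: sigma_rise and sigma_fall must be positive")
  if (tau_lag < 0) stop("impulse_kernel: tau_lag must be non-negative")
  structure(list(tau_lag = tau_lag, sigma_rise = sigma_rise,
                 sigma_fall = sigma_fall), class = "impulse_kernel")
}

# two-sided Gaussian (pre-convolution response shape), peak at t = 0
two_sided_gaussian <- function(kernel, t) {
  c0 <- 2 / (sqrt(pi) * (kernel$sigma_rise + kernel$sigma_fall))
  ifelse(t < 0, c0 * exp(-t^2 / (2 * kernel$sigma_rise^2)),
         c0 * exp(-t^2 / (2 * kernel$sigma_fall^2)))
}

#' Evaluate the full impulse response (two-sided Gaussian x calcium kernel)
#'
#' Discrete convolution of the two-sided Gaussian response shape with the
#' normalized calcium kernel, computed on an internal fine grid and linearly
#' interpolated onto `t`. The response is expressed relative to the cue time
#' excluding the lag (apply `tau_lag` as a shift of the evaluation times).
#'
#' @param kernel An [impulse_kernel()].
#' @param calcium A [calcium_kernel()].
#' @param t Evaluation times, s (relative to cue onset + lag).
#' @param dt Internal grid resolution, s. A warning is given (and the grid
#'   refined) if `dt` is coarse relative to `sigma_rise`.
#' @return Numeric vector of kernel values at `t`.
#' @export
impulse_response_eval <- function(kernel, calcium, t, dt = 1 / 960) {
  if (dt > kernel$sigma_rise / 2) {
    warning("impulse_response_eval: grid coarse relative to sigma_rise; oversampling")
    dt <- kernel$sigma_rise / 4
  }
  tab <- impulse_response_table(kernel, calcium, dt = dt)
  interp0(tab$t, tab$g, t)
}

# tabulated impulse response on a uniform fine grid, reused on hot paths.
# support chosen to cover >4 rise SDs before and the calcium tail after.
impulse_response_table <- function(kernel, calcium, dt = 1 / 960,
                                   t_min = NULL, t_max = 3.0) {
  if (is.null(t_min)) t_min <- -max(0.8, 4.5 * kernel$sigma_rise)
  tb <- seq(t_min, t_max, by = dt)
  b <- two_sided_gaussian(kernel, tb)
  tc <- seq(0, t_max, by = dt)
  ca <- calcium_kernel_eval(calcium, tc)
  # full discrete convolution; result grid starts at tb[1] + tc[1] = t_min
  g <- conv_open(b, ca) * dt
  tg <- tb[1] + (seq_along(g) - 1) * dt
  keep <- tg <= t_max
  list(t = tg[keep], g = g[keep], dt = dt)
}

#' Ground-truth neuron specification for the forward model
#'
#' Bundles everything needed to synthesize one cell's fluorescence trace:
#' its preferred cue side, impulse and calcium kernels, amplitude-modulation
#' model with parameters, Gamma shape, noise level, and onset-jitter scale.
#'
#' @param preferred_side `"R"` or `"L"`.
#' @param kernel An [impulse_kernel()].
#' @param calcium A [calcium_kernel()].
#' @param modulation List describing the amplitude model: `type` one of
#'   `"null"`, `"ssa"`, `"choice"`, `"counts"` plus type-specific parameters
#'   (see [true_mean_amplitudes()]).
#' @param gamma_shape Gamma shape k (> 0); for the choice model a named
#'   vector `c(R = , L = )` of per-choice shapes is accepted.
#' @param noise_sd Gaussian noise SD on the 15 Hz trace, dF/F units.
#' @param jitter_sd SD of per-cue onset jitters, s.
#' @param has_secondary If `TRUE`, the neuron also responds (weakly) to
#'   opposite-side cues.
#' @param secondary_scale Mean amplitude of secondary responses relative to
#'   the primary mean.
#' @return Object of class `ground_truth_neuron`.
#' @export
ground_truth_neuron <- function(preferred_side = "R",
                                kernel = impulse_kernel(),
                                calcium = calcium_kernel(),
                                modulation = list(type = "null",
                                                  rf = default_rf(preferred_side),
                                                  speed_coef = 0.3),
                                gamma_shape = 4, noise_sd = 0.1,
                                jitter_sd = 0.05, has_secondary = FALSE,
                                secondary_scale = 0.3) {
  stopifnot(preferred_side %in% c("R", "L"), all(gamma_shape > 0),
            noise_sd >= 0, jitter_sd >= 0)
  structure(list(preferred_side = preferred_side, kernel = kernel,
                 calcium = calcium, modulation = modulation,
                 gamma_shape = gamma_shape, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, has_secondary = has_secondary,
                 secondary_scale = secondary_scale),
            class = "ground_truth_neuron")
}

#' Default angular receptive field centred on the cue-onset geometry
#'
#' Skew-Gaussian receptive field peaking at the visual angle at which cues of
#' the preferred side appear under zero view angle (+/- 22 degrees).
#'
#' @param preferred_side `"R"` or `"L"`.
#' @param sigma RF width, degrees.
#' @param zeta Skewness parameter.
#' @return Parameter list understood by [angular_rf_eval()].
#' @export
default_rf <- function(preferred_side = "R", sigma = 35, zeta = 0.1) {
  list(form = "skew_gaussian",
       phi0 = if (preferred_side == "R") 22 else -22,
       sigma = sigma, zeta = zeta)
}
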