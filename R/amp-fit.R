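#' Prepare a cell's amplitude table for modulation-model fitting
#'
#' Computes the derived per-cue quantities the mean models use: standardized
#' speed quantiles, cue position within the cue region, cumulative cue
#' counts relative to the cell's preferred side, and the running-speed
#' inclusion filter (cues where the speed is within 25% of its median).
#'
#' @param amp One cell's rows of the amplitude table (see
#'   [amplitude_table()]): columns `A`, `phi`, `v`, `y`, `t`, `delta`,
#'   `choice`, `cue_index`, `side`.
#' @param config The session's [maze_config()] (for the cue-region span).
#' @return List with the filtered fit data (`A`, `phi`, `vt`, `y_rel`,
#'   `dpref`, `count_pref`, `count_anti`, `choice_pref`, `t`), the full
#'   unfiltered sequence (for the adaptation recursion), speed quantiles,
#'   spline knots, and bookkeeping.
#' @export
amp_fit_data <- function(amp, config) {
  if (any(amp$A < 0)) stop("amp_fit_data: negative amplitudes")
  side <- amp$side[1]
  q <- quantile(amp$v, c(0.1, 0.5, 0.9), names = FALSE)
  vt <- standardize_speed(amp$v, q[1], q[2], q[3])
  med_v <- median(amp$v)
  keep <- amp$v >= 0.75 * med_v & amp$v <= 1.25 * med_v
  y_rel <- pmin(pmax(amp$y - config$L_pre, 0), config$L_cue)
  dpref <- if (side == "R") amp$delta else -amp$delta
  n_pref <- (amp$cue_index + dpref) / 2
  n_anti <- (amp$cue_index - dpref) / 2
  choice_pref <- ifelse(amp$choice == side, "pref", "anti")
  vq <- quantile(amp$v[keep], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  list(A = amp$A, phi = amp$phi, v = amp$v, vt = vt, y_rel = y_rel,
       dpref = dpref, count_pref = n_pref, count_anti = n_anti,
       choice = choice_pref, t = amp$t, keep = keep,
       speed_q = c(q10 = q[1], q50 = q[2], q90 = q[3]),
       v_knots = vq, side = side, L_cue = config$L_cue,
       median_gap = median(diff(sort(amp$t))))
}

# AICc from a negative log-likelihood
aicc_from_nll <- function(nll, n, npar) {
  if (n <= npar + 1) stop("aicc_from_nll: n must exceed npar + 1")
  2 * npar + 2 * nll + 2 * npar * (npar + 1) / (n - npar - 1)
}

# profile the Gamma shape k out of the negative log-likelihood. The
# stationarity condition is log(k) - digamma(k) = c with
# c = mean(A/mu + log(mu) - log(A)) - 1 >= 0 by Jensen; solved by the
# standard initial approximation plus a few Newton steps on k.
profile_gamma_nll <- function(A, mu) {
  n <- length(A)
  s_lna <- sum(log(A))
  s_rest <- sum(A / mu) + sum(log(mu))
  cc <- (s_rest - s_lna) / n - 1
  if (!is.finite(cc) || cc <= 1e-12) {
    k <- 500
  } else {
    k <- (3 - cc + sqrt((cc - 3)^2 + 24 * cc)) / (12 * cc)
    for (it in 1:4) {
      f <- log(k) - digamma(k) - cc
      fp <- 1 / k - trigamma(k)
      step <- f / fp
      k <- k - step
      if (!is.finite(k) || k <= 0.05) { k <- 0.05; break }
      if (k > 500) { k <- 500; break }
      if (abs(step) < 1e-10 * k) break
    }
  }
  nll <- s_lna + k * (s_rest - s_lna) - n * k * log(k) + n * lgamma(k)
  list(nll = nll, k = k)
}

# soft-floored positive part used inside mean functions
pos_part <- function(x, eps = 1e-6) pmax(x, eps)

# mean function builders; each returns mu over the FILTERED data points
# given a named parameter vector, or NULL on invalid parameters
amp_mean_fun <- function(model_type, rf_form, fd, count_type = "difference") {
  rf_of <- function(p) {
    if (rf_form == "skew_gaussian")
      list(form = "skew_gaussian", phi0 = p[["phi0"]], sigma = exp(p[["log_sigma"]]),
           zeta = p[["zeta"]])
    else
      list(form = "sigmoid", phi0 = p[["phi0"]], zeta = exp(p[["log_zeta"]]),
           rho0 = p[["rho0"]], nu = p[["nu"]])
  }
  # pre-extracted filtered covariates (hot path: one call per objective eval)
  phi_k <- fd$phi[fd$keep]; vt_k <- fd$vt[fd$keep]; v_k <- fd$v[fd$keep]
  y_k <- fd$y_rel[fd$keep]
  counts_x <- switch(count_type, contra = fd$count_pref,
                     ipsi = fd$count_anti, difference = fd$dpref)[fd$keep]
  counts_knots <- if (count_type == "difference") c(-4, 0, 4) else c(0, 3, 8)
  is_pref <- fd$choice[fd$keep] == "pref"
  yk <- c(0, 0.5, 1) * fd$L_cue
  switch(model_type,
    null = function(p) {
      rho <- pos_part(angular_rf_eval(rf_of(p), phi_k))
      sv <- spline_eval(fd$v_knots, exp(p[4:8 + (rf_form != "skew_gaussian")]),
                        v_k)
      pos_part(rho * sv)
    },
    ssa = function(p) {
      # recursion runs over the full cue sequence; likelihood uses the
      # filtered subset
      rho <- pos_part(angular_rf_eval(rf_of(p), fd$phi))
      base <- rho * pos_part(1 + p[["phi_v"]] * fd$vt, 0.05)
      mu <- ssa_mean_sequence(fd$t, base, exp(p[["log_xi"]]),
                              exp(p[["log_lambda"]]))
      pos_part(mu[fd$keep])
    },
    choice = function(p) {
      rho <- pos_part(angular_rf_eval(rf_of(p), phi_k))
      phiv <- numeric(length(phi_k))
      phiv[is_pref] <- p[["phi_v_pref"]]
      phiv[!is_pref] <- p[["phi_v_anti"]]
      sy <- numeric(length(phi_k))
      sy[is_pref] <- spline_eval(yk, exp(p[c("s_y_pref1", "s_y_pref2",
                                             "s_y_pref3")]), y_k[is_pref])
      sy[!is_pref] <- spline_eval(yk, exp(p[c("s_y_anti1", "s_y_anti2",
                                              "s_y_anti3")]), y_k[!is_pref])
      pos_part(rho * pos_part(1 + phiv * vt_k, 0.05) * pos_part(sy))
    },
    counts = function(p) {
      rho <- pos_part(angular_rf_eval(rf_of(p), phi_k))
      sd_ <- spline_eval(counts_knots, exp(p[c("s_d1", "s_d2", "s_d3")]),
                         counts_x)
      pos_part(rho * pos_part(1 + p[["phi_v"]] * vt_k, 0.05) * pos_part(sd_))
    })
}

# parameter template: names, lower/upper bounds, and start generator
amp_par_spec <- function(model_type, rf_form, fd) {
  la <- log(pos_part(mean(fd$A[fd$keep])))
  phi_guess <- sum(fd$phi[fd$keep] * fd$A[fd$keep]) / sum(fd$A[fd$keep])
  rf <- if (rf_form == "skew_gaussian") {
    list(names = c("phi0", "log_sigma", "zeta"),
         lower = c(-60, log(5), -1.5), upper = c(60, log(120), 1.5),
         start = function(r) c(phi_guess + rnorm(1, 0, 10 * r),
                               log(35) + rnorm(1, 0, 0.4 * r),
                               rnorm(1, 0, 0.3 * r)))
  } else {
    list(names = c("phi0", "log_zeta", "rho0", "nu"),
         lower = c(-60, log(1), -4, -8), upper = c(60, log(60), 4, 8),
         start = function(r) c(phi_guess + rnorm(1, 0, 10 * r),
                               log(10) + rnorm(1, 0, 0.5 * r),
                               rnorm(1, 0.5, 0.5 * r), rnorm(1, 1, r)))
  }
  br <- switch(model_type,
    null = list(names = paste0("s_v", 1:5), lower = rep(la - 4, 5),
                upper = rep(la + 4, 5),
                start = function(r) rep(la, 5) + rnorm(5, 0, 0.3 * r)),
    ssa = list(names = c("phi_v", "log_xi", "log_lambda"),
               lower = c(-3, log(0.02), log(0.05)),
               upper = c(3, log(4), log(10)),
               start = function(r) c(rnorm(1, 0, 0.3 * r),
                                     log(runif(1, 0.3, 1.6)),
                                     log(runif(1, 0.2, 2.5)))),
    choice = list(names = c("phi_v_pref", "phi_v_anti",
                            paste0("s_y_pref", 1:3), paste0("s_y_anti", 1:3)),
                  lower = c(-3, -3, rep(la - 4, 6)),
                  upper = c(3, 3, rep(la + 4, 6)),
                  start = function(r) c(rnorm(2, 0, 0.3 * r),
                                        rep(la, 6) + rnorm(6, 0, 0.3 * r))),
    counts = list(names = c("phi_v", paste0("s_d", 1:3)),
                  lower = c(-3, rep(la - 4, 3)), upper = c(3, rep(la + 4, 3)),
                  start = function(r) c(rnorm(1, 0, 0.3 * r),
                                        rep(la, 3) + rnorm(3, 0, 0.3 * r))))
  list(names = c(rf$names, br$names), lower = c(rf$lower, br$lower),
       upper = c(rf$upper, br$upper),
       start = function(r) setNames(c(rf$start(r), br$start(r)),
                                    c(rf$names, br$names)))
}

# fit one (branch, RF form, count type) combination by multi-start bounded
# quasi-Newton with the Gamma shape profiled out
fit_amp_variant <- function(fd, model_type, rf_form,
                            count_type = "difference", n_starts = 8) {
  mean_fun <- amp_mean_fun(model_type, rf_form, fd, count_type)
  A <- fd$A[fd$keep]
  ch <- fd$choice[fd$keep]
  obj <- function(p) {
    p <- setNames(p, spec$names)
    mu <- tryCatch(mean_fun(p), error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu))) return(1e10)
    if (model_type == "choice") {
      # per-choice Gamma shapes, profiled on each subset
      tot <- 0
      for (cc in c("pref", "anti")) {
        sel <- ch == cc
        if (!any(sel)) next
        tot <- tot + profile_gamma_nll(A[sel], mu[sel])$nll
      }
      tot
    } else profile_gamma_nll(A, mu)$nll
  }
  spec <- amp_par_spec(model_type, rf_form, fd)
  starts <- lapply(seq_len(n_starts), function(i) {
    p <- spec$start(if (i == 1) 0 else 1)
    pmin(pmax(p, spec$lower), spec$upper)
  })
  vals <- vapply(starts, obj, numeric(1))
  n_polish <- min(getOption("pulsecue.amp_polish", 1L), n_starts)
  fits <- lapply(order(vals)[seq_len(n_polish)], function(i) {
    nlminb(starts[[i]], obj, lower = spec$lower, upper = spec$upper,
           control = list(iter.max = 150, rel.tol = 1e-8))
  })
  w <- which.min(vapply(fits, `[[`, numeric(1), "objective"))
  opt <- fits[[w]]
  p <- setNames(opt$par, spec$names)
  mu <- mean_fun(p)
  if (model_type == "choice") {
    k <- c(pref = profile_gamma_nll(A[ch == "pref"], mu[ch == "pref"])$k,
           anti = profile_gamma_nll(A[ch == "anti"], mu[ch == "anti"])$k)
    n_k <- 2
  } else {
    k <- profile_gamma_nll(A, mu)$k
    n_k <- 1
  }
  npar <- length(p) + n_k
  n <- length(A)
  structure(list(model_type = model_type, rf_form = rf_form,
                 count_type = if (model_type == "counts") count_type else NA,
                 params = as.list(p), k = k, neg_loglik = opt$objective,
                 n_points = n, n_par = npar,
                 aicc = aicc_from_nll(opt$objective, n, npar),
                 speed_q = fd$speed_q, v_knots = fd$v_knots,
                 L_cue = fd$L_cue, side = fd$side,
                 median_gap = fd$median_gap,
                 convergence = opt$convergence),
            class = "amp_model_fit")
}

#' Fit one amplitude-modulation model branch to a cell
#'
#' Maximum-likelihood fit of the requested branch of the Gamma
#' amplitude-modulation family. Within the branch, both angular
#' receptive-field forms (skew-Gaussian and sigmoid) are fitted and the one
#' with the better AICc kept; for the cue-counts branch the count definition
#' (cumulative preferred-side, opposite-side, or difference) is likewise
#' chosen by AICc. Observations are restricted to cues at running speeds
#' within 25% of the median; the Gamma shape is profiled out (per choice for
#' the choice branch).
#'
#' @param amp One cell's amplitude-table rows (positive amplitudes; apply
#'   [substitute_zero_amplitudes()] first if the impulse fit produced
#'   zeros).
#' @param config The session's [maze_config()].
#' @param model_type One of `"null"`, `"ssa"`, `"choice"`, `"counts"`.
#' @param n_starts Candidate starts per variant (the two best are polished).
#' @param seed Integer seed for the randomized starts.
#' @return An `amp_model_fit` with parameters, Gamma shape(s), negative
#'   log-likelihood, AICc, and the context needed for prediction.
#' @export
fit_amp_model <- function(amp, config,
                          model_type = c("null", "ssa", "choice", "counts"),
                          n_starts = 8, seed = 1L) {
  model_type <- match.arg(model_type)
  fd <- amp_fit_data(amp, config)
  if (sum(fd$keep) < 30)
    stop("fit_amp_model: fewer than 30 amplitudes after the speed filter")
  if (any(fd$A[fd$keep] <= 0))
    stop("fit_amp_model: non-positive amplitudes; substitute zeros first")
  with_seed(seed, {
    variants <- if (model_type == "counts") {
      expand.grid(rf = c("skew_gaussian", "sigmoid"),
                  ct = c("contra", "ipsi", "difference"),
                  stringsAsFactors = FALSE)
    } else {
      expand.grid(rf = c("skew_gaussian", "sigmoid"), ct = "difference",
                  stringsAsFactors = FALSE)
    }
    fits <- Map(function(rf, ct) fit_amp_variant(fd, model_type, rf, ct,
                                                 n_starts),
                variants$rf, variants$ct)
    fits[[which.min(vapply(fits, `[[`, numeric(1), "aicc"))]]
  })
}

#' @export
print.amp_model_fit <- function(x, ...) {
  cat(sprintf("amp_model_fit: %s (%s%s), AICc %.1f, k %s, n %d\n",
              x$model_type, x$rf_form,
              if (!is.na(x$count_type)) paste0(", ", x$count_type) else "",
              x$aicc, paste(signif(x$k, 3), collapse = "/"), x$n_points))
  invisible(x)
}

#' Predict mean amplitudes from a fitted modulation model
#'
#' Evaluates the branch's mean function on new cue contexts. For the
#' adaptation branch, whose mean is defined by a recursion over the cue
#' history, the prediction uses the recursion's stationary state at the
#' supplied inter-cue interval (`gap`, defaulting to the fitted session's
#' median).
#'
#' @param fit An `amp_model_fit`.
#' @param newdata Data frame with any of `phi` (degrees), `v` (cm/s),
#'   `y_rel` (cm within the cue region), `dpref` (signed preferred-side
#'   count difference), `count_pref`, `count_anti`, `choice` (`"pref"` /
#'   `"anti"`), `gap` (s); missing columns default to the reference context
#'   (median speed, `dpref = 0`, mid-region).
#' @return Vector of positive predicted means.
#' @export
predict_amp_mean <- function(fit, newdata) {
  n <- nrow(newdata)
  get_col <- function(nm, default) {
    if (!is.null(newdata[[nm]])) newdata[[nm]] else rep(default, n)
  }
  phi <- get_col("phi", if (fit$side == "R") 22 else -22)
  v <- get_col("v", fit$speed_q[["q50"]])
  vt <- standardize_speed(v, fit$speed_q[["q10"]], fit$speed_q[["q50"]],
                          fit$speed_q[["q90"]])
  y_rel <- get_col("y_rel", fit$L_cue / 2)
  dpref <- get_col("dpref", 0)
  choice <- get_col("choice", "pref")
  gap <- get_col("gap", fit$median_gap)
  p <- fit$params
  rf <- if (fit$rf_form == "skew_gaussian")
    list(form = "skew_gaussian", phi0 = p$phi0, sigma = exp(p$log_sigma),
         zeta = p$zeta)
  else
    list(form = "sigmoid", phi0 = p$phi0, zeta = exp(p$log_zeta),
         rho0 = p$rho0, nu = p$nu)
  rho <- pos_part(angular_rf_eval(rf, phi))
  switch(fit$model_type,
    null = {
      sv <- spline_eval(fit$v_knots, exp(unlist(p[paste0("s_v", 1:5)])), v)
      pos_part(rho * sv)
    },
    ssa = {
      base <- rho * pos_part(1 + p$phi_v * vt, 0.05)
      xi <- exp(p$log_xi); lam <- exp(p$log_lambda)
      E <- exp(-gap / lam)
      den <- 1 - base * xi * E
      mu <- ifelse(den > 0.1, base * (1 - E) / den, 10 * base)
      pos_part(mu)
    },
    choice = {
      yk <- c(0, 0.5, 1) * fit$L_cue
      phiv <- ifelse(choice == "pref", p$phi_v_pref, p$phi_v_anti)
      sy <- ifelse(choice == "pref",
                   spline_eval(yk, exp(unlist(p[paste0("s_y_pref", 1:3)])), y_rel),
                   spline_eval(yk, exp(unlist(p[paste0("s_y_anti", 1:3)])), y_rel))
      pos_part(rho * pos_part(1 + phiv * vt, 0.05) * pos_part(sy))
    },
    counts = {
      knots <- if (fit$count_type == "difference") c(-4, 0, 4) else c(0, 3, 8)
      x <- switch(fit$count_type, contra = get_col("count_pref", 2),
                  ipsi = get_col("count_anti", 2), difference = dpref)
      sd_ <- spline_eval(knots, exp(unlist(p[paste0("s_d", 1:3)])), x)
      pos_part(rho * pos_part(1 + p$phi_v * vt, 0.05) * pos_part(sd_))
    })
}

#' Select the best modulation model and form the AICc-weighted ensemble
#'
#' The best model is the alternative branch with the lowest AICc, unless the
#' null model's relative likelihood against it,
#' `exp((AICc_best - AICc_null)/2)`, is 0.05 or larger, in which case the
#' null model is kept (ambiguous cases default to null). Ensemble weights
#' are Akaike weights `w_m \propto exp(-(AICc_m - min AICc)/2)`, normalized
#' to sum to 1, and the ensemble mean predictor is the weight-averaged
#' branch prediction.
#'
#' @param fits Named list with components `null`, `ssa`, `choice`,
#'   `counts`, each an `amp_model_fit`.
#' @param null_threshold Relative-likelihood threshold for abandoning the
#'   null model (default 0.05).
#' @return An `amp_model_ensemble` with `weights`, `best_model`, the fits,
#'   and the selection diagnostics.
#' @export
select_and_average <- function(fits, null_threshold = 0.05) {
  stopifnot(all(c("null", "ssa", "choice", "counts") %in% names(fits)))
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w <- w / sum(w)
  alt <- setdiff(names(fits), "null")
  best_alt <- alt[which.min(aiccs[alt])]
  null_rel_lik <- exp((aiccs[best_alt] - aiccs["null"]) / 2)
  best <- if (null_rel_lik < null_threshold) best_alt else "null"
  structure(list(fits = fits, aicc = aiccs, weights = w, best_model = best,
                 null_rel_lik = unname(null_rel_lik),
                 side = fits$null$side, L_cue = fits$null$L_cue),
            class = "amp_model_ensemble")
}

#' @export
print.amp_model_ensemble <- function(x, ...) {
  cat(sprintf("amp_model_ensemble: best %s; weights %s\n", x$best_model,
              paste(sprintf("%s %.2f", names(x$weights), x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Ensemble mean-amplitude prediction
#'
#' @param ensemble An `amp_model_ensemble`.
#' @param newdata As in [predict_amp_mean()].
#' @return Akaike-weight-averaged predicted means.
#' @export
predict_ensemble_mean <- function(ensemble, newdata) {
  preds <- vapply(names(ensemble$fits), function(nm) {
    predict_amp_mean(ensemble$fits[[nm]], newdata)
  }, numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  as.numeric(preds %*% ensemble$weights)
}

#' Replace zero amplitudes with noise-level estimates
#'
#' The Gamma observation model requires positive amplitudes, but the
#' non-negativity constraint of the impulse fit produces exact zeros.
#' Zeros are replaced by draws from the distribution of amplitudes obtained
#' by fitting the same cue timings (with the cell's fitted kernel) to a
#' simulated noise-only trace of SD `sigma_f` - a "noise floor" amplitude
#' distribution whose scale is proportional to `sigma_f`.
#'
#' @param fit An `impulse_fit`.
#' @param sigma_f Noise SD; defaults to the fit's residual estimate.
#' @param seed Integer seed.
#' @return The fit's amplitude vector with zeros replaced (strictly
#'   positive).
#' @export
substitute_zero_amplitudes <- function(fit, sigma_f = fit$sigma_f,
                                       seed = 1L) {
  if (sigma_f <= 0) stop("substitute_zero_amplitudes: sigma_f must be > 0")
  amps <- fit$amplitudes
  zero <- which(amps <= 0)
  if (length(zero) == 0) return(amps)
  fd <- fit$internal$fd
  cues <- fit$internal$cues[[fit$primary_side]]
  with_seed(seed, {
    pool <- numeric(0)
    tries <- 0
    while (length(pool) < 10 && tries < 5) {
      noise <- rnorm(fd$n, 0, sigma_f)
      np <- impulse_nnls_pass(fd, cues, fit$internal$tab,
                              fit$kernel$tau_lag, numeric(cues$m), y = noise)
      pool <- c(pool, np$amps[np$amps > 0])
      tries <- tries + 1
    }
    if (length(pool) == 0) pool <- abs(rnorm(50, 0, sigma_f)) + 1e-9
    amps[zero] <- sample(pool, length(zero), replace = TRUE)
    amps
  })
}

#' Choice-modulation strength profile
#'
#' The location-dependent choice-modulation strength is the difference
#' between the ensemble's predicted amplitudes on preferred-choice
#' (contralateral, i.e. the cell's cue side) versus anti-preferred-choice
#' trials, evaluated along the cue region at the fixed visual angle
#' corresponding to zero view angle (+22 degrees for right-side cues, -22
#' for left), at the median speed and zero accumulated evidence, and
#' normalized by the harmonic-mean amplitude
#' `<A> = (1/(2 Lcue) * sum_C integral dy / max(A_C(y), sigma_f))^(-1)`.
#'
#' @param ensemble An `amp_model_ensemble`.
#' @param sigma_f Noise floor used inside the normalization integral.
#' @param n_grid Number of evaluation points along the cue region (>= 100).
#' @return List with `y` (cm within the cue region), `delta_a` (unitless
#'   profile), `mean_amplitude` (the normalizer `<A>`), and the two choice
#'   profiles.
#' @export
choice_modulation_strength <- function(ensemble, sigma_f, n_grid = 101) {
  L <- ensemble$L_cue
  y <- seq(0, L, length.out = max(n_grid, 100))
  phi_ref <- if (ensemble$side == "R") 22 else -22
  ctx <- function(choice) data.frame(phi = phi_ref, y_rel = y, dpref = 0,
                                     choice = choice)
  a_contra <- predict_ensemble_mean(ensemble, ctx("pref"))
  a_ipsi <- predict_ensemble_mean(ensemble, ctx("anti"))
  trapz <- function(f) sum((f[-1] + f[-length(f)]) / 2) * (y[2] - y[1])
  inv_mean <- (trapz(1 / pmax(a_contra, sigma_f)) +
                 trapz(1 / pmax(a_ipsi, sigma_f))) / (2 * L)
  mean_amp <- 1 / inv_mean
  list(y = y, delta_a = (a_contra - a_ipsi) / mean_amp,
       mean_amplitude = mean_amp, a_contra = a_contra, a_ipsi = a_ipsi)
}
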