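#' Psychometric curve: 4-parameter sigmoid fit over evidence bins
#'
#' The fraction of rightward choices is computed in 11 bins of the final
#' evidence `Delta = #R - #L` (integer-centred bins spanning the observed
#' range symmetrically), with Jeffreys binomial intervals per bin, and
#' fitted by weighted least squares to
#' `pR(Delta) = p0 + B / (1 + exp(-(Delta - Delta0) / lambda))`.
#'
#' @param session A `session_log`, or a data frame with columns `delta`
#'   (final evidence) and `choice_right` (0/1).
#' @param n_boot Optional bootstrap resamples for parameter CIs (0 = none).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `psychometric_fit`: `params` (p0, B, Delta0,
#'   lambda), `bins` (centers, n, k, fraction, CI), optional `ci`, and the
#'   fitted `curve(delta)` function. Degenerate all-one-side data raises an
#'   error.
#' @export
psychometric_fit <- function(session, n_boot = 0, seed = 1L) {
  df <- psychometric_data(session)
  if (nrow(df) < 100) stop("psychometric_fit: need >= 100 trials")
  if (length(unique(df$choice_right)) < 2)
    stop("psychometric_fit: degenerate choices (all one side)")
  fit_once <- function(d) {
    bins <- evidence_bins(d$delta, n_bins = 11)
    agg <- data.frame(center = bins$centers)
    agg$n <- vapply(seq_len(11), function(i) sum(bins$bin == i, na.rm = TRUE),
                    numeric(1))
    agg$k <- vapply(seq_len(11), function(i)
      sum(d$choice_right[bins$bin == i], na.rm = TRUE), numeric(1))
    agg <- agg[agg$n > 0, , drop = FALSE]
    agg$fraction <- agg$k / agg$n
    wts <- sqrt(agg$n)
    resid_fun <- function(p) {
      wts * (agg$fraction - (p[1] + p[2] / (1 + exp(-(agg$center - p[3]) / p[4]))))
    }
    best <- NULL
    for (lam0 in c(1.5, 0.5, 3)) {
      fit <- tryCatch(minpack.lm::nls.lm(
        par = c(p0 = 0.05, B = 0.9, Delta0 = 0, lam = lam0),
        lower = c(-0.5, 0, -15, 0.05), upper = c(1, 1.5, 15, 20),
        fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$deviance < best$deviance)) best <- fit
    }
    if (is.null(best)) stop("psychometric_fit: sigmoid fit failed")
    list(params = setNames(best$par, c("p0", "B", "Delta0", "lam")),
         agg = agg)
  }
  main <- fit_once(df)
  agg <- main$agg
  ci_bins <- t(vapply(seq_len(nrow(agg)), function(i)
    jeffreys_ci(agg$k[i], agg$n[i]), numeric(2)))
  agg$ci_lower <- ci_bins[, 1]; agg$ci_upper <- ci_bins[, 2]
  boot_ci <- NULL
  if (n_boot > 0) {
    draws <- with_seed(seed, t(vapply(seq_len(n_boot), function(b) {
      d <- df[sample.int(nrow(df), replace = TRUE), ]
      tryCatch(fit_once(d)$params, error = function(e) rep(NA_real_, 4))
    }, numeric(4))))
    boot_ci <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975),
                       na.rm = TRUE))
    rownames(boot_ci) <- names(main$params)
  }
  p <- main$params
  structure(list(params = c(p0 = unname(p["p0"]), B = unname(p["B"]),
                            Delta0 = unname(p["Delta0"]),
                            lambda = unname(p["lam"])),
                 bins = agg, ci = boot_ci,
                 curve = function(delta) unname(p["p0"] + p["B"] /
                   (1 + exp(-(delta - p["Delta0"]) / p["lam"])))),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("psychometric_fit: p0 %.3f, B %.3f, Delta0 %.2f, lambda %.2f\n",
              x$params["p0"], x$params["B"], x$params["Delta0"],
              x$params["lambda"]))
  invisible(x)
}

# per-trial final evidence and choice from a session
psychometric_data <- function(session) {
  if (is.data.frame(session)) return(session)
  data.frame(
    delta = vapply(session$trials, function(tr)
      sum(tr$cues$side == "R") - sum(tr$cues$side == "L"), numeric(1)),
    choice_right = vapply(session$trials, function(tr)
      as.numeric(tr$choice == "R"), numeric(1)))
}

# 11 integer-centred evidence bins spanning the observed range symmetrically
evidence_bins <- function(delta, n_bins = 11) {
  m <- max(abs(delta), 1)
  step <- max(1, round(2 * m / (n_bins - 1)))
  centers <- step * (seq_len(n_bins) - (n_bins + 1) / 2)
  bin <- vapply(delta, function(d) which.min(abs(d - centers)), integer(1))
  list(centers = centers, bin = bin, step = step)
}

#' Spatially binned evidence weights by logistic regression
#'
#' Logistic regression of choice on the per-third evidence differences
#' `Delta_i` (cues in three equal thirds of the cue region), with bootstrap
#' confidence intervals. On separation the fit falls back to a lightly
#' ridge-penalized logistic regression and flags it.
#'
#' @param session A `session_log`, or a data frame with columns `d1`, `d2`,
#'   `d3`, `choice_right`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return Object of class `evidence_logistic`: `weights` (3 per-third
#'   weights), `intercept`, `ci`, `ridged` flag, and the bootstrap draws.
#' @export
evidence_logistic <- function(session, n_boot = 1000, seed = 1L,
                              level = 0.95) {
  df <- evidence_logistic_data(session)
  if (nrow(df) < 100) stop("evidence_logistic: need >= 100 trials")
  fit_once <- function(d) {
    ridged <- FALSE
    co <- tryCatch({
      fit <- suppressWarnings(glm(choice_right ~ d1 + d2 + d3,
                                  family = binomial(), data = d))
      co <- coef(fit)
      if (any(abs(co[-1]) > 15) || !fit$converged) stop("separation")
      co
    }, error = function(e) {
      ridged <<- TRUE
      X <- as.matrix(d[, c("d1", "d2", "d3")])
      gf <- glmnet::glmnet(X, d$choice_right, family = "binomial",
                           alpha = 0, lambda = 1e-3)
      cg <- as.numeric(coef(gf))
      setNames(cg, c("(Intercept)", "d1", "d2", "d3"))
    })
    list(coef = co, ridged = ridged)
  }
  main <- fit_once(df)
  draws <- with_seed(seed, t(vapply(seq_len(n_boot), function(b) {
    d <- df[sample.int(nrow(df), replace = TRUE), ]
    tryCatch(fit_once(d)$coef, error = function(e) rep(NA_real_, 4))
  }, numeric(4))))
  a <- (1 - level) / 2
  ci <- t(apply(draws[, -1, drop = FALSE], 2, quantile,
                probs = c(a, 1 - a), na.rm = TRUE))
  dimnames(ci) <- list(c("d1", "d2", "d3"), c("lower", "upper"))
  structure(list(weights = main$coef[-1], intercept = main$coef[1],
                 ci = ci, ridged = main$ridged, boot = draws),
            class = "evidence_logistic")
}

#' @export
print.evidence_logistic <- function(x, ...) {
  cat(sprintf("evidence_logistic: weights [%s]%s\n",
              paste(signif(x$weights, 3), collapse = ", "),
              if (x$ridged) " (ridge fallback)" else ""))
  invisible(x)
}

# per-trial per-third evidence table
evidence_logistic_data <- function(session) {
  if (is.data.frame(session)) return(session)
  cfg <- session$config
  rows <- lapply(session$trials, function(tr) {
    d <- evidence_by_third(list(R = tr$cues$y[tr$cues$side == "R"],
                                L = tr$cues$y[tr$cues$side == "L"]), cfg)
    data.frame(d1 = d[1], d2 = d[2], d3 = d[3],
               choice_right = as.numeric(tr$choice == "R"))
  })
  do.call(rbind, rows)
}

#' Sliding-window session performance and inclusion flag
#'
#' Maximum fraction of correct trials over a sliding window; sessions are
#' included when the maximum windowed performance reaches the threshold
#' (inclusive).
#'
#' @param correct Logical per-trial correctness (or a `session_log`).
#' @param window Window length in trials (default 100).
#' @param threshold Inclusion threshold (default 0.65).
#' @return List with `max_performance`, `include`, and the windowed series.
#' @export
sliding_performance <- function(correct, window = 100, threshold = 0.65) {
  if (inherits(correct, "session_log"))
    correct <- vapply(correct$trials, `[[`, logical(1), "correct")
  n <- length(correct)
  if (n < window)
    stop("sliding_performance: need at least `window` trials")
  cs <- cumsum(c(0, as.numeric(correct)))
  perf <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  mx <- max(perf)
  list(max_performance = mx, include = mx >= threshold, windowed = perf)
}
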