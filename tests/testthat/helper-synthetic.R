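# Shared synthetic fixtures, built once per test run and cached by key.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

shared_session <- function(n_trials = 40, seed = 11, ...) {
  key <- paste0("session_", n_trials, "_", seed)
  cached(key, generate_session(maze_config(...), agent_params(), n_trials,
                               seed = seed))
}

# amplitude table assembled from a population's ground truth (bypassing the
# impulse-fit stage), for testing the amplitude-model machinery in isolation
amp_from_truth <- function(pop, events, cell) {
  tr <- pop$truth[pop$truth$cell_id == cell, ]
  ev <- events[events$side == tr$side[1], ]
  idx <- match(paste(tr$trial_id, tr$cue_index),
               paste(ev$trial_id, ev$cue_index))
  data.frame(cell_id = cell, side = tr$side[1], trial_id = tr$trial_id,
             cue_index = tr$cue_index, t = tr$t, y = ev$y[idx],
             phi = ev$phi[idx], v = ev$v[idx], delta = ev$delta[idx],
             choice = ev$choice[idx], A = tr$A, stringsAsFactors = FALSE)
}

# align an impulse fit's amplitudes with the generator's ground truth
truth_alignment <- function(fit, truth_cell) {
  match(paste(fit$events$trial_id, fit$events$cue_index),
        paste(truth_cell$trial_id, truth_cell$cue_index))
}

# brute-force Benjamini-Hochberg oracle (direct application of the
# definition), shared by the decoding and acceptance suites
oracle_bh <- function(p, alpha = 0.05) {
  n <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(n) * alpha / n)
  if (!length(ok)) return(rep(FALSE, n))
  p <= ps[max(ok)]
}

# natural cubic spline via an explicit tridiagonal solve, used as an
# independent oracle for spline_eval
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  # second derivatives M solve a tridiagonal system (natural: M1 = Mn = 0)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1] / 6
    A[i, i] <- (h[i - 1] + h[i]) / 3
    A[i, i + 1] <- h[i] / 6
    rhs[i] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  M <- solve(A, rhs)
  vapply(xout, function(xx) {
    if (xx <= x[1]) { # linear extrapolation with the end-segment slope
      s <- (y[2] - y[1]) / h[1] - h[1] * (2 * M[1] + M[2]) / 6
      return(y[1] + s * (xx - x[1]))
    }
    if (xx >= x[n]) {
      s <- (y[n] - y[n - 1]) / h[n - 1] + h[n - 1] * (M[n - 1] + 2 * M[n]) / 6
      return(y[n] + s * (xx - x[n]))
    }
    i <- findInterval(xx, x, rightmost.closed = TRUE)
    dx1 <- xx - x[i]; dx2 <- x[i + 1] - xx
    (M[i] * dx2^3 + M[i + 1] * dx1^3) / (6 * h[i]) +
      (y[i] / h[i] - M[i] * h[i] / 6) * dx2 +
      (y[i + 1] / h[i] - M[i + 1] * h[i] / 6) * dx1
  }, numeric(1))
}
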