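#' Build the neural state table for population decoding
#'
#' One row per contralateral cue presentation, one column per
#' contralateral-cue-locked cell (cells preferring the hemisphere's
#' contralateral side, flagged cue-locked, without secondary responses),
#' holding each cell's fitted amplitude for that cue. Rows are tagged with
#' the spatial third of the cue region in which the cue appeared.
#'
#' @param amp Amplitude table ([amplitude_table()]) for the session's cells.
#' @param cue_locked Named logical vector (or vector aligned with the
#'   distinct `cell_id`s) flagging cue-locked cells.
#' @param session The `session_log`.
#' @param contra_side Which cue side is contralateral to the recorded
#'   hemisphere (default `"R"`, i.e. a left-hemisphere recording).
#' @param has_secondary Optional logical vector aligned like `cue_locked`;
#'   cells with secondary responses are excluded ("contralateral cues
#'   only").
#' @return List with `states` (cues x cells matrix), `meta` (data frame:
#'   `trial_id`, `cue_index`, `t`, `y`, `third`, and the task variables at
#'   each cue), and `cells` (the column cell ids). Errors with class
#'   `pulsecue_no_cells` if no cell qualifies.
#' @export
build_neural_states <- function(amp, cue_locked, session, contra_side = "R",
                                has_secondary = NULL) {
  cfg <- session$config
  ids <- sort(unique(amp$cell_id))
  if (is.null(names(cue_locked))) names(cue_locked) <- ids
  if (is.null(has_secondary))
    has_secondary <- setNames(rep(FALSE, length(ids)), ids)
  if (is.null(names(has_secondary))) names(has_secondary) <- ids
  side_of <- vapply(ids, function(id) amp$side[amp$cell_id == id][1],
                    character(1))
  use <- ids[cue_locked[as.character(ids)] & side_of == contra_side &
               !has_secondary[as.character(ids)]]
  if (length(use) == 0)
    stop(structure(class = c("pulsecue_no_cells", "error", "condition"),
                   list(message = "build_neural_states: no qualifying cue-locked cells",
                        call = sys.call())))
  sub <- amp[amp$cell_id %in% use & amp$side == contra_side, , drop = FALSE]
  key <- paste(sub$trial_id, sub$cue_index)
  ukey <- unique(key)
  states <- matrix(NA_real_, nrow = length(ukey), ncol = length(use),
                   dimnames = list(NULL, paste0("cell_", use)))
  for (j in seq_along(use)) {
    rows <- sub[sub$cell_id == use[j], , drop = FALSE]
    states[match(paste(rows$trial_id, rows$cue_index), ukey), j] <- rows$A
  }
  first <- sub[match(ukey, key), , drop = FALSE]
  y_rel <- pmin(pmax(first$y - cfg$L_pre, 0), cfg$L_cue)
  third <- pmin(3, pmax(1, ceiling(y_rel / (cfg$L_cue / 3))))
  third[y_rel == 0] <- 1
  meta <- data.frame(trial_id = first$trial_id, cue_index = first$cue_index,
                     t = first$t, y = first$y, third = third,
                     theta = first$theta, v = first$v, delta = first$delta,
                     choice = ifelse(first$choice == "R", 1, -1),
                     prev_choice = ifelse(is.na(first$prev_choice), NA,
                                          ifelse(first$prev_choice == "R", 1, -1)),
                     prev_reward = ifelse(is.na(first$prev_reward), NA,
                                          ifelse(first$prev_reward, 1, -1)))
  ord <- order(meta$t)
  list(states = states[ord, , drop = FALSE], meta = meta[ord, , drop = FALSE],
       cells = use)
}

#' Uncorrelated task-variable modes via polar decomposition
#'
#' Finds the matrix `Y` with orthonormal columns closest (Frobenius norm) to
#' the column-standardized task-variable matrix `X`: from the polar
#' decomposition `X = Y H` (Y orthogonal, H symmetric), computed through the
#' SVD `X = U S V'` as `Y = U V'`. Each mode is identified with its original
#' column and its Pearson correlation with it is reported.
#'
#' @param X Numeric matrix or data frame, columns = task variables across
#'   cue presentations.
#' @return Object of class `uncorrelated_modes`: `Y` (orthonormal columns),
#'   `H` (symmetric factor), `correlations` (per mode vs. its original
#'   variable).
#' @export
uncorrelated_modes <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("uncorrelated_modes: non-finite values in X")
  Xs <- scale(X, center = TRUE, scale = FALSE)
  nrm <- sqrt(colSums(Xs^2))
  if (any(nrm == 0)) stop("uncorrelated_modes: constant column(s): ",
                          paste(colnames(X)[nrm == 0], collapse = ", "))
  Xs <- sweep(Xs, 2, nrm, "/")
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(Xs)]]
    stop("uncorrelated_modes: rank-deficient X; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  sv <- svd(Xs)
  Y <- sv$u %*% t(sv$v)
  H <- sv$v %*% diag(sv$d, length(sv$d)) %*% t(sv$v)
  colnames(Y) <- colnames(X)
  dimnames(H) <- list(colnames(X), colnames(X))
  cors <- vapply(seq_len(ncol(X)), function(j) cor(Y[, j], X[, j]),
                 numeric(1))
  structure(list(Y = Y, H = H,
                 correlations = setNames(cors, colnames(X))),
            class = "uncorrelated_modes")
}

#' @export
print.uncorrelated_modes <- function(x, ...) {
  cat("uncorrelated_modes: mode-variable correlations\n")
  print(round(x$correlations, 3))
  invisible(x)
}

# trial-stratified fold assignment: all cues of a trial share a fold
trial_folds <- function(trial_ids, n_folds = 3) {
  trials <- unique(trial_ids)
  f <- rep_len(seq_len(n_folds), length(trials))[sample.int(length(trials))]
  f[match(trial_ids, trials)]
}

#' Decode a task variable from neural states
#'
#' Linear support-vector decoder (classification for binary +/-1 labels,
#' epsilon-regression for continuous labels) assessed by trial-stratified
#' k-fold cross-validation: folds are assigned at the trial level so cues
#' of one trial never span the train/test split. Features are z-scored
#' using training-fold statistics. Held-out predictions are concatenated
#' across folds and summarized by their Pearson correlation with the labels.
#'
#' @param states Cue x cell matrix of amplitudes.
#' @param labels Task-variable values per cue (finite; binary labels coded
#'   +/-1).
#' @param trial_ids Trial id per row, for the stratified folds.
#' @param n_folds Number of folds (default 3).
#' @param seed Integer seed for the fold assignment.
#' @param cost SVM regularization constant (default 1).
#' @return List with `r` (Pearson correlation), `predictions`, `folds`.
#'   For degenerate (single-class) labels, `r` is `NA` with a warning.
#' @export
decode_variable <- function(states, labels, trial_ids, n_folds = 3,
                            seed = 1L, cost = 1) {
  states <- as.matrix(states)
  stopifnot(nrow(states) == length(labels),
            length(trial_ids) == length(labels))
  keep <- is.finite(labels) & apply(is.finite(states), 1, all)
  states <- states[keep, , drop = FALSE]
  labels <- labels[keep]; trial_ids <- trial_ids[keep]
  if (nrow(states) < 12) stop("decode_variable: fewer than 12 usable cues")
  binary <- length(unique(labels)) <= 2
  if (binary && length(unique(labels)) < 2) {
    warning("decode_variable: single-class labels; performance undefined")
    return(list(r = NA_real_, predictions = rep(NA_real_, length(labels)),
                folds = rep(NA_integer_, length(labels))))
  }
  with_seed(seed, {
    folds <- trial_folds(trial_ids, n_folds)
    pred <- rep(NA_real_, length(labels))
    for (f in seq_len(n_folds)) {
      tr <- folds != f; te <- folds == f
      if (!any(te) || !any(tr)) next
      mu <- colMeans(states[tr, , drop = FALSE])
      sdv <- apply(states[tr, , drop = FALSE], 2, sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      xtr <- sweep(sweep(states[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(states[te, , drop = FALSE], 2, mu), 2, sdv, "/")
      if (binary) {
        ytr <- factor(labels[tr], levels = sort(unique(labels)))
        if (nlevels(droplevels(ytr)) < 2) {
          # degenerate training fold: predict its majority class
          pred[te] <- as.numeric(as.character(names(which.max(table(ytr)))))
          next
        }
        fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost,
                          scale = FALSE)
        pred[te] <- as.numeric(as.character(predict(fit, xte)))
      } else {
        fit <- e1071::svm(xtr, labels[tr], kernel = "linear", cost = cost,
                          type = "eps-regression", scale = FALSE)
        pred[te] <- predict(fit, xte)
      }
    }
    ok <- is.finite(pred)
    r <- if (sd(pred[ok]) == 0 || sd(labels[ok]) == 0) 0
         else cor(pred[ok], labels[ok])
    list(r = r, predictions = pred, folds = folds)
  })
}

# permute rows at the trial level: whole trial blocks of states are
# reassigned against the fixed label rows, preserving inter-neuron
# correlations and within-trial structure
permute_trial_blocks <- function(states, trial_ids) {
  trials <- unique(trial_ids)
  perm <- sample(trials)
  idx <- unlist(lapply(perm, function(tr) which(trial_ids == tr)))
  states[idx, , drop = FALSE]
}

#' Permutation p-value for decoding performance
#'
#' Builds `n_null` pseudo-experiments by permuting the neural states across
#' trials (entire trial blocks of rows move together, preserving
#' inter-neuron correlations) and re-running the decoder; the p-value uses
#' the add-one convention `p = (1 + #{null r >= observed r}) / (n_null + 1)`.
#'
#' @inheritParams decode_variable
#' @param n_null Number of permutations (>= 20; default 100).
#' @return List with `p`, `r_obs`, and the vector `r_null`.
#' @export
permutation_pvalue <- function(states, labels, trial_ids, n_null = 100,
                               n_folds = 3, seed = 1L, cost = 1) {
  stopifnot(n_null >= 20)
  r_obs <- decode_variable(states, labels, trial_ids, n_folds,
                           seed = seed, cost = cost)$r
  if (is.na(r_obs)) return(list(p = NA_real_, r_obs = NA_real_,
                                r_null = rep(NA_real_, n_null)))
  r_null <- with_seed(seed + 1L, vapply(seq_len(n_null), function(i) {
    sp <- permute_trial_blocks(states, trial_ids)
    decode_variable(sp, labels, trial_ids, n_folds, seed = seed,
                    cost = cost)$r
  }, numeric(1)))
  p <- (1 + sum(r_null >= r_obs, na.rm = TRUE)) / (n_null + 1)
  list(p = p, r_obs = r_obs, r_null = r_null)
}

#' Benjamini-Hochberg significance mask
#'
#' Standard BH step-up procedure: sort p-values ascending, find the largest
#' rank i with `p_(i) <= i * alpha / n`, and flag all p-values at or below
#' that threshold. A literal "first rank" variant (smallest qualifying rank)
#' is available for comparison.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param alpha False-discovery level (default 0.05).
#' @param literal_first_rank If `TRUE`, use the smallest rank satisfying the
#'   inequality instead of the largest.
#' @return Logical significance mask aligned with `p_values`.
#' @export
bh_correct <- function(p_values, alpha = 0.05, literal_first_rank = FALSE) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  n <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  qualifies <- ps <= seq_len(n) * alpha / n
  if (!any(qualifies)) return(rep(FALSE, n))
  i_star <- if (literal_first_rank) which(qualifies)[1] else max(which(qualifies))
  p_values <= ps[i_star]
}

#' Decode the six task variables per spatial third
#'
#' Runs the permutation-tested decoder for view angle, speed, evidence,
#' choice, previous choice and previous reward, separately on cues from
#' each third of the cue region, and applies Benjamini-Hochberg correction
#' across all (variable, third) tests of the session.
#'
#' @param ns A neural-state list from [build_neural_states()].
#' @param n_null Permutations per test.
#' @param seed Integer seed.
#' @param min_cues Minimum usable cues per (variable, third).
#' @param alpha BH false-discovery level.
#' @return Data frame with one row per (variable, third): `r`, `p`,
#'   `bh_significant`, `n_cues`, `n_cells`.
#' @export
decode_session <- function(ns, n_null = 100, seed = 1L, min_cues = 12,
                           alpha = 0.05) {
  vars <- c("theta", "v", "delta", "choice", "prev_choice", "prev_reward")
  rows <- list()
  for (third in 1:3) {
    sel <- ns$meta$third == third
    for (vn in vars) {
      labels <- ns$meta[[vn]][sel]
      ok <- sum(is.finite(labels))
      if (ok < min_cues) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = vn, third = third, r = NA_real_, p = NA_real_,
          n_cues = ok, n_cells = ncol(ns$states))
        next
      }
      res <- tryCatch(
        permutation_pvalue(ns$states[sel, , drop = FALSE], labels,
                           ns$meta$trial_id[sel], n_null = n_null,
                           seed = seed + third * 101 + match(vn, vars)),
        warning = function(w) NULL, error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        variable = vn, third = third,
        r = if (is.null(res)) NA_real_ else res$r_obs,
        p = if (is.null(res)) NA_real_ else res$p,
        n_cues = ok, n_cells = ncol(ns$states))
    }
  }
  out <- do.call(rbind, rows)
  out$bh_significant <- FALSE
  ok <- !is.na(out$p)
  if (any(ok)) out$bh_significant[ok] <- bh_correct(out$p[ok], alpha)
  out
}

#' Session-level meta-regression of decoding accuracy
#'
#' Linear support-vector regression of per-session decoding accuracy on
#' area/layer indicator variables and the number of recorded cue-locked
#' cells, with confidence intervals from bootstrapping sessions.
#'
#' @param accuracy Per-session decoding accuracy (e.g. mid-cue-region r).
#' @param predictors Data frame of numeric regressors (indicators and cell
#'   counts), one row per session.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level for the bootstrap intervals.
#' @return List with `weights` (named), `ci` (matrix lower/upper), and the
#'   bootstrap weight draws.
#' @export
decoding_meta_regression <- function(accuracy, predictors, n_boot = 1000,
                                     seed = 1L, level = 0.95) {
  X <- as.matrix(predictors)
  stopifnot(nrow(X) == length(accuracy))
  if (nrow(X) < 10) stop("decoding_meta_regression: need >= 10 sessions")
  svr_weights <- function(x, y) {
    mu <- colMeans(x); sdv <- apply(x, 2, sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    fit <- e1071::svm(xs, y, kernel = "linear", type = "eps-regression",
                      cost = 1, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV) / sdv
    setNames(w, colnames(x))
  }
  with_seed(seed, {
    w0 <- svr_weights(X, accuracy)
    boots <- t(vapply(seq_len(n_boot), function(b) {
      i <- sample.int(nrow(X), replace = TRUE)
      tryCatch(svr_weights(X[i, , drop = FALSE], accuracy[i]),
               error = function(e) rep(NA_real_, ncol(X)))
    }, numeric(ncol(X))))
    a <- (1 - level) / 2
    ci <- t(apply(boots, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE))
    dimnames(ci) <- list(colnames(X), c("lower", "upper"))
    list(weights = w0, ci = ci, boot = boots)
  })
}
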