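# Nuisance removal and per-trial response estimation: 24-regressor motion
# confound model, 128-s cosine high-pass, and the additive per-trial GLM
# ("Add" model) over the stationary phase of each trial.

#' Expand six motion parameters into the 24-regressor confound matrix
#'
#' The classic expansion: the 6 realignment parameters, their temporal
#' derivatives (backward differences, first sample 0), their squares, and
#' the squares of the derivatives.
#'
#' @param motion 6 x T matrix (a `motion_series` or plain matrix).
#' @return Object of class `confound_matrix`: 24 x T matrix, row blocks
#'   params / derivatives / squares / squared derivatives.
#' @export
friston24_expansion <- function(motion) {
  m <- unclass(motion)
  if (!is.matrix(m) || nrow(m) != 6L) stop("motion must be a 6 x T matrix")
  if (ncol(m) < 2L) stop("motion must have at least 2 time points")
  d <- cbind(0, t(apply(m, 1, diff)))
  out <- rbind(m, d, m^2, d^2)
  rn <- rownames(m) %||% paste0("p", 1:6)
  rownames(out) <- c(rn, paste0(rn, "_deriv"), paste0(rn, "_sq"),
                     paste0(rn, "_deriv_sq"))
  structure(out, class = c("confound_matrix", "matrix"))
}

# Cosine (DCT-II) drift basis whose columns have period strictly greater
# than cutoff_s. Dimensions: T x K.
cosine_drift_basis <- function(n_volumes, tr_s, cutoff_s) {
  dur <- n_volumes * tr_s
  k_max <- floor(2 * dur / cutoff_s)
  if (2 * dur / k_max == cutoff_s) k_max <- k_max - 1L   # period must exceed cutoff
  if (k_max < 1L) return(matrix(numeric(0), n_volumes, 0))
  t_idx <- seq_len(n_volumes) - 0.5
  vapply(seq_len(k_max), function(k) cos(pi * k * t_idx / n_volumes),
         numeric(n_volumes))
}

#' High-pass filter by cosine-basis projection
#'
#' Removes fluctuations with period longer than `cutoff_s` by regressing
#' out a discrete-cosine drift basis (all components with period >
#' `cutoff_s`), then re-adds each row's mean so baselines are preserved.
#'
#' @param x An `roi_timeseries`, or a plain rows x T matrix (then `tr_s`
#'   is required).
#' @param cutoff_s Cut-off period in seconds (128); must exceed 2 x TR.
#' @param tr_s Repetition time, only for matrix input.
#' @return Same type as the input, filtered.
#' @export
highpass <- function(x, cutoff_s = 128, tr_s = NULL) {
  is_ts <- inherits(x, "roi_timeseries")
  m <- if (is_ts) x$data else unclass(x)
  tr <- if (is_ts) x$tr_s else tr_s
  if (is.null(tr)) stop("tr_s must be supplied for matrix input")
  if (cutoff_s <= 2 * tr) stop("cutoff_s must exceed twice the repetition time")
  basis <- cosine_drift_basis(ncol(m), tr, cutoff_s)
  mu <- rowMeans(m)
  res <- m - matrix(mu, nrow(m), ncol(m))
  if (ncol(basis) > 0) {
    # project rows onto the drift basis and subtract the fitted drift
    coef <- res %*% basis %*% solve(crossprod(basis))
    res <- res - coef %*% t(basis)
  }
  out <- res + matrix(mu, nrow(m), ncol(m))
  if (is_ts) { x$data <- out; x } else out
}

#' Regress confounds out of a time series
#'
#' Per-voxel ordinary-least-squares residuals with respect to the confound
#' rows plus an intercept. Linearly dependent confound rows are dropped
#' with a warning. The result is orthogonal to every retained confound.
#'
#' @param ts An `roi_timeseries`, or a rows x T matrix.
#' @param confounds A `confound_matrix` (rows x T), typically high-passed
#'   with the same filter as the data first.
#' @return Same type as `ts`, residualised.
#' @export
residualize <- function(ts, confounds) {
  is_ts <- inherits(ts, "roi_timeseries")
  m <- if (is_ts) ts$data else unclass(ts)
  cf <- unclass(confounds)
  if (ncol(cf) != ncol(m)) stop("confounds and time series disagree on T")
  X <- cbind(1, t(cf))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning("dropping ", ncol(X) - qx$rank, " linearly dependent confound column(s)")
    X <- X[, keep, drop = FALSE]
    qx <- qr(X)
  }
  res <- t(qr.resid(qx, t(m)))
  if (is_ts) { ts$data <- res; ts } else res
}

#' Unconvolved per-trial boxcar regressor
#'
#' A binary regressor marking the volumes whose acquisition midpoint lies
#' in the window 6 to 12 s after trial onset (three TRs at TR = 2 s for
#' on-grid onsets): the putative haemodynamic peak of the stationary phase
#' of the trial, which occupies 2-6 s after onset.
#'
#' @param onset_s Trial onset in seconds from run start.
#' @param n_volumes Volumes in the run.
#' @param tr_s Repetition time in seconds.
#' @param window_s Window relative to onset, default `c(6, 12)`
#'   (half-open).
#' @return Length-T 0/1 vector.
#' @export
trial_regressor <- function(onset_s, n_volumes, tr_s = 2, window_s = c(6, 12)) {
  mid <- (seq_len(n_volumes) - 0.5) * tr_s
  as.numeric(mid >= onset_s + window_s[1] & mid < onset_s + window_s[2])
}

#' Estimate single-trial response amplitudes (additive per-trial GLM)
#'
#' Each trial is estimated in its own model containing three regressors:
#' the trial's own boxcar ([trial_regressor()]), the union boxcar of all
#' other trials in the run, and an intercept. The stored estimate is the
#' coefficient of the trial's own regressor, per voxel. The time series
#' should already be high-pass filtered and residualised.
#'
#' @param ts An `roi_timeseries` for one run.
#' @param events The matching run's trial events data frame.
#' @param window_s Estimation window relative to onset (seconds).
#' @return Object of class `trial_betas`: list with `run`, `betas`
#'   (n_trials x n_voxels, rows in `events` order), `n_active` (active
#'   volumes per trial regressor).
#' @export
estimate_trial_betas <- function(ts, events, window_s = c(6, 12)) {
  m <- ts$data
  T_run <- ncol(m)
  run_end_s <- T_run * ts$tr_s
  late <- which(events$onset_s + window_s[2] > run_end_s)
  if (length(late) > 0) {
    stop("trial window extends past run end for trial index ",
         paste(events$trial_index[late], collapse = ", "))
  }
  regs <- vapply(events$onset_s, trial_regressor, numeric(T_run),
                 n_volumes = T_run, tr_s = ts$tr_s, window_s = window_s)
  n_active <- colSums(regs)
  union_all <- as.numeric(rowSums(regs) > 0)
  tY <- t(m)
  per_trial <- vapply(seq_len(nrow(events)), function(i) {
    x_t <- regs[, i]
    x_other <- as.numeric(union_all > 0 & x_t == 0)
    X <- cbind(x_t, x_other, 1)
    coef <- qr.coef(qr(X), tY)
    coef[1, , drop = TRUE]
  }, numeric(nrow(m)))
  betas <- if (is.matrix(per_trial)) t(per_trial) else matrix(per_trial, ncol = 1)
  structure(list(run = events$run[1], betas = betas, n_active = n_active),
            class = "trial_betas")
}
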