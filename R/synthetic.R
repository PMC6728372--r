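# Synthetic BOLD generator: plants direction-specific multivoxel patterns
# into ROI voxel time series driven by the trial table, on top of
# low-frequency drift, motion-coupled nuisance and AR(1) + white noise.

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities peaking at 6 s with a 16 s
#' undershoot at 1/6 amplitude; the usual default in SPM-style analyses.
#'
#' @param t Time in seconds (vector).
#' @param peak_delay,undershoot_delay Gamma shape parameters (seconds).
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @return HRF values at `t`, scaled to unit peak.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             undershoot_ratio = 6) {
  h <- dgamma(t, shape = peak_delay, scale = 1) -
    dgamma(t, shape = undershoot_delay, scale = 1) / undershoot_ratio
  h / max(h)
}

#' Generate direction-specific condition patterns for one ROI
#'
#' The four direction patterns are a shared baseline pattern plus
#' `effect_amplitude` times one of four mutually orthonormal
#' direction-specific components. Because the baseline is orthogonal to
#' every component, all four patterns have exactly equal Euclidean norm,
#' so no direction is trivially louder than another; with amplitude 0 the
#' four patterns are identical and the factor carries no information.
#'
#' @param n_voxels Number of voxels (>= 4).
#' @param factor Which factor the set encodes (`"allo_boundary"` or
#'   `"allo_goal"`); stored as a label only.
#' @param effect_amplitude Euclidean norm of each direction-specific
#'   component (>= 0), in the same arbitrary units as the noise.
#' @param baseline_scale Norm of the shared baseline pattern.
#' @param seed RNG seed.
#' @return Object of class `condition_patterns`: list with `factor`,
#'   `patterns` (4 x n_voxels, rows named N/E/S/W), `effect_amplitude`.
#' @export
generate_condition_patterns <- function(n_voxels, factor = c("allo_boundary", "allo_goal"),
                                        effect_amplitude = 1, baseline_scale = 1,
                                        seed = 1L) {
  factor <- match.arg(factor)
  if (n_voxels < 4) stop("n_voxels must be at least 4")
  if (effect_amplitude < 0) stop("effect_amplitude must be non-negative")
  k <- min(5L, n_voxels)
  Q <- withr::with_seed(seed, {
    M <- matrix(rnorm(n_voxels * k), nrow = n_voxels, ncol = k)
    qr.Q(qr(M))
  })
  comps <- t(Q[, 1:4, drop = FALSE])
  base <- if (k == 5L) Q[, 5] * baseline_scale else rep(0, n_voxels)
  patterns <- matrix(rep(base, each = 4), nrow = 4) + effect_amplitude * comps
  rownames(patterns) <- compass_directions()
  structure(list(factor = factor, patterns = patterns,
                 effect_amplitude = effect_amplitude),
            class = "condition_patterns")
}

#' Generate a six-parameter head-motion trace
#'
#' Each parameter (3 translations in mm, 3 rotations in radians) is an
#' independent bounded random walk, reflected at its bound so traces stay
#' within realistic head-motion magnitudes.
#'
#' @param n_volumes Number of volumes T (>= 2).
#' @param step_sd Step standard deviation for the translation walks (mm);
#'   rotation steps use `step_sd * rot_scale`.
#' @param rot_scale Rotation-to-translation step ratio.
#' @param bounds Length-2 numeric: reflection bounds for translations (mm)
#'   and rotations (radians).
#' @param seed RNG seed.
#' @return Object of class `motion_series`: 6 x T matrix with rows
#'   trans_x..rot_z.
#' @export
generate_motion <- function(n_volumes, step_sd = 0.05, rot_scale = 0.01,
                            bounds = c(trans = 2, rot = 0.02), seed = 1L) {
  if (n_volumes < 2) stop("n_volumes must be at least 2")
  reflect <- function(x, b) {
    if (b <= 0) return(x)
    r <- (x + b) %% (4 * b)
    ifelse(r < 2 * b, r - b, 3 * b - r)
  }
  sds <- c(rep(step_sd, 3), rep(step_sd * rot_scale, 3))
  bnd <- c(rep(bounds[[1]], 3), rep(bounds[[2]], 3))
  m <- withr::with_seed(seed, {
    t(vapply(seq_len(6), function(i) {
      reflect(cumsum(c(0, rnorm(n_volumes - 1, sd = sds[i]))), bnd[i])
    }, numeric(n_volumes)))
  })
  rownames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  structure(m, class = c("motion_series", "matrix"))
}

#' Default noise configuration for the BOLD simulator
#'
#' @param ar_coef AR(1) coefficient of the temporally correlated noise.
#' @param ar_sd Innovation standard deviation of the AR(1) component.
#' @param white_sd Standard deviation of the additional white noise.
#' @param drift_amp Per-voxel amplitude scale of the cosine drift terms
#'   (periods >= 128 s, so the high-pass stage can remove them).
#' @param motion_coupling Scale of the linear coupling of the first two
#'   motion parameters into voxel baselines.
#' @return A named list understood by [simulate_roi_timeseries()].
#' @export
noise_config <- function(ar_coef = 0.3, ar_sd = 1, white_sd = 0.5,
                         drift_amp = 1, motion_coupling = 0.5) {
  list(ar_coef = ar_coef, ar_sd = ar_sd, white_sd = white_sd,
       drift_amp = drift_amp, motion_coupling = motion_coupling)
}

# HRF-convolved regressor for one trial: neural boxcar over the movement +
# stationary period [onset, onset + 6 s), sampled at volume midpoints.
convolved_trial_regressor <- function(onset_s, n_volumes, tr_s = 2, neural_dur_s = 6) {
  mid <- (seq_len(n_volumes) - 0.5) * tr_s
  neural <- as.numeric(mid >= onset_s & mid < onset_s + neural_dur_s)
  h <- hrf_double_gamma(seq(0, 32, by = tr_s))
  convolve(neural, rev(h), type = "open")[seq_len(n_volumes)]
}

#' Simulate one run of ROI voxel time series
#'
#' The signal is the sum over trials of the voxel pattern for the trial's
#' boundary direction plus the pattern for its goal direction, each scaled
#' by an HRF-convolved regressor of the trial's movement + stationary
#' period. On top of the signal sit slow cosine drifts, a linear coupling
#' of the first two motion parameters into voxel baselines, and AR(1) plus
#' white noise.
#'
#' @param events One run's trial events (a data frame from a
#'   `trial_table`, i.e. `table$runs[[r]]`).
#' @param patterns Named list with elements `allo_boundary` and
#'   `allo_goal`, each a `condition_patterns` object with matching voxel
#'   counts (either may be omitted to plant only one factor).
#' @param motion A `motion_series` with T columns, or NULL for none.
#' @param noise_cfg List from [noise_config()].
#' @param n_volumes,tr_s Volumes per run (445) and repetition time (2 s).
#' @param roi_label Label stored on the result.
#' @param seed RNG seed for drift, coupling weights, and noise.
#' @return Object of class `roi_timeseries`: list with `roi_label`, `data`
#'   (n_voxels x T), `tr_s`, `n_volumes`, `run`.
#' @export
simulate_roi_timeseries <- function(events, patterns, motion = NULL,
                                    noise_cfg = noise_config(),
                                    n_volumes = 445, tr_s = 2,
                                    roi_label = "roi", seed = 1L) {
  pats <- Filter(Negate(is.null), patterns[c("allo_boundary", "allo_goal")])
  if (length(pats) == 0L) stop("patterns must contain allo_boundary and/or allo_goal")
  nv <- unique(vapply(pats, function(p) ncol(p$patterns), integer(1)))
  if (length(nv) != 1L) stop("pattern sets disagree on voxel count")
  n_trials <- nrow(events)

  # n_trials x T regressor matrix and n_trials x n_voxels amplitude matrix
  X <- t(vapply(events$onset_s, convolved_trial_regressor,
                numeric(n_volumes), n_volumes = n_volumes, tr_s = tr_s))
  P <- matrix(0, n_trials, nv)
  for (p in pats) {
    P <- P + p$patterns[events[[p$factor]], , drop = FALSE]
  }
  Y <- t(P) %*% X

  withr::with_seed(seed, {
    if (noise_cfg$drift_amp > 0) {
      dur <- n_volumes * tr_s
      periods <- (2 * dur) / (1:4)
      periods <- periods[periods >= 128]
      tt <- (seq_len(n_volumes) - 0.5) * tr_s
      basis <- vapply(periods, function(p) cos(2 * pi * tt / p), numeric(n_volumes))
      W <- matrix(rnorm(nv * length(periods), sd = noise_cfg$drift_amp), nv)
      Y <- Y + W %*% t(basis)
    }
    if (!is.null(motion) && noise_cfg$motion_coupling > 0) {
      if (ncol(motion) != n_volumes) stop("motion length does not match n_volumes")
      Wm <- matrix(rnorm(nv * 2, sd = noise_cfg$motion_coupling), nv)
      Y <- Y + Wm %*% motion[1:2, , drop = FALSE]
    }
    if (noise_cfg$ar_sd > 0) {
      innov <- matrix(rnorm(nv * n_volumes, sd = noise_cfg$ar_sd), n_volumes, nv)
      ar <- apply(innov, 2, function(e) {
        as.numeric(stats::filter(e, noise_cfg$ar_coef, method = "recursive"))
      })
      Y <- Y + t(ar)
    }
    if (noise_cfg$white_sd > 0) {
      Y <- Y + matrix(rnorm(nv * n_volumes, sd = noise_cfg$white_sd), nv)
    }
  })
  structure(list(roi_label = roi_label, data = Y, tr_s = tr_s,
                 n_volumes = n_volumes, run = events$run[1]),
            class = "roi_timeseries")
}

#' Default ROI configuration for a simulated cohort
#'
#' @param label ROI label (free-form; no anatomy is modelled).
#' @param n_voxels Voxels in the ROI.
#' @param amp_boundary,amp_goal Planted effect amplitudes for the boundary
#'   and goal direction factors.
#' @return Named list understood by [simulate_participant()].
#' @export
roi_config <- function(label = "posterior_roi", n_voxels = 100,
                       amp_boundary = 0.35, amp_goal = 0) {
  list(label = label, n_voxels = n_voxels,
       amp_boundary = amp_boundary, amp_goal = amp_goal)
}

#' Simulate one participant: design, motion, and ROI time series
#'
#' @param participant Participant index (used for seed derivation).
#' @param rois List of ROI configurations from [roi_config()].
#' @param noise_cfg Noise configuration from [noise_config()].
#' @param n_volumes,tr_s Acquisition geometry per run.
#' @param design_args Extra arguments passed to [build_trial_table()].
#' @param env An `environment_spec`.
#' @param seed Master seed; everything about the participant derives from
#'   `(seed, participant)`.
#' @return List with `participant`, `table` (the `trial_table`), `motion`
#'   (per run), `rois` (per ROI: `patterns` ground truth and `runs`, a
#'   list of `roi_timeseries`), and `seed`.
#' @export
simulate_participant <- function(participant, rois = list(roi_config()),
                                 noise_cfg = noise_config(),
                                 n_volumes = 445, tr_s = 2,
                                 design_args = list(), env = build_environment(),
                                 seed = 1L) {
  pseed <- derive_seed(seed, participant)
  table <- do.call(build_trial_table,
                   c(list(paths = enumerate_paths(env), env = env,
                          seed = derive_seed(pseed, 1)), design_args))
  n_runs <- length(table$runs)
  motion <- lapply(seq_len(n_runs), function(r) {
    generate_motion(n_volumes, seed = derive_seed(pseed, 2, r))
  })
  roi_out <- lapply(seq_along(rois), function(i) {
    cfg <- rois[[i]]
    pats <- list(
      allo_boundary = generate_condition_patterns(
        cfg$n_voxels, "allo_boundary", cfg$amp_boundary,
        seed = derive_seed(pseed, 3, i, 1)),
      allo_goal = generate_condition_patterns(
        cfg$n_voxels, "allo_goal", cfg$amp_goal,
        seed = derive_seed(pseed, 3, i, 2)))
    runs <- lapply(seq_len(n_runs), function(r) {
      simulate_roi_timeseries(table$runs[[r]], pats, motion[[r]], noise_cfg,
                              n_volumes = n_volumes, tr_s = tr_s,
                              roi_label = cfg$label,
                              seed = derive_seed(pseed, 4, i, r))
    })
    list(config = cfg, patterns = pats, runs = runs)
  })
  names(roi_out) <- vapply(rois, `[[`, character(1), "label")
  list(participant = participant, table = table, motion = motion,
       rois = roi_out, seed = pseed)
}

#' Simulate a cohort and optionally persist it to disk
#'
#' With `out_dir` given, writes a BIDS-style layout per participant:
#' events TSV per run, confounds TSV per run, one NIfTI image per ROI and
#' run (voxels unravelled along the first axis) with a JSON sidecar, plus
#' a top-level manifest JSON recording every seed and the ground-truth
#' effect amplitudes.
#'
#' @param n_participants Cohort size (28).
#' @param rois,noise_cfg,n_volumes,tr_s,design_args,env,seed As in
#'   [simulate_participant()].
#' @param out_dir Output directory, or NULL to keep everything in memory.
#' @param overwrite Overwrite an existing non-empty `out_dir`.
#' @return List with `participants` (list of [simulate_participant()]
#'   results) and `manifest`.
#' @export
simulate_cohort <- function(n_participants = 28, rois = list(roi_config()),
                            noise_cfg = noise_config(), n_volumes = 445,
                            tr_s = 2, design_args = list(),
                            env = build_environment(), seed = 1L,
                            out_dir = NULL, overwrite = FALSE) {
  if (!is.null(out_dir) && dir.exists(out_dir) &&
      length(list.files(out_dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty; use overwrite = TRUE")
  }
  participants <- lapply(seq_len(n_participants), simulate_participant,
                         rois = rois, noise_cfg = noise_cfg,
                         n_volumes = n_volumes, tr_s = tr_s,
                         design_args = design_args, env = env, seed = seed)
  manifest <- list(
    master_seed = seed, n_participants = n_participants,
    n_volumes = n_volumes, tr_s = tr_s,
    rois = rois, noise = noise_cfg,
    participant_seeds = vapply(participants, `[[`, integer(1), "seed"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (p in participants) write_participant(p, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(participants = participants, manifest = manifest)
}
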