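test_that("condition patterns have equal norms, controlled separation and are reproducible", {
  p0 <- generate_condition_patterns(50, "allo_boundary", effect_amplitude = 0, seed = 4)
  expect_equal(nrow(p0$patterns), 4)
  expect_true(all(abs(sweep(p0$patterns, 2, p0$patterns[1, ])) < 1e-12))

  p1 <- generate_condition_patterns(50, "allo_goal", effect_amplitude = 2, seed = 4)
  norms <- sqrt(rowSums(p1$patterns^2))
  expect_lt(diff(range(norms)), 1e-6)
  cors <- cor(t(p1$patterns))
  expect_true(all(cors[upper.tri(cors)] < 1))
  # planted separation: distance between any two patterns is amp * sqrt(2)
  d12 <- sqrt(sum((p1$patterns[1, ] - p1$patterns[2, ])^2))
  expect_equal(d12, 2 * sqrt(2), tolerance = 1e-8)

  expect_identical(p1$patterns,
                   generate_condition_patterns(50, "allo_goal", 2, seed = 4)$patterns)
  expect_error(generate_condition_patterns(3, "allo_goal"), "at least 4")
  expect_error(generate_condition_patterns(50, "allo_goal", -1), "non-negative")
})

test_that("motion traces are bounded random walks with the right shape", {
  m <- generate_motion(445, seed = 2)
  expect_equal(dim(unclass(m)), c(6L, 445L))
  expect_true(all(abs(m[1:3, ]) <= 2))
  expect_true(all(abs(m[4:6, ]) <= 0.02))
  expect_identical(unclass(m), unclass(generate_motion(445, seed = 2)))
  z <- generate_motion(100, step_sd = 0, seed = 2)
  expect_true(all(z == 0))
  expect_error(generate_motion(1), "at least 2")
})

test_that("simulated series equal pattern x convolved regressor in the noiseless case", {
  tab <- default_table()
  ev <- tab$runs[[1]][1, , drop = FALSE]  # single trial
  nv <- 12
  quiet <- noise_config(ar_sd = 0, white_sd = 0, drift_amp = 0, motion_coupling = 0)

  # all-zero patterns and no noise give an all-zero series
  zero <- generate_condition_patterns(nv, "allo_boundary", 0, baseline_scale = 0, seed = 1)
  ts0 <- simulate_roi_timeseries(ev, list(allo_boundary = zero), noise_cfg = quiet, seed = 1)
  expect_true(all(ts0$data == 0))

  # unit pattern for the trial's boundary direction: outer-product oracle
  v <- rnorm(nv)
  pat <- matrix(0, 4, nv, dimnames = list(c("N", "E", "S", "W"), NULL))
  pat[ev$allo_boundary, ] <- v
  custom <- structure(list(factor = "allo_boundary", patterns = pat,
                           effect_amplitude = 1), class = "condition_patterns")
  ts1 <- simulate_roi_timeseries(ev, list(allo_boundary = custom),
                                 noise_cfg = quiet, seed = 1)
  # independent convolution oracle: direct lagged sum of boxcar and HRF
  mid <- (1:445 - 0.5) * 2
  neural <- as.numeric(mid >= ev$onset_s & mid < ev$onset_s + 6)
  h <- hrf_double_gamma(seq(0, 32, by = 2))
  conv <- sapply(seq_along(neural), function(t) {
    k <- seq_len(min(t, length(h)))
    sum(h[k] * neural[t - k + 1])
  })
  expect_equal(ts1$data, outer(v, conv), tolerance = 1e-10)

  # a run of 445 volumes at TR 2 covers 14.8 minutes
  expect_equal(round(445 * ts1$tr_s / 60, 1), 14.8)
})

test_that("two-factor simulation is additive given a shared seed", {
  tab <- default_table()
  ev <- tab$runs[[1]]
  pb <- generate_condition_patterns(10, "allo_boundary", 1, seed = 21)
  pg <- generate_condition_patterns(10, "allo_goal", 1.5, seed = 22)
  quiet <- noise_config(ar_sd = 0, white_sd = 0, drift_amp = 0, motion_coupling = 0)
  noisy <- noise_config(ar_sd = 0.5, white_sd = 0.5, drift_amp = 0.5, motion_coupling = 0)

  both <- simulate_roi_timeseries(ev, list(allo_boundary = pb, allo_goal = pg),
                                  noise_cfg = noisy, seed = 9)
  only_b <- simulate_roi_timeseries(ev, list(allo_boundary = pb),
                                    noise_cfg = noisy, seed = 9)
  only_g <- simulate_roi_timeseries(ev, list(allo_goal = pg),
                                    noise_cfg = quiet, seed = 9)
  expect_equal(both$data - only_b$data, only_g$data, tolerance = 1e-10)
})

test_that("cohorts persist to disk reproducibly", {
  dir <- withr::local_tempdir()
  quiet <- noise_config(ar_sd = 0.5, white_sd = 0.5, drift_amp = 0.5,
                        motion_coupling = 0.5)
  rois <- list(roi_config("tiny", n_voxels = 6, amp_boundary = 0.3))
  ch <- simulate_cohort(n_participants = 2, rois = rois, noise_cfg = quiet,
                        n_volumes = 445, seed = 5, out_dir = dir)
  expect_length(ch$participants, 2)
  expect_length(ch$manifest$participant_seeds, 2)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "sub-01", "sub-01_run-1_events.tsv")))
  expect_true(file.exists(file.path(dir, "sub-02", "sub-02_run-3_roi-tiny.nii.gz")))

  expect_error(simulate_cohort(n_participants = 2, rois = rois, noise_cfg = quiet,
                               seed = 5, out_dir = dir), "overwrite")

  # regeneration from the same master seed is identical
  ch2 <- simulate_cohort(n_participants = 2, rois = rois, noise_cfg = quiet,
                         n_volumes = 445, seed = 5)
  expect_identical(ch$participants[[2]]$rois$tiny$runs[[1]]$data,
                   ch2$participants[[2]]$rois$tiny$runs[[1]]$data)
  # round trip through the NIfTI writer
  back <- read_roi_nifti(file.path(dir, "sub-01", "sub-01_run-1_roi-tiny.nii.gz"))
  expect_equal(back$data, ch$participants[[1]]$rois$tiny$runs[[1]]$data,
               tolerance = 1e-6)
  expect_equal(back$tr_s, 2)
})

test_that("decoding accuracy is non-decreasing in planted effect amplitude", {
  acc_at <- function(amp) {
    accs <- vapply(1:2, function(i) {
      cfg <- default_config(
        n_participants = 2,
        rois = list(roi_config("roi", n_voxels = 60, amp_boundary = amp, amp_goal = 0)),
        seed = 640L)
      analyze_participant(i, cfg)$scores$roi$allo_boundary$mean_accuracy
    }, numeric(1))
    mean(accs)
  }
  ladder <- vapply(c(0, 0.35, 1), acc_at, numeric(1))
  # stochastic tolerance: one fold is 19 samples, so allow binomial noise
  expect_gt(ladder[2], ladder[1] - 0.05)
  expect_gt(ladder[3], ladder[2] - 0.05)
  expect_gt(ladder[3], ladder[1] + 0.2)
})
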