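# Shared fixtures. Heavyweight objects are built once per test run and
# memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

default_env <- function() fixture("env", build_environment)
default_paths <- function() fixture("paths", function() enumerate_paths(default_env()))
default_table <- function() {
  fixture("table", function() build_trial_table(default_paths(), default_env(), seed = 7L))
}

# 4-class Gaussian blobs with class-mean separation `sep`
make_blobs <- function(n_per_class = 24, n_features = 20, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    dirs <- c("N", "E", "S", "W")
    centers <- matrix(rnorm(4 * n_features), 4)
    centers <- sep * centers / sqrt(rowSums(centers^2))
    x <- do.call(rbind, lapply(1:4, function(k) {
      matrix(rnorm(n_per_class * n_features), n_per_class) +
        matrix(centers[k, ], n_per_class, n_features, byrow = TRUE)
    }))
    list(x = x, y = rep(dirs, each = n_per_class))
  })
}

# Synthetic trial betas for one run: per-direction mean pattern + noise,
# labelled by the run's factor levels. Independent of the GLM machinery.
make_run_betas <- function(events, factor, n_voxels = 30, sep = 0, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(4 * n_voxels), 4)
    centers <- if (sep > 0) sep * centers / sqrt(rowSums(centers^2)) else 0 * centers
    lab <- match(events[[factor]], c("N", "E", "S", "W"))
    b <- centers[lab, , drop = FALSE] +
      matrix(rnorm(nrow(events) * n_voxels, sd = sd), nrow(events))
    structure(list(run = events$run[1], betas = b, n_active = rep(3, nrow(events))),
              class = "trial_betas")
  })
}

# One fully analysed participant with a planted boundary (not goal) signal,
# shared by the decoding/synthetic property tests.
analyzed_boundary_participant <- function() {
  fixture("analyzed_boundary", function() {
    cfg <- default_config(
      n_participants = 1,
      rois = list(roi_config("roi", n_voxels = 80, amp_boundary = 0.5, amp_goal = 0)),
      seed = 302L)
    analyze_participant(1, cfg)
  })
}
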