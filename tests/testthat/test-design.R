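test_that("environment invariants hold and bad configs are rejected", {
  env <- default_env()
  expect_length(env$boundaries, 4)
  axes <- vapply(env$boundaries, `[[`, character(1), "long_axis")
  expect_equal(sum(axes == "NS"), 2)
  expect_equal(sum(axes == "EW"), 2)
  expect_setequal(unname(env$landmark_compass), c("N", "S", "E", "W"))
  expect_equal(unname(env$landmark_compass["Mountain"]), "N")

  expect_error(build_environment(landmarks = c("A", "B", "C")), "4 unique landmark")
  expect_error(build_environment(textures = rep("brick", 4)), "unique boundary textures")
  expect_error(build_environment(boundary_centres = rbind(c(-260, 0), c(125, 0), c(0, 125), c(0, -125))),
               "explorable extent")
})

test_that("relative landmark lookups follow the compass", {
  env <- default_env()
  expect_equal(relative_landmark("Mountain", 90, env), "ClockTower")
  expect_equal(relative_landmark("Cathedral", 180, env), "Mountain")
  for (lm in names(env$landmark_compass)) {
    expect_equal(relative_landmark(lm, 0, env), lm)
  }
  expect_error(relative_landmark("Mountain", 45, env), "multiple of 90")
  expect_error(relative_landmark("Lighthouse", 90, env), "unknown landmark")
})

test_that("path enumeration is exhaustive, non-redundant and geometrically consistent", {
  paths <- default_paths()
  expect_equal(nrow(paths), 24)
  expect_false(any(duplicated(paths[c("boundary_id", "boundary_side", "ego_boundary")])))
  # every (boundary, side) has exactly one front, left and right path
  combos <- table(paste(paths$boundary_id, paths$boundary_side), paths$ego_boundary)
  expect_true(all(combos == 1))
  expect_equal(nrow(combos), 8)

  # independent geometric oracle: unit vectors, y = N, x = E; rotating a
  # heading -90 deg (counterclockwise) must point at a left-lying wall
  vec <- function(d) switch(d, N = c(0, 1), E = c(1, 0), S = c(0, -1), W = c(-1, 0))
  rot_cw <- function(v) c(v[2], -v[1])  # clockwise quarter turn
  for (i in seq_len(nrow(paths))) {
    h <- vec(paths$heading[i]); b <- vec(paths$boundary_side[i])
    expected <- switch(paths$ego_boundary[i],
                       front = h, right = rot_cw(h), left = -rot_cw(h))
    expect_equal(b, expected, info = paste("path", i))
  }
  # worked cases: wall to the N approached with the wall on the left means
  # heading E; on the right means heading W
  n_left <- paths[paths$boundary_side == "N" & paths$ego_boundary == "left", ]
  n_right <- paths[paths$boundary_side == "N" & paths$ego_boundary == "right", ]
  expect_true(all(n_left$heading == "E"))
  expect_true(all(n_right$heading == "W"))
})

test_that("trial tables are balanced, reproducible, and internally consistent", {
  tab <- default_table()
  expect_length(tab$runs, 3)
  for (run in tab$runs) {
    expect_equal(nrow(run), 96)
    expect_true(all(table(run$path_id) == 4))
    expect_true(all(table(run$path_id, run$cue_side) == 2))
    expect_equal(unname(table(factor(run$allo_boundary, c("N", "E", "S", "W")))),
                 rep(24L, 4), ignore_attr = TRUE)
    expect_equal(unname(table(factor(run$allo_goal, c("N", "E", "S", "W")))),
                 rep(24L, 4), ignore_attr = TRUE)
    expect_true(all(diff(run$onset_s) > 0))
    expect_true(all(run$movement_duration + run$blank_duration + run$decision_duration == 8))
    # round trip: goal and response recomputable from heading and cue side
    goal <- compass_rotate(run$heading, ifelse(run$cue_side == "right", 90, -90))
    expect_equal(run$allo_goal, goal)
    env <- default_env()
    expect_equal(run$correct_response_landmark,
                 names(env$landmark_compass)[match(run$allo_goal, env$landmark_compass)])
  }
  tab2 <- build_trial_table(default_paths(), default_env(), seed = 7L)
  expect_identical(tab$runs, tab2$runs)
  tab3 <- build_trial_table(default_paths(), default_env(), seed = 8L)
  expect_false(identical(tab$runs[[1]]$path_id, tab3$runs[[1]]$path_id))
  expect_error(build_trial_table(default_paths(), default_env(), reps_per_run = 3),
               "even")
})

test_that("JRD enumeration covers all ordered landmark pairs with correct responses", {
  jrd <- enumerate_jrd(default_env())
  expect_equal(nrow(jrd), 12)
  expect_true(all(jrd$facing_landmark != jrd$probe_landmark))
  expect_true(all(table(jrd$facing_landmark) == 3))
  for (f in unique(jrd$facing_landmark)) {
    expect_setequal(jrd$angular_disparity[jrd$facing_landmark == f], c(90, 180, 270))
  }
  expect_equal(jrd$correct_response[jrd$facing_landmark == "Mountain" &
                                      jrd$probe_landmark == "Cathedral"], "behind")
  expect_equal(jrd$angular_disparity[jrd$facing_landmark == "Mountain" &
                                       jrd$probe_landmark == "Cathedral"], 180)
  expect_equal(unname(c(`90` = "right", `180` = "behind", `270` = "left")[
    as.character(jrd$angular_disparity)]), jrd$correct_response)
})

test_that("balance verification passes for the default design and flags violations", {
  tab <- default_table()
  for (fac in c("allo_boundary", "allo_goal")) {
    bal <- verify_balance(tab, fac)
    expect_true(bal$pass)
    expect_equal(sum(bal$report$n_trials), 3 * 96)
  }
  # egocentric counts per level and run: 2 walls x 4 reps per position
  n_sub <- tab$runs[[1]]
  expect_equal(unname(table(n_sub$ego_boundary[n_sub$allo_boundary == "N"])),
               rep(8L, 3), ignore_attr = TRUE)
  broken <- tab
  broken$runs <- lapply(broken$runs, function(r) { r$cue_side <- "left"; r })
  rep2 <- verify_balance(broken, "allo_boundary")
  expect_false(rep2$pass)
  expect_true(all(!rep2$report$cue_balanced))
})

test_that("occupancy histogram is a 10,000-bin probability distribution with correct mask fractions", {
  env <- default_env()
  masks <- boundary_masks(env)
  expect_equal(nrow(masks), 8)
  expect_equal(unname(table(masks$direction)), rep(2L, 4), ignore_attr = TRUE)

  # trajectory confined to one N-direction mask
  m <- masks[masks$direction == "N", ][1, ]
  traj <- data.frame(t = 0:10,
                     x = seq(m$xmin + 0.1, m$xmax - 0.1, length.out = 11),
                     y = rep((m$ymin + m$ymax) / 2, 11))
  occ <- occupancy_fraction(traj, env)
  expect_equal(length(occ$histogram), 10000)
  expect_equal(sum(occ$histogram), 1, tolerance = 1e-9)
  expect_equal(unname(occ$per_direction["N"]), 1.0)
  expect_equal(occ$total, 1.0)

  # uniform occupancy of all bin centres: mask-area arithmetic
  centres <- seq(-247.5, 247.5, by = 5)
  grid <- expand.grid(x = centres, y = centres)
  traj_u <- data.frame(t = seq_len(nrow(grid) + 1)[-1] - 1, x = grid$x, y = grid$y)
  traj_u <- rbind(traj_u, data.frame(t = nrow(grid) + 1, x = 0, y = 0))
  occ_u <- occupancy_fraction(traj_u, env)
  expect_equal(occ_u$total, 8 * (40 * 5) / (500 * 500), tolerance = 1e-12)
  expect_equal(unname(occ_u$per_direction), rep(0.0016, 4), tolerance = 1e-12)

  expect_error(occupancy_fraction(data.frame(t = numeric(), x = numeric(), y = numeric()), env),
               "empty")
  expect_error(occupancy_fraction(data.frame(t = c(0, 0), x = c(0, 0), y = c(0, 0)), env),
               "increasing")
})
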