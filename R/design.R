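# Experimental design: the virtual arena, the 24 passive paths, and the
# 96-trial run tables in which allocentric boundary direction and
# allocentric goal direction are orthogonal by construction.

#' Construct the virtual environment specification
#'
#' The arena is a 600 x 600 m grass plain with a 500 x 500 m explorable
#' area centred on the origin. It contains four rectangular boundary walls
#' (2 m wide, 40 m long), two with their long axis running north-south and
#' two running east-west, and is surrounded by four global landmarks
#' rendered at infinity, one per cardinal direction.
#'
#' @param landmarks Character vector of 4 unique landmark names, in the
#'   order N, S, E, W of `landmark_compass`.
#' @param textures Character vector of 4 unique boundary texture labels.
#' @param landmark_compass Named character vector mapping each landmark to
#'   a compass direction; must be a bijection onto N/S/E/W.
#' @param boundary_centres 4 x 2 numeric matrix of boundary centre
#'   coordinates (metres, arena-centred); rows follow `textures`.
#' @param boundary_axes Character vector of 4 long-axis orientations,
#'   `"NS"` or `"EW"`; exactly two of each.
#' @param arena_extent,explorable_extent Side length in metres of the full
#'   arena and the explorable area.
#' @param boundary_length,boundary_width Wall dimensions in metres.
#' @param mask_depth Depth in metres of the boundary-proximity occupancy
#'   masks attached to each wall face.
#' @return An object of class `environment_spec`.
#' @examples
#' env <- build_environment()
#' env$landmark_compass
#' @export
build_environment <- function(landmarks = c("Mountain", "Cathedral", "ClockTower", "City"),
                              textures = c("red_brick", "grey_brick", "yellow_brick", "brown_brick"),
                              landmark_compass = stats::setNames(c("N", "S", "E", "W"), landmarks),
                              boundary_centres = rbind(c(-125, 0), c(125, 0), c(0, 125), c(0, -125)),
                              boundary_axes = c("NS", "NS", "EW", "EW"),
                              arena_extent = 600,
                              explorable_extent = 500,
                              boundary_length = 40,
                              boundary_width = 2,
                              mask_depth = 5) {
  if (length(landmarks) != 4L || anyDuplicated(landmarks)) {
    stop("exactly 4 unique landmark names are required")
  }
  if (length(textures) != 4L || anyDuplicated(textures)) {
    stop("exactly 4 unique boundary textures are required")
  }
  if (length(landmark_compass) != 4L ||
      !setequal(names(landmark_compass), landmarks) ||
      !setequal(landmark_compass, c("N", "S", "E", "W"))) {
    stop("landmark_compass must be a bijection from the 4 landmarks onto N/S/E/W")
  }
  if (length(boundary_axes) != 4L || sum(boundary_axes == "NS") != 2L ||
      sum(boundary_axes == "EW") != 2L) {
    stop("exactly 2 boundaries must have long axis NS and 2 EW")
  }
  boundary_centres <- as.matrix(boundary_centres)
  if (!all(dim(boundary_centres) == c(4L, 2L))) {
    stop("boundary_centres must be a 4 x 2 matrix")
  }
  half <- explorable_extent / 2
  boundaries <- lapply(seq_len(4L), function(i) {
    axis <- boundary_axes[i]
    hl <- boundary_length / 2
    hw <- boundary_width / 2
    dx <- if (axis == "NS") hw else hl
    dy <- if (axis == "NS") hl else hw
    ctr <- boundary_centres[i, ]
    if (abs(ctr[1]) + dx >= half || abs(ctr[2]) + dy >= half) {
      stop("boundary ", i, " does not lie strictly inside the explorable extent")
    }
    list(id = i, texture_label = textures[i], centre_xy = ctr,
         long_axis = axis, length = boundary_length, width = boundary_width)
  })
  structure(
    list(arena_extent = arena_extent,
         explorable_extent = explorable_extent,
         boundaries = boundaries,
         landmark_compass = landmark_compass,
         boundary_mask_depth = mask_depth),
    class = "environment_spec")
}

# Landmark located at a given compass direction (inverse of landmark_compass).
landmark_at <- function(env, direction) {
  names(env$landmark_compass)[match(direction, env$landmark_compass)]
}

#' Landmark located at a clockwise offset from a facing landmark
#'
#' Answers questions of the form "which landmark is to the right of the
#' Mountain?": with the default layout, `relative_landmark("Mountain", 90)`
#' is the clock tower.
#'
#' @param facing Name of the landmark currently faced.
#' @param offset_deg Clockwise offset in degrees; multiple of 90.
#' @param env An `environment_spec`.
#' @return The landmark name at the offset direction.
#' @export
relative_landmark <- function(facing, offset_deg, env = build_environment()) {
  if (!facing %in% names(env$landmark_compass)) {
    stop("unknown landmark: ", facing)
  }
  landmark_at(env, compass_rotate(unname(env$landmark_compass[facing]), offset_deg))
}

# The two allocentric directions a wall can occupy relative to a viewer
# standing in front of one of its long faces. A wall whose long axis runs
# north-south has faces pointing east and west: a viewer west of the wall
# has the wall to their East.
.boundary_sides <- function(axis) if (axis == "NS") c("E", "W") else c("N", "S")

#' Enumerate the 24 passive paths
#'
#' Each of the 4 walls has 2 usable long faces (8 boundary sides); each
#' side is approached by 3 paths placing the wall egocentrically to the
#' front, left or right of the moving observer. Headings follow from the
#' compass geometry: a front path heads straight at the wall; a left
#' (right) path runs parallel to it with the wall 90 degrees
#' counterclockwise (clockwise) of the heading.
#'
#' @param env An `environment_spec`.
#' @return A data frame with one row per path: `path_id`, `boundary_id`,
#'   `texture_label`, `boundary_side` (the allocentric boundary direction),
#'   `ego_boundary`, `heading`, `facing_landmark`.
#' @export
enumerate_paths <- function(env = build_environment()) {
  rows <- list()
  pid <- 0L
  for (b in env$boundaries) {
    for (side in .boundary_sides(b$long_axis)) {
      for (ego in c("front", "left", "right")) {
        heading <- switch(ego,
          front = side,
          left  = compass_rotate(side, 90),   # wall on the left of the heading
          right = compass_rotate(side, -90))
        pid <- pid + 1L
        rows[[pid]] <- data.frame(
          path_id = pid, boundary_id = b$id, texture_label = b$texture_label,
          boundary_side = side, ego_boundary = ego, heading = heading,
          facing_landmark = landmark_at(env, heading),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Build randomised trial tables for the scanned task
#'
#' Each run presents every path `reps_per_run` times, with the cue object
#' on the left for half of the repetitions and on the right for the other
#' half, in seeded random order. Every trial lasts 8 s (2 s passive
#' movement, 4 s blank stationary phase, 2 s decision) followed by a
#' jittered inter-trial interval. The allocentric goal direction is the
#' heading rotated +90 degrees for a right cue and -90 for a left cue, and
#' the correct response is the landmark at that direction.
#'
#' @param paths Path table from [enumerate_paths()].
#' @param env The `environment_spec` the paths came from.
#' @param n_runs Number of runs (3).
#' @param reps_per_run Repetitions of each path per run (4); must be even
#'   so the cue side can be balanced.
#' @param iti_mean,iti_jitter Inter-trial interval distribution: uniform on
#'   `iti_mean` +/- `iti_jitter` seconds.
#' @param start_s Onset of the first trial, seconds from run start.
#' @param seed Design seed; the table is fully reproducible from it.
#' @return An object of class `trial_table`: a list with `runs` (one data
#'   frame of trial events per run), `design_seed`, and timing parameters.
#' @export
build_trial_table <- function(paths = enumerate_paths(env), env = build_environment(),
                              n_runs = 3, reps_per_run = 4,
                              iti_mean = 1.0, iti_jitter = 0.5,
                              start_s = 10, seed = 1L) {
  if (reps_per_run %% 2 != 0) {
    stop("reps_per_run must be even so cue sides split equally")
  }
  movement_s <- 2; blank_s <- 4; decision_s <- 2
  runs <- lapply(seq_len(n_runs), function(r) {
    base <- paths[rep(seq_len(nrow(paths)), each = reps_per_run), ]
    base$cue_side <- rep(rep(c("left", "right"), each = reps_per_run / 2),
                         times = nrow(paths))
    withr::with_seed(derive_seed(seed, r), {
      ord <- sample.int(nrow(base))
      iti <- runif(nrow(base), iti_mean - iti_jitter, iti_mean + iti_jitter)
    })
    tab <- base[ord, ]
    tab$run <- r
    tab$trial_index <- seq_len(nrow(tab)) - 1L
    tab$onset_s <- start_s + cumsum(c(0, (movement_s + blank_s + decision_s) + iti[-length(iti)]))
    tab$movement_duration <- movement_s
    tab$blank_duration <- blank_s
    tab$decision_duration <- decision_s
    tab$iti_s <- iti
    tab$allo_boundary <- tab$boundary_side
    tab$allo_goal <- compass_rotate(tab$heading,
                                    ifelse(tab$cue_side == "right", 90, -90))
    tab$correct_response_landmark <- landmark_at(env, tab$allo_goal)
    rownames(tab) <- NULL
    tab
  })
  structure(
    list(runs = runs, design_seed = seed,
         params = list(n_runs = n_runs, reps_per_run = reps_per_run,
                       iti_mean = iti_mean, iti_jitter = iti_jitter,
                       start_s = start_s, trial_span_s = movement_s + blank_s + decision_s)),
    class = "trial_table")
}

#' Enumerate the judgement-of-relative-direction (JRD) criterion questions
#'
#' All ordered pairs of distinct landmarks: the participant imagines facing
#' the first landmark and reports the direction of the second. Angular
#' disparity is the clockwise angle from facing to probe; 90 degrees maps
#' to a "right" response, 180 to "behind", 270 to "left".
#'
#' @param env An `environment_spec`.
#' @return A data frame of 12 questions: `facing_landmark`,
#'   `probe_landmark`, `angular_disparity`, `correct_response`.
#' @export
enumerate_jrd <- function(env = build_environment()) {
  lm <- names(env$landmark_compass)
  grid <- expand.grid(facing_landmark = lm, probe_landmark = lm,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$facing_landmark != grid$probe_landmark, ]
  deg <- .compass_deg[unname(env$landmark_compass[grid$probe_landmark])] -
    .compass_deg[unname(env$landmark_compass[grid$facing_landmark])]
  grid$angular_disparity <- as.integer(deg %% 360)
  grid$correct_response <- c(`90` = "right", `180` = "behind", `270` = "left")[
    as.character(grid$angular_disparity)]
  rownames(grid) <- NULL
  grid
}

#' Check the balance (orthogonality) properties of a trial table
#'
#' For each level of the grouping factor and each run, checks that cue
#' sides are equally frequent, that the three egocentric boundary positions
#' are equally frequent, that the boundary walls contributing to the level
#' appear equally often, and that all four levels of the other allocentric
#' factor are present. These are the properties that make boundary- and
#' goal-direction comparisons orthogonal.
#'
#' @param table A `trial_table`.
#' @param factor `"allo_boundary"` or `"allo_goal"`.
#' @return An object of class `balance_report`: list with `factor`, a
#'   `report` data frame of per-run, per-level flags, and overall `pass`.
#' @export
verify_balance <- function(table, factor = c("allo_boundary", "allo_goal")) {
  factor <- match.arg(factor)
  other <- setdiff(c("allo_boundary", "allo_goal"), factor)
  all_equal <- function(x) length(unique(x)) == 1L
  rows <- list()
  for (tab in table$runs) {
    for (lev in compass_directions()) {
      sub <- tab[tab[[factor]] == lev, ]
      cue <- table(factor(sub$cue_side, levels = c("left", "right")))
      ego <- table(factor(sub$ego_boundary, levels = c("front", "left", "right")))
      # within each boundary direction present at this level, the two
      # walls of that direction must contribute equally
      tex_ok <- all(vapply(split(sub$texture_label, sub$allo_boundary),
                           function(tx) all_equal(as.vector(table(tx))),
                           logical(1)))
      oth <- table(factor(sub[[other]], levels = compass_directions()))
      rows[[length(rows) + 1L]] <- data.frame(
        run = tab$run[1], level = lev, n_trials = nrow(sub),
        cue_balanced = all_equal(as.vector(cue)),
        ego_balanced = all_equal(as.vector(ego)),
        texture_balanced = tex_ok,
        other_factor_complete = all(oth > 0),
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  report$pass <- report$cue_balanced & report$ego_balanced &
    report$texture_balanced & report$other_factor_complete
  structure(list(factor = factor, report = report, pass = all(report$pass)),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance report for factor", x$factor, "-",
      if (x$pass) "all checks pass" else "FAILURES present", "\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
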