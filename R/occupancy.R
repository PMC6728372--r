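# Boundary-proximity occupancy analysis of free-exploration trajectories.

#' Boundary-proximity mask rectangles
#'
#' One mask per usable wall face (8 in total): a strip of the arena floor
#' `mask_depth` m deep and as long as the wall, attached to the face a
#' viewer stands in front of when the wall lies in the mask's direction.
#'
#' @param env An `environment_spec`.
#' @return Data frame of mask rectangles: `boundary_id`, `direction` (the
#'   allocentric boundary direction for a viewer inside the mask), and the
#'   rectangle edges `xmin`, `xmax`, `ymin`, `ymax` in metres.
#' @export
boundary_masks <- function(env = build_environment()) {
  d <- env$boundary_mask_depth
  rows <- list()
  for (b in env$boundaries) {
    hl <- b$length / 2
    hw <- b$width / 2
    cx <- b$centre_xy[1]; cy <- b$centre_xy[2]
    for (side in .boundary_sides(b$long_axis)) {
      # A viewer with the wall to side `side` stands on the opposite side
      # of the wall: mask for side E sits against the west face, etc.
      rect <- switch(side,
        E = c(cx - hw - d, cx - hw, cy - hl, cy + hl),
        W = c(cx + hw, cx + hw + d, cy - hl, cy + hl),
        N = c(cx - hl, cx + hl, cy - hw - d, cy - hw),
        S = c(cx - hl, cx + hl, cy + hw, cy + hw + d))
      rows[[length(rows) + 1L]] <- data.frame(
        boundary_id = b$id, direction = side,
        xmin = rect[1], xmax = rect[2], ymin = rect[3], ymax = rect[4])
    }
  }
  do.call(rbind, rows)
}

#' Occupancy histogram and boundary-proximity fractions for a trajectory
#'
#' Divides the explorable area into a 100 x 100 grid of 5 x 5 m bins
#' (10,000 bins), accumulates time-weighted occupancy normalised to sum to
#' 1, and reports the fraction of time spent inside the eight 40 x 5 m
#' boundary-proximity masks, aggregated by allocentric boundary direction
#' and in total. Each sampled position is weighted by the time elapsed
#' until the next sample; a single-point trajectory gets unit weight.
#'
#' @param trajectory Data frame with columns `t` (seconds, strictly
#'   increasing), `x`, `y` (metres, inside the explorable extent).
#' @param env An `environment_spec`.
#' @return List with `histogram` (100 x 100 matrix summing to 1),
#'   `per_direction` (named fractions for N/S/E/W), and `total`.
#' @export
occupancy_fraction <- function(trajectory, env = build_environment()) {
  if (is.null(trajectory) || nrow(trajectory) == 0L) {
    stop("trajectory is empty")
  }
  t <- trajectory$t; x <- trajectory$x; y <- trajectory$y
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  half <- env$explorable_extent / 2
  if (any(abs(x) > half) || any(abs(y) > half)) {
    stop("positions must lie within the explorable extent")
  }
  if (nrow(trajectory) == 1L) {
    w <- 1
  } else {
    w <- diff(t)
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  w <- w / sum(w)

  n_bins <- round(env$explorable_extent / 5)
  ix <- pmin(pmax(floor((x + half) / 5) + 1L, 1L), n_bins)
  iy <- pmin(pmax(floor((y + half) / 5) + 1L, 1L), n_bins)
  hist <- matrix(0, n_bins, n_bins)
  for (i in seq_along(w)) hist[ix[i], iy[i]] <- hist[ix[i], iy[i]] + w[i]

  masks <- boundary_masks(env)
  in_mask <- function(m) x >= m["xmin"] & x <= m["xmax"] & y >= m["ymin"] & y <= m["ymax"]
  per_dir <- vapply(compass_directions(), function(d) {
    sub <- masks[masks$direction == d, ]
    inside <- rep(FALSE, length(x))
    for (i in seq_len(nrow(sub))) {
      inside <- inside | in_mask(unlist(sub[i, c("xmin", "xmax", "ymin", "ymax")]))
    }
    sum(w[inside])
  }, numeric(1))
  list(histogram = hist, per_direction = per_dir, total = sum(per_dir))
}
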