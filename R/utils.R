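# Compass convention used throughout: N = +y, E = +x, clockwise-positive
# angles, so N/E/S/W sit at 0/90/180/270 degrees and "right" = +90 degrees.
.compass_deg <- c(N = 0, E = 90, S = 180, W = 270)

compass_directions <- function() names(.compass_deg)

#' Rotate a compass direction by a clockwise offset
#'
#' @param direction Character vector of compass directions (`"N"`, `"E"`,
#'   `"S"`, `"W"`).
#' @param offset_deg Clockwise rotation in degrees; must be a multiple of 90.
#' @return Character vector of rotated compass directions.
#' @examples
#' compass_rotate("N", 90)   # "E"
#' compass_rotate("S", 180)  # "N"
#' @export
compass_rotate <- function(direction, offset_deg) {
  if (any(!direction %in% names(.compass_deg))) {
    stop("unknown compass direction: ", paste(setdiff(direction, names(.compass_deg)), collapse = ", "))
  }
  if (any(offset_deg %% 90 != 0)) {
    stop("offset_deg must be a multiple of 90 degrees")
  }
  deg <- (.compass_deg[direction] + offset_deg) %% 360
  unname(names(.compass_deg)[match(deg, .compass_deg)])
}

# Deterministically derive a child seed from a parent seed and integer
# indices. Keeps every product below 2^53 so double arithmetic is exact,
# and every result below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
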