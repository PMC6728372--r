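# Readers and writers for the on-disk layout: BIDS-style events and
# confounds TSV, NIfTI ROI series with JSON sidecars, and result JSON.

#' Write one events TSV per run (BIDS events dialect)
#'
#' Columns: onset, duration, trial_type, path_id, cue_side, allo_boundary,
#' allo_goal, ego_boundary, facing_landmark, response_landmark; onset and
#' duration in seconds with 3-decimal fixed point. A sidecar JSON records
#' the design seed.
#'
#' @param table A `trial_table`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_events_tsv <- function(table, dir, prefix = "sub-01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(table$runs), function(r) {
    tab <- table$runs[[r]]
    out <- data.frame(
      onset = sprintf("%.3f", tab$onset_s),
      duration = sprintf("%.3f", tab$movement_duration + tab$blank_duration +
                           tab$decision_duration),
      trial_type = sprintf("path%02d", tab$path_id),
      path_id = tab$path_id,
      cue_side = tab$cue_side,
      allo_boundary = tab$allo_boundary,
      allo_goal = tab$allo_goal,
      ego_boundary = tab$ego_boundary,
      facing_landmark = tab$facing_landmark,
      response_landmark = tab$correct_response_landmark,
      stringsAsFactors = FALSE)
    f <- file.path(dir, sprintf("%s_run-%d_events.tsv", prefix, r))
    write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }, character(1))
  jsonlite::write_json(list(design_seed = table$design_seed,
                            params = table$params),
                       file.path(dir, sprintf("%s_events.json", prefix)),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read one run's events TSV
#'
#' @param path Path to a TSV written by [write_events_tsv()].
#' @return Data frame with numeric `onset_s` and the condition columns.
#' @export
read_events_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$onset_s <- as.numeric(tab$onset)
  tab$duration_s <- as.numeric(tab$duration)
  tab
}

#' Write a confounds TSV (6 motion columns)
#'
#' @param motion A `motion_series` (6 x T).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_confounds_tsv <- function(motion, path) {
  df <- as.data.frame(t(unclass(motion)))
  names(df) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a confounds TSV back into a motion series
#'
#' @param path Path to a confounds TSV.
#' @return A `motion_series` (6 x T).
#' @export
read_confounds_tsv <- function(path) {
  df <- read.delim(path)
  m <- t(as.matrix(df))
  structure(m, class = c("motion_series", "matrix"))
}

#' Write an ROI time series as NIfTI with a JSON sidecar
#'
#' Voxels are unravelled along the first spatial axis of a 4-D image
#' (n_voxels x 1 x 1 x T); the sidecar records the ROI label, run and TR.
#'
#' @param ts An `roi_timeseries`.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_roi_nifti <- function(ts, path) {
  img <- array(ts$data, dim = c(nrow(ts$data), 1, 1, ncol(ts$data)))
  RNifti::writeNifti(RNifti::asNifti(img, pixdim = c(1.5, 1.5, 1.5, ts$tr_s)),
                     path)
  jsonlite::write_json(
    list(roi_label = ts$roi_label, run = ts$run, tr_s = ts$tr_s,
         n_voxels = nrow(ts$data), n_volumes = ts$n_volumes),
    sub("\\.nii(\\.gz)?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI time series written by [write_roi_nifti()]
#'
#' @param path Path to the NIfTI file.
#' @return An `roi_timeseries`.
#' @export
read_roi_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  d <- dim(img)
  structure(list(roi_label = meta$roi_label,
                 data = matrix(as.numeric(img), d[1], d[4]),
                 tr_s = meta$tr_s, n_volumes = d[4], run = meta$run),
            class = "roi_timeseries")
}

# Persist one simulated participant under out_dir/sub-XX/.
write_participant <- function(p, out_dir) {
  sub <- sprintf("sub-%02d", p$participant)
  dir <- file.path(out_dir, sub)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_events_tsv(p$table, dir, prefix = sub)
  for (r in seq_along(p$motion)) {
    write_confounds_tsv(p$motion[[r]],
                        file.path(dir, sprintf("%s_run-%d_confounds.tsv", sub, r)))
  }
  for (roi in p$rois) {
    for (r in seq_along(roi$runs)) {
      write_roi_nifti(roi$runs[[r]],
                      file.path(dir, sprintf("%s_run-%d_roi-%s.nii.gz",
                                             sub, r, roi$config$label)))
    }
  }
  invisible(dir)
}
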