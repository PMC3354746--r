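# Small phantom used by the unit tests: same structure as the default, a
# quarter of the voxels, so each pipeline run stays around two seconds.
small_phantom_spec <- function(seed = 1, ...) {
  args <- list(shape = c(80, 112, 24), spacing = c(1, 1, 2),
               breast_radius_mm = 16, band_row_frac = 0.75,
               center_depth_mm = 5, dense_fraction = 0.2, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# Truth labels restricted to one breast ROI (cropped at the frontier row,
# opposite side of the split column zeroed), for stage-level comparisons.
roi_truth <- function(truth, roi) {
  tr <- truth$labels[seq_len(roi$chest_row[1]), , , drop = FALSE]
  if (roi$side == "LEFT") tr[, seq(roi$split_col, dim(tr)[2]), ] <- 0L
  else tr[, seq_len(roi$split_col), ] <- 0L
  tr
}
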