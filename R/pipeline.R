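#' Configuration of the full skin-segmentation pipeline
#'
#' Collects every stage parameter with defaults that reproduce the method's
#' published operating point: curvature flow at `time_step = 0.0625` for 10
#' iterations, background clearing at level 6 of 255, a 4-cluster partition
#' re-split with 2 clusters, and a 3 mm skin-depth limit in the nipple
#' region.
#'
#' @param time_step,iterations Curvature-flow parameters.
#' @param level_255 Low-threshold level on a 0–255 scale.
#' @param k1,k2 Cluster counts of the two C-means stages (4, then 2).
#' @param seed Master seed; each clustering stage derives its own from it.
#' @param skin A [skin_params()] object.
#' @param fixed_thickness_mm `NULL` for the adaptive method (default), or a
#'   thickness in mm to run the fixed-shell baseline instead.
#' @param sides Which breasts to process: `"both"`, `"left"`, `"right"`.
#' @param band_fraction,grad_quantile Frontier-search parameters of
#'   [split_breasts()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(time_step = 0.0625, iterations = 10L,
                            level_255 = 6, k1 = 4L, k2 = 2L, seed = 1L,
                            skin = skin_params(),
                            fixed_thickness_mm = NULL,
                            sides = c("both", "left", "right"),
                            band_fraction = 1 / 3, grad_quantile = 0.9) {
  sides <- match.arg(sides)
  stopifnot(inherits(skin, "skin_params"))
  if (k1 != 4L || k2 != 2L)
    warning("non-default cluster counts: the label mapping assumes k1 = 4, k2 = 2")
  structure(list(time_step = time_step, iterations = as.integer(iterations),
                 level_255 = level_255, k1 = as.integer(k1),
                 k2 = as.integer(k2), seed = as.integer(seed), skin = skin,
                 fixed_thickness_mm = fixed_thickness_mm, sides = sides,
                 band_fraction = band_fraction, grad_quantile = grad_quantile),
            class = "pipeline_config")
}

label_counts <- function(lab) {
  as.list(table(factor(lab, levels = label_codes(),
                       labels = names(label_codes()))))
}

#' Run the full skin-segmentation pipeline
#'
#' Executes the staged process on a volume: breast/axial separation, then
#' per breast — curvature flow, low threshold, 4-cluster partition,
#' re-clustering of the mixed clusters, largest-object selection,
#' open–close border smoothing, skin/dense separation (or the
#' fixed-thickness baseline), isolated-dense absorption, interior
#' smoothness filtering, 3D skin closure, skin deletion, and fat/dense
#' segmentation of the skin-free tissue. Every stage is logged with its
#' parameters and the per-class voxel counts after it; the run is
#' deterministic for a fixed config.
#'
#' @param volume A [gray_volume()], or a path to a DICOM directory or
#'   NIfTI file.
#' @param config A [pipeline_config()].
#' @return Object of class `skin_pipeline_result`: `labels` (full-size
#'   final [label_volume()]; rows posterior to the frontier are background),
#'   `rois` (per-breast results with cropped `labels`, `skin_free` volume
#'   and density report), `skin_free` (full-size volume with skin deleted),
#'   `density`, `frontier`, `stage_log`, `config`.
#' @export
run_pipeline <- function(volume, config = pipeline_config()) {
  if (is.character(volume)) {
    volume <- if (dir.exists(volume)) read_dicom_series(volume)
      else read_volume(volume)
  }
  stopifnot(inherits(volume, "gray_volume"), inherits(config, "pipeline_config"))

  log <- list()
  note <- function(stage, params, lab = NULL) {
    log[[length(log) + 1L]] <<- list(
      stage = stage, params = params,
      counts = if (!is.null(lab)) label_counts(lab) else NULL)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("pipeline_error", "error", "condition"),
                     list(message = paste0("stage '", stage, "' failed: ",
                                           conditionMessage(e)),
                          call = sys.call(-1), stage = stage,
                          partial = list(stage_log = log))))
    })
  }

  split <- run_stage("split_breasts",
                     split_breasts(volume, config$band_fraction,
                                   config$grad_quantile))
  note("split_breasts", list(band_fraction = config$band_fraction,
                             grad_quantile = config$grad_quantile,
                             frontier = split$frontier))

  sides <- switch(config$sides, both = c("left", "right"),
                  left = "left", right = "right")
  rois <- list()
  for (side in sides) {
    roi <- split[[side]]
    v0 <- roi$volume
    seed_side <- config$seed + if (side == "left") 0L else 1000L

    v1 <- run_stage("curvature_flow",
                    curvature_flow(v0, config$time_step, config$iterations))
    note(paste0(side, ":curvature_flow"),
         list(time_step = config$time_step, iterations = config$iterations))
    v2 <- run_stage("low_threshold", low_threshold(v1, config$level_255))
    note(paste0(side, ":low_threshold"), list(level_255 = config$level_255))

    lab <- run_stage("partition_4", partition_4(v2, seed = seed_side))
    note(paste0(side, ":partition_4"), list(k = config$k1, seed = seed_side),
         lab$labels)
    lab <- run_stage("recluster_mixed",
                     recluster_mixed(v0, lab, seed = seed_side + 1L))
    note(paste0(side, ":recluster_mixed"),
         list(k = config$k2, seed = seed_side + 1L), lab$labels)

    lab <- run_stage("largest_foreground", largest_foreground(lab))
    note(paste0(side, ":largest_foreground"), list(connectivity = 26L),
         lab$labels)
    lab <- run_stage("open_close", open_close(lab))
    note(paste0(side, ":open_close"), list(element = "3x3 box"), lab$labels)

    if (is.null(config$fixed_thickness_mm)) {
      lab <- run_stage("separate_skin_dense",
                       separate_skin_dense(v0, lab, config$skin))
      note(paste0(side, ":separate_skin_dense"), config$skin[], lab$labels)
      lab <- run_stage("absorb_isolated_dense",
                       absorb_isolated_dense(lab, config$skin))
      note(paste0(side, ":absorb_isolated_dense"), NULL, lab$labels)
      lab <- run_stage("interior_smoothness",
                       interior_smoothness(lab, config$skin))
      note(paste0(side, ":interior_smoothness"),
           list(max_iter = config$skin$smooth_max_iter), lab$labels)
    } else {
      lab <- run_stage("fixed_thickness_skin",
                       fixed_thickness_skin(lab, config$fixed_thickness_mm))
      note(paste0(side, ":fixed_thickness_skin"),
           list(thickness_mm = config$fixed_thickness_mm), lab$labels)
    }
    lab <- run_stage("close_skin_3d", close_skin_3d(lab, config$skin))
    note(paste0(side, ":close_skin_3d"),
         list(connectivity = config$skin$connectivity_3d), lab$labels)

    skin_free <- run_stage("apply_skin_mask", apply_skin_mask(v0, lab))
    note(paste0(side, ":apply_skin_mask"), NULL)
    lab <- run_stage("segment_fat_dense",
                     segment_fat_dense(skin_free, lab, seed = seed_side + 2L))
    note(paste0(side, ":segment_fat_dense"),
         list(k = 2L, seed = seed_side + 2L), lab$labels)

    rois[[side]] <- list(side = roi$side, labels = lab, skin_free = skin_free,
                         split_col = roi$split_col, chest_row = roi$chest_row,
                         density = density_report(lab))
  }

  d <- dim(volume$data)
  full <- array(BG, d)
  chest_row <- split$frontier["row"]
  for (side in names(rois)) {
    lab <- rois[[side]]$labels$labels
    keep <- lab != BG
    sub <- full[seq_len(chest_row), , , drop = FALSE]
    sub[keep] <- lab[keep]
    full[seq_len(chest_row), , ] <- sub
  }
  full_labels <- label_volume(full, volume$spacing)
  skin_free_full <- apply_skin_mask(volume, full_labels)

  structure(list(labels = full_labels, rois = rois,
                 skin_free = skin_free_full,
                 density = density_report(full_labels),
                 frontier = split$frontier, stage_log = log,
                 config = config),
            class = "skin_pipeline_result")
}

#' @export
print.skin_pipeline_result <- function(x, ...) {
  cat("<skin_pipeline_result>\n")
  cat(sprintf("  frontier: row %d, col %d; sides: %s\n",
              x$frontier["row"], x$frontier["col"],
              paste(names(x$rois), collapse = ", ")))
  cat(sprintf("  dense fraction: %.3f (%d dense / %d breast voxels)\n",
              x$density$dense_fraction, x$density$dense_voxels,
              x$density$breast_voxels))
  cat(sprintf("  stages logged: %d\n", length(x$stage_log)))
  invisible(x)
}

#' Check the skin-closure invariant
#'
#' After [close_skin_3d()] no `FAT` or `DENSE` voxel may have a
#' `BACKGROUND` neighbour under the chosen 3D connectivity. Returns the
#' number of violating voxels (0 when the invariant holds).
#'
#' @param labels A [label_volume()].
#' @param connectivity 6 (default) or 26.
#' @return Integer count of exposed internal-tissue voxels.
#' @export
exposed_tissue_count <- function(labels, connectivity = 6L) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  offs <- if (connectivity == 6L) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    o <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
    o <- o[rowSums(abs(o)) > 0, ]
    lapply(seq_len(nrow(o)), function(i) as.numeric(o[i, ]))
  }
  bg <- lab == BG
  near_bg <- Reduce(`|`, lapply(offs, function(o)
    shift3(bg, o[1], o[2], o[3], pad = FALSE)))
  sum((lab == FAT | lab == DENSE) & near_bg)
}
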