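#' Fat/dense segmentation of the skin-free breast
#'
#' With the skin removed, a 2-cluster [c_means()] over the remaining breast
#' voxels separates the two major tissues; under T2 contrast the brighter
#' cluster is `FAT` and the darker `DENSE`. Voxels outside the mask keep
#' their labels (skin and background pass through untouched), so the result
#' is governed by the mask alone — whether skin voxels were zeroed or
#' cropped in the intensity volume is irrelevant.
#'
#' @param skin_free A [gray_volume()] with the skin deleted.
#' @param mask Either a logical array selecting the breast-interior voxels
#'   to cluster, or a [label_volume()] from the skin stage (then the mask is
#'   its `FAT`/`DENSE` voxels and `SKIN`/`BACKGROUND` pass through).
#' @param seed Seed forwarded to [c_means()].
#' @return A [label_volume()] with the clustering model attached as
#'   attribute `"model"`.
#' @export
segment_fat_dense <- function(skin_free, mask, seed = 1L) {
  stopifnot(inherits(skin_free, "gray_volume"))
  if (inherits(mask, "label_volume")) {
    base <- mask$labels
    sel <- base == FAT | base == DENSE
  } else {
    sel <- as_volume_array(mask)
    if (!is.logical(sel)) stop("mask must be logical or a label_volume")
    base <- array(BG, dim(sel))
  }
  if (!identical(dim(sel), dim(skin_free$data)))
    stop("mask and volume have different shapes")
  vals <- skin_free$data[sel]
  if (length(unique(vals)) < 2L)
    stop("need at least 2 distinct masked intensities to split fat and dense")
  cm <- c_means(vals, k = 2L, seed = seed)
  lab <- base
  lab[sel] <- ifelse(cm$assignment == 2L, FAT, DENSE)  # means ascending
  out <- label_volume(lab, skin_free$spacing)
  attr(out, "model") <- cm
  out
}

#' Breast density report
#'
#' Dense-tissue volume fraction of the breast: dense voxels over all
#' breast-tissue voxels (`FAT + DENSE`; skin excluded).
#'
#' @param labels A final [label_volume()].
#' @return List with `dense_voxels`, `fat_voxels`, `breast_voxels`,
#'   `dense_fraction`.
#' @export
density_report <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  nd <- sum(labels$labels == DENSE)
  nf <- sum(labels$labels == FAT)
  list(dense_voxels = nd, fat_voxels = nf, breast_voxels = nd + nf,
       dense_fraction = if (nd + nf > 0) nd / (nd + nf) else NA_real_)
}
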