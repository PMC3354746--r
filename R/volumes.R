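#' Tissue label codes
#'
#' Fixed integer codes used by every label volume in the package. The codes
#' are a stable on-disk contract: `BACKGROUND = 0`, `SKIN = 1`, `FAT = 2`,
#' `DENSE = 3`. `MIXED = 4` is a transient class that may only exist between
#' the 4-cluster intensity partition and the re-clustering of its two middle
#' clusters; it never appears in final output.
#'
#' @return Named integer vector of label codes.
#' @export
#' @examples
#' label_codes()
label_codes <- function() {
  c(BACKGROUND = 0L, SKIN = 1L, FAT = 2L, DENSE = 3L, MIXED = 4L)
}

BG <- 0L
SKIN <- 1L
FAT <- 2L
DENSE <- 3L
MIXED <- 4L

#' 3D grayscale volume with voxel spacing
#'
#' A thin container for a scalar 3D image: a `(row, col, slice)` array of
#' intensities plus the physical voxel spacing in millimetres per axis.
#' Row index increases toward posterior (the chest) and slice index runs
#' along the scanner axis; slices are always ordered by spatial position.
#'
#' @param data Numeric 3D array, dimensions `(rows, cols, slices)`.
#' @param spacing Numeric length-3 vector `(row_mm, col_mm, slice_mm)`,
#'   strictly positive and finite.
#' @return An object of class `gray_volume` with fields `data`, `spacing`
#'   and `intensity_range`.
#' @export
gray_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as_volume_array(data)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values (mm)")
  if (any(!is.finite(data)))
    stop("volume data contains NaN or Inf")
  d <- dim(data)
  if (d[3] < 1L || d[1] < 8L || d[2] < 8L)
    stop("volume too small: need >= 1 slice and >= 8 rows and cols")
  structure(
    list(data = data, spacing = spacing,
         intensity_range = range(data)),
    class = "gray_volume")
}

#' 3D categorical label volume
#'
#' Companion of [gray_volume()]: an integer array over the classes of
#' [label_codes()], with the spacing inherited from its source volume. Every
#' voxel carries exactly one class.
#'
#' @param labels Integer 3D array of label codes.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param allow_mixed Permit the transient `MIXED` class (default `FALSE`).
#' @return An object of class `label_volume` with fields `labels`, `spacing`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), allow_mixed = FALSE) {
  labels <- as_volume_array(labels)
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values (mm)")
  valid <- label_codes()
  if (!allow_mixed) valid <- valid[names(valid) != "MIXED"]
  if (anyNA(labels) || !all(labels %in% valid))
    stop("labels contain codes outside ", paste(valid, collapse = "/"))
  structure(list(labels = labels, spacing = spacing),
            class = "label_volume")
}

# Coerce matrix-or-array input to a 3D array without copying values.
as_volume_array <- function(x) {
  if (is.null(dim(x))) stop("expected a matrix or 3D array")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected a 3D array")
  x
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gray_volume> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              x$intensity_range[1], x$intensity_range[2]))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(x$labels, levels = label_codes(),
                      labels = names(label_codes())))
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  print(tab)
  invisible(x)
}

#' @export
dim.gray_volume <- function(x) dim(x$data)

#' @export
dim.label_volume <- function(x) dim(x$labels)

# Shift a 3D array by (dr, dc, ds), padding out-of-range positions.
# pad = "replicate" repeats the border plane; a numeric pad fills with that
# value. Used by the finite-difference and neighbourhood operators.
shift3 <- function(a, dr = 0L, dc = 0L, ds = 0L, pad = "replicate") {
  d <- dim(a)
  idx <- function(n, k) {
    i <- seq_len(n) - k
    if (identical(pad, "replicate")) pmin(pmax(i, 1L), n) else i
  }
  ir <- idx(d[1], dr); ic <- idx(d[2], dc); is <- idx(d[3], ds)
  if (identical(pad, "replicate")) {
    a[ir, ic, is, drop = FALSE]
  } else {
    out <- array(pad, d)
    okr <- ir >= 1L & ir <= d[1]
    okc <- ic >= 1L & ic <= d[2]
    oks <- is >= 1L & is <= d[3]
    out[okr, okc, oks] <- a[ir[okr], ic[okc], is[oks], drop = FALSE]
    out
  }
}

# Connected components of a logical mask (2D or 3D); connectivity 4/8 label
# within-slice, 6/18/26 in 3D. Thin wrapper over the compiled BFS.
connected_components <- function(mask, connectivity) {
  stopifnot(is.logical(mask))
  d <- dim(mask)
  if (is.null(d)) stop("mask must be a matrix or array")
  .cc_label_cpp(mask, as.integer(d), as.integer(connectivity))
}

# Euclidean distance (mm) from voxels inside `mask` to the nearest voxel
# outside it; 0 outside the mask, Inf if the mask fills the grid.
distance_to_background <- function(mask, spacing) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be a matrix or array")
  .edt_cpp(mask, as.integer(d), as.numeric(spacing))
}
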