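#' Read a single-file volume (NIfTI)
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [gray_volume()] with spacing taken from the file's pixel
#'   dimensions.
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  a <- array(as.numeric(im), dim(im))
  sp <- RNifti::pixdim(im)
  if (length(sp) < 3 || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    sp <- c(1, 1, 1)
  gray_volume(a, sp[1:3])
}

#' Write a gray volume to NIfTI
#'
#' @param volume A [gray_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "gray_volume"))
  im <- RNifti::asNifti(volume$data)
  RNifti::pixdim(im) <- volume$spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

labelmap_codes_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".codes.json")
}

#' Write a label map with its code table
#'
#' Writes the integer-coded labels as a NIfTI volume and the class/code
#' table as a JSON file alongside (`<name>.codes.json`), so the on-disk
#' artifact is self-describing. Write–read round-trips preserve every
#' voxel. Refuses to write the transient `MIXED` class.
#'
#' @param labels A final [label_volume()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_labelmap <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  if (any(labels$labels == MIXED))
    stop("labels contain the transient MIXED class; finish the pipeline first")
  im <- RNifti::asNifti(labels$labels)
  RNifti::pixdim(im) <- labels$spacing
  RNifti::writeNifti(im, path, datatype = "int16")
  codes <- label_codes()
  codes <- codes[names(codes) != "MIXED"]
  jsonlite::write_json(as.list(codes), labelmap_codes_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a label map written by [write_labelmap()]
#'
#' @param path Path to the label NIfTI.
#' @return A [label_volume()].
#' @export
read_labelmap <- function(path) {
  im <- RNifti::readNifti(path)
  a <- array(as.integer(im), dim(im))
  sp <- RNifti::pixdim(im)
  if (length(sp) < 3 || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    sp <- c(1, 1, 1)
  cp <- labelmap_codes_path(path)
  if (file.exists(cp)) {
    codes <- unlist(jsonlite::read_json(cp))
    expected <- label_codes()[names(codes)]
    if (!identical(as.integer(codes), as.integer(expected)))
      stop("code table at ", cp, " does not match the package label codes")
  }
  label_volume(a, sp[1:3])
}

#' Delete the skin from a volume using its label map
#'
#' Sets every voxel labelled `SKIN` to the background intensity (0),
#' leaving all other voxels untouched — the final step that readies the
#' volume for skin-free tissue analysis.
#'
#' @param volume A [gray_volume()].
#' @param labels A [label_volume()] of the same shape.
#' @return A [gray_volume()] with the skin deleted.
#' @export
apply_skin_mask <- function(volume, labels) {
  stopifnot(inherits(volume, "gray_volume"), inherits(labels, "label_volume"))
  if (!identical(dim(volume$data), dim(labels$labels)))
    stop("volume and labels have different shapes")
  a <- volume$data
  a[labels$labels == SKIN] <- 0
  gray_volume(a, volume$spacing)
}
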