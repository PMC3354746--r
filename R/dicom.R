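# Minimal DICOM codec: uncompressed single-frame little-endian files only
# (explicit VR written; explicit and implicit VR read). The installed stack
# has no DICOM reader, so the handful of tags a volume needs — geometry,
# spacing, rescale and pixel data — is parsed here directly.

u16 <- function(raw, pos) {
  readBin(raw[pos:(pos + 1)], "integer", size = 2, endian = "little",
          signed = FALSE)
}
u32 <- function(raw, pos) {
  lo <- u16(raw, pos)
  hi <- u16(raw, pos + 2)
  hi * 65536 + lo
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

tag_key <- function(group, elem) sprintf("%04X%04X", group, elem)

# Parse one data element starting at pos; returns list(key, value_raw, next_pos)
parse_element <- function(raw, pos, explicit) {
  group <- u16(raw, pos)
  elem <- u16(raw, pos + 2)
  if (explicit) {
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- u32(raw, pos + 8)
      val_at <- pos + 12
    } else {
      len <- u16(raw, pos + 6)
      val_at <- pos + 8
    }
  } else {
    vr <- NA_character_
    len <- u32(raw, pos + 4)
    val_at <- pos + 8
  }
  if (len == 4294967295)
    stop("undefined-length element (", tag_key(group, elem),
         "): sequences are not supported")
  if (val_at + len - 1 > length(raw))
    stop("truncated DICOM element ", tag_key(group, elem))
  list(group = group, elem = elem, key = tag_key(group, elem),
       value = if (len > 0) raw[val_at:(val_at + len - 1)] else raw(0),
       next_pos = val_at + len)
}

dicom_str <- function(v) {
  v <- v[v != as.raw(0)]  # strip NUL padding (rawToChar rejects embedded NULs)
  if (!length(v)) return("")
  trimws(rawToChar(v))
}
dicom_ds <- function(v) {
  s <- dicom_str(v)
  if (!nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dicom_us <- function(v) u16(v, 1)

read_dicom_file <- function(path) {
  n <- file.info(path)$size
  raw <- readBin(path, "raw", n)
  if (n < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133
  meta <- list()
  while (pos + 7 <= n && u16(raw, pos) == 2L) {
    el <- parse_element(raw, pos, explicit = TRUE)
    meta[[el$key]] <- el$value
    pos <- el$next_pos
  }
  ts <- dicom_str(meta[["00020010"]])
  explicit <- if (ts == "1.2.840.10008.1.2") FALSE
    else if (ts %in% c("1.2.840.10008.1.2.1", "")) TRUE
    else stop("unsupported transfer syntax ", ts, " in ", path)
  el <- list()
  while (pos + 7 <= n) {
    e <- parse_element(raw, pos, explicit)
    el[[e$key]] <- e$value
    pos <- e$next_pos
    if (e$key == "7FE00010") break
  }
  rows <- dicom_us(el[["00280010"]])
  cols <- dicom_us(el[["00280011"]])
  bits <- if (!is.null(el[["00280100"]])) dicom_us(el[["00280100"]]) else 16L
  if (bits != 16L) stop("only 16-bit pixel data is supported")
  signed <- !is.null(el[["00280103"]]) && dicom_us(el[["00280103"]]) == 1L
  px_raw <- el[["7FE00010"]]
  if (is.null(px_raw)) stop("no pixel data in ", path)
  px <- readBin(px_raw, "integer", n = length(px_raw) / 2, size = 2,
                endian = "little", signed = signed)
  if (length(px) != rows * cols)
    stop("pixel data size does not match Rows x Columns in ", path)
  slope <- if (length(dicom_ds(el[["00281053"]]))) dicom_ds(el[["00281053"]]) else 1
  intercept <- if (length(dicom_ds(el[["00281052"]]))) dicom_ds(el[["00281052"]]) else 0
  # pixel stream is row-major; transpose into R's column-major (row, col)
  img <- t(matrix(px, nrow = cols, ncol = rows))
  img <- img * slope + intercept
  img[img < 0] <- 0  # stored values treated as unsigned magnitudes

  list(img = img,
       series_uid = dicom_str(el[["0020000E"]]),
       instance = suppressWarnings(as.integer(dicom_str(el[["00200013"]]))),
       position = dicom_ds(el[["00200032"]]),
       orientation = dicom_ds(el[["00200037"]]),
       pixel_spacing = dicom_ds(el[["00280030"]]),
       slice_thickness = dicom_ds(el[["00180050"]]),
       spacing_between = dicom_ds(el[["00180088"]]))
}

#' Read a DICOM series into a gray volume
#'
#' Reads every single-frame DICOM file of a directory, checks that they
#' belong to one series, sorts the slices by their spatial position along
#' the slice normal (never by filename), and assembles a [gray_volume()].
#' Pixel spacing is taken from the pixel-spacing tag and the slice step from
#' the sorted positions (falling back to spacing-between-slices, then slice
#' thickness); stored intensities are preserved, with any rescale
#' slope/intercept applied and negatives clamped to zero.
#'
#' @param directory_path Directory holding one DICOM series.
#' @return A [gray_volume()].
#' @export
read_dicom_series <- function(directory_path) {
  files <- list.files(directory_path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no series: directory contains no files")
  slices <- lapply(files, read_dicom_file)

  uids <- unique(vapply(slices, function(s) s$series_uid, ""))
  if (length(uids) > 1L)
    stop("ambiguous series: directory mixes ", length(uids), " series UIDs")

  # order along the slice normal (cross product of the orientation vectors)
  ord_key <- vapply(slices, function(s) {
    o <- s$orientation
    p <- s$position
    if (length(o) == 6 && length(p) == 3) {
      r <- o[1:3]; c <- o[4:6]
      nrm <- c(r[2] * c[3] - r[3] * c[2],
               r[3] * c[1] - r[1] * c[3],
               r[1] * c[2] - r[2] * c[1])
      sum(p * nrm)
    } else if (length(p) == 3) p[3]
    else NA_real_
  }, 0)
  if (anyNA(ord_key)) {
    inst <- vapply(slices, function(s)
      if (is.na(s$instance)) NA_real_ else as.numeric(s$instance), 0)
    ord_key <- if (anyNA(inst)) seq_along(slices) else inst
  }
  slices <- slices[order(ord_key)]
  ord_key <- sort(ord_key)

  dims <- vapply(slices, function(s) dim(s$img), c(0L, 0L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("slices disagree on image size")

  ps <- slices[[1]]$pixel_spacing
  missing_inplane <- length(ps) != 2 || any(!is.finite(ps))
  if (missing_inplane) ps <- c(1, 1)
  dz <- if (length(slices) > 1 && all(is.finite(ord_key)))
    stats::median(abs(diff(ord_key))) else NA_real_
  if (!isTRUE(dz > 0)) {
    dz <- if (length(slices[[1]]$spacing_between)) slices[[1]]$spacing_between[1]
      else if (length(slices[[1]]$slice_thickness)) slices[[1]]$slice_thickness[1]
      else NA_real_
  }
  missing_slice <- !isTRUE(dz > 0)
  if (missing_slice) dz <- 2
  if (missing_inplane || missing_slice)
    warning("missing spacing tags; defaulting to (2, 1, 1) mm where absent")

  a <- array(0, c(dims[1, 1], dims[2, 1], length(slices)))
  for (i in seq_along(slices)) a[, , i] <- slices[[i]]$img
  gray_volume(a, c(ps[1], ps[2], dz))
}

raw_u16 <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))
}

el_raw <- function(group, elem, vr, value) {
  head <- c(raw_u16(group), raw_u16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    lo <- length(value) %% 65536
    hi <- length(value) %/% 65536
    c(head, as.raw(c(0, 0)), raw_u16(lo), raw_u16(hi), value)
  } else {
    c(head, raw_u16(length(value)), value)
  }
}
el_str <- function(group, elem, vr, s) {
  v <- charToRaw(s)
  if (length(v) %% 2 == 1)
    v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  el_raw(group, elem, vr, v)
}
el_us <- function(group, elem, x) el_raw(group, elem, "US", raw_u16(x))

#' Write a gray volume as a DICOM series
#'
#' Writes one explicit-VR little-endian secondary-capture file per slice,
#' with geometry tags (pixel spacing, slice positions along the normal,
#' orientation) matching the volume's spacing. Intensities are rounded and
#' clamped to the unsigned 16-bit range.
#'
#' @param volume A [gray_volume()].
#' @param directory_path Output directory (created if needed).
#' @param series_uid Optional series instance UID (one is generated
#'   otherwise).
#' @return Invisibly, the vector of files written.
#' @export
write_dicom_series <- function(volume, directory_path, series_uid = NULL) {
  stopifnot(inherits(volume, "gray_volume"))
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$data)
  sp <- volume$spacing
  root <- "1.2.826.0.1.3680043.9.7484"
  if (is.null(series_uid))
    series_uid <- paste(root, format(as.integer(Sys.time())),
                        sample.int(1e6, 1), sep = ".")
  study_uid <- paste0(series_uid, ".0")
  files <- character(d[3])
  for (s in seq_len(d[3])) {
    sop_uid <- paste(series_uid, s, sep = ".")
    img <- volume$data[, , s]
    px <- pmin(pmax(round(img), 0), 65535)
    body <- c(
      el_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
      el_str(0x0008, 0x0018, "UI", sop_uid),
      el_str(0x0018, 0x0050, "DS", format(sp[3])),
      el_str(0x0018, 0x0088, "DS", format(sp[3])),
      el_str(0x0020, 0x000D, "UI", study_uid),
      el_str(0x0020, 0x000E, "UI", series_uid),
      el_str(0x0020, 0x0013, "IS", format(s)),
      el_str(0x0020, 0x0032, "DS",
             paste(0, 0, format((s - 1) * sp[3]), sep = "\\")),
      el_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      el_us(0x0028, 0x0002, 1),
      el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      el_us(0x0028, 0x0010, d[1]),
      el_us(0x0028, 0x0011, d[2]),
      el_str(0x0028, 0x0030, "DS", paste(format(sp[1]), format(sp[2]), sep = "\\")),
      el_us(0x0028, 0x0100, 16),
      el_us(0x0028, 0x0101, 16),
      el_us(0x0028, 0x0102, 15),
      el_us(0x0028, 0x0103, 0),
      # pixel stream row-major: transpose the column-major slice
      el_raw(0x7FE0, 0x0010, "OW", raw_u16(as.vector(t(px))))
    )
    meta_body <- c(
      el_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.7"),
      el_str(0x0002, 0x0003, "UI", sop_uid),
      el_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    )
    glen <- length(meta_body)
    meta <- c(el_raw(0x0002, 0x0000, "UL",
                     c(raw_u16(glen %% 65536), raw_u16(glen %/% 65536))),
              meta_body)
    out <- c(as.raw(rep(0, 128)), charToRaw("DICM"), meta, body)
    files[s] <- file.path(directory_path, sprintf("slice_%04d.dcm", s))
    writeBin(out, files[s])
  }
  invisible(files)
}
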