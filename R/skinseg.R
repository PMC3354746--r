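#' Parameters of the geometric skin search
#'
#' @param max_depth_mm Depth limit of the boundary-to-interior skin search,
#'   applied inside the nipple region where skin and dense tissue may be in
#'   physical contact (default 3 mm).
#' @param nipple_band_fraction Anterior fraction of each breast's per-slice
#'   anterior–posterior extent treated as the nipple region (default 0.15).
#' @param connectivity_2d In-plane connectivity for component labelling and
#'   contact tests: 4 or 8 (default 8).
#' @param connectivity_3d 3D connectivity for the background-contact test of
#'   the skin closure: 6 or 26 (default 6).
#' @param smooth_max_iter Iteration cap of the interior smoothness filter
#'   (default 100; the filter normally reaches its fixpoint much earlier).
#' @param global_depth_limit Apply `max_depth_mm` everywhere instead of only
#'   in the nipple band (default `FALSE`, the literal reading of the method).
#' @return Object of class `skin_params`.
#' @export
skin_params <- function(max_depth_mm = 3, nipple_band_fraction = 0.15,
                        connectivity_2d = 8L, connectivity_3d = 6L,
                        smooth_max_iter = 100L, global_depth_limit = FALSE) {
  if (max_depth_mm <= 0) stop("max_depth_mm must be > 0")
  if (nipple_band_fraction <= 0 || nipple_band_fraction >= 0.5)
    stop("nipple_band_fraction must lie in (0, 0.5)")
  if (!connectivity_2d %in% c(4L, 8L)) stop("connectivity_2d must be 4 or 8")
  if (!connectivity_3d %in% c(6L, 26L)) stop("connectivity_3d must be 6 or 26")
  structure(list(max_depth_mm = max_depth_mm,
                 nipple_band_fraction = nipple_band_fraction,
                 connectivity_2d = as.integer(connectivity_2d),
                 connectivity_3d = as.integer(connectivity_3d),
                 smooth_max_iter = as.integer(smooth_max_iter),
                 global_depth_limit = isTRUE(global_depth_limit)),
            class = "skin_params")
}

#' Keep only the largest non-background object
#'
#' Labels the 3D connected components of all non-`BACKGROUND` voxels and
#' keeps the largest one — the breast — resetting every other foreground
#' voxel to `BACKGROUND`. Ties are broken deterministically toward the
#' component containing the smallest linear voxel index.
#'
#' @param labels A [label_volume()].
#' @param connectivity 3D connectivity (default 26).
#' @return Filtered [label_volume()].
#' @export
largest_foreground <- function(labels, connectivity = 26L) {
  stopifnot(inherits(labels, "label_volume"))
  fg <- labels$labels != BG
  if (!any(fg)) stop("no foreground voxels")
  comp <- connected_components(fg, connectivity)
  sizes <- tabulate(comp[fg])
  best_size <- max(sizes)
  # components are numbered by first appearance in linear order, so the
  # first max-size component id is the tie-break winner
  best <- which(sizes == best_size)[1]
  lab <- labels$labels
  lab[fg & comp != best] <- BG
  out <- label_volume(lab, labels$spacing,
                      allow_mixed = any(lab == MIXED))
  out
}

ebimage_kern <- function() EBImage::makeBrush(3, shape = "box")

#' Per-slice open–close smoothing of the breast border
#'
#' Applies binary morphological opening then closing with a 3x3 square
#' element to the foreground of every slice: opening removes one-voxel
#' spurs and satellites, closing fills one-voxel notches in the border.
#' Labels are unchanged wherever the foreground persists; voxels removed
#' become `BACKGROUND` and voxels added by closing take the majority label
#' of their 8-neighbourhood (falling back to `DENSE`, the candidate class,
#' when isolated).
#'
#' @param labels A [label_volume()].
#' @return Smoothed [label_volume()].
#' @export
open_close <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  d <- dim(lab)
  kern <- ebimage_kern()
  for (s in seq_len(d[3])) {
    sl <- lab[, , s]
    fg <- sl != BG
    if (!any(fg)) next
    sm <- EBImage::closing(EBImage::opening(fg * 1, kern), kern) > 0.5
    removed <- fg & !sm
    added <- !fg & sm
    sl[removed] <- BG
    if (any(added)) {
      for (v in which(added)) {
        r <- (v - 1) %% d[1] + 1
        c <- (v - 1) %/% d[1] + 1
        nb <- sl[max(1, r - 1):min(d[1], r + 1), max(1, c - 1):min(d[2], c + 1)]
        nb <- nb[nb != BG]
        sl[v] <- if (length(nb)) as.integer(names(which.max(table(nb)))) else DENSE
      }
    }
    lab[, , s] <- sl
  }
  label_volume(lab, labels$spacing, allow_mixed = any(lab == MIXED))
}

# Per-slice in-plane depth in voxel steps: 1 on the boundary, growing
# inward. Uses the exact Euclidean distance divided by the smaller in-plane
# spacing, so a physical depth of D mm corresponds to D / min(spacing) steps.
slice_depth <- function(fg, spacing) {
  dmm <- distance_to_background(fg, spacing[1:2])
  dmm / min(spacing[1:2])
}

# 4-neighbour dilation of a logical matrix (out-of-bounds treated FALSE)
dilate4 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-d[1], ]
  out[-d[1], ] <- out[-d[1], ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -d[2]]
  out[, -d[2]] <- out[, -d[2]] | m[, -1]
  out
}

#' Separate skin from dense tissue by a boundary-to-interior search
#'
#' For every slice, marches inward from the breast boundary through the
#' contiguous dark candidate voxels produced by [recluster_mixed()]:
#' candidates reached from the boundary before the first `FAT` voxel become
#' `SKIN`. Inside the nipple band — the anterior `nipple_band_fraction` of
#' the breast's per-slice extent, where skin and dense tissue may be in
#' physical contact — the march never exceeds
#' `ceiling(max_depth_mm / in-plane spacing)` voxel steps, so a dense mass
#' fused to the skin there keeps everything deeper than the limit.
#' Candidate components not reached by the march but enclosed by skin (and
#' background) alone are closed to `SKIN`; every remaining candidate stays
#' `DENSE`.
#'
#' @param volume The [gray_volume()] the labels came from (carried for
#'   interface symmetry with the intensity stages; the search itself is
#'   purely geometric).
#' @param labels A [label_volume()] whose dark candidates are `DENSE`.
#' @param params A [skin_params()].
#' @return [label_volume()] with `SKIN` assigned. Warns if no skin was
#'   found anywhere.
#' @export
separate_skin_dense <- function(volume, labels, params = skin_params()) {
  stopifnot(inherits(labels, "label_volume"), inherits(params, "skin_params"))
  lab <- labels$labels
  d <- dim(lab)
  sp <- labels$spacing
  cap <- ceiling(params$max_depth_mm / min(sp[1:2]))
  if (!any(lab != BG)) stop("no boundary voxels: labels contain no foreground")

  for (s in seq_len(d[3])) {
    sl <- lab[, , s]
    if (!any(sl != BG)) next

    # "every pixel between the skin limits" belongs to a tissue class:
    # background pockets not connected to the exterior are dark tissue that
    # fell into the background cluster and rejoin the dense candidates. The
    # exterior is any background component touching the anterior or lateral
    # image borders; the posterior border is the chest cut, not exterior air.
    bg0 <- sl == BG
    if (any(bg0)) {
      cmp <- connected_components(bg0, 4L)
      ext_ids <- setdiff(unique(c(cmp[1, ], cmp[, 1], cmp[, d[2]])), 0L)
      hole <- bg0 & !(cmp %in% c(0L, ext_ids))
      sl[hole] <- DENSE
    }

    fg <- sl != BG
    cand <- sl == DENSE
    if (!any(cand)) { lab[, , s] <- sl; next }
    depth <- slice_depth(fg, sp)

    rows_fg <- range(which(rowSums(fg) > 0))
    band_end <- rows_fg[1] + params$nipple_band_fraction * diff(rows_fg)
    in_band <- if (params$global_depth_limit) matrix(TRUE, d[1], d[2])
      else matrix(rep(seq_len(d[1]) <= band_end, d[2]), d[1], d[2])
    allowed <- cand & (!in_band | depth <= cap + 1e-9)

    skin <- allowed & dilate4(!fg)  # candidates on the boundary
    repeat {
      grown <- allowed & dilate4(skin)
      if (!any(grown & !skin)) break
      skin <- grown
    }

    # close candidate pockets enclosed by skin alone
    rest <- cand & !skin
    if (any(rest)) {
      comp <- connected_components(rest, params$connectivity_2d)
      ncmp <- attr(comp, "n_components")
      if (ncmp > 0) {
        halo_skin <- dilate4(skin)
        halo_fat <- dilate4(sl == FAT)
        halo_bg <- dilate4(!fg)
        blocked <- in_band & depth > cap + 1e-9  # beyond the nipple depth limit
        for (k in seq_len(ncmp)) {
          cm <- comp == k
          if (any(cm & halo_skin) && !any(cm & halo_fat) && !any(cm & halo_bg) &&
              !any(cm & blocked))
            skin <- skin | cm
        }
      }
    }
    sl[skin] <- SKIN
    lab[, , s] <- sl
  }
  if (!any(lab == SKIN))
    warning("no candidate voxels on the breast boundary: no SKIN produced")
  label_volume(lab, labels$spacing)
}

#' Absorb isolated dense pixels touching the skin
#'
#' Single-voxel `DENSE` components (per slice) that are in contact with
#' `SKIN` are passed to the skin.
#'
#' @param labels A [label_volume()].
#' @param params A [skin_params()] (supplies the in-plane connectivity used
#'   both for component labelling and for the contact test).
#' @return [label_volume()].
#' @export
absorb_isolated_dense <- function(labels, params = skin_params()) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  d <- dim(lab)
  for (s in seq_len(d[3])) {
    sl <- lab[, , s]
    dn <- sl == DENSE
    if (!any(dn)) next
    comp <- connected_components(dn, params$connectivity_2d)
    sizes <- tabulate(comp[dn])
    singles <- which(sizes == 1L)
    if (!length(singles)) next
    touch <- if (params$connectivity_2d == 4L) dilate4(sl == SKIN)
      else dilate8(sl == SKIN)
    for (k in singles) {
      v <- which(comp == k)
      if (touch[v]) sl[v] <- SKIN
    }
    lab[, , s] <- sl
  }
  label_volume(lab, labels$spacing)
}

dilate8 <- function(m) {
  out <- dilate4(m)
  d <- dim(m)
  out[-1, -1] <- out[-1, -1] | m[-d[1], -d[2]]
  out[-1, -d[2]] <- out[-1, -d[2]] | m[-d[1], -1]
  out[-d[1], -1] <- out[-d[1], -1] | m[-1, -d[2]]
  out[-d[1], -d[2]] <- out[-d[1], -d[2]] | m[-1, -1]
  out
}

# counts of 4-neighbours equal to a given code; borders count as BACKGROUND
count4 <- function(sl, code) {
  d <- dim(sl)
  pad <- function(dr, dc) {
    out <- matrix(BG, d[1], d[2])
    rs <- max(1, 1 + dr):min(d[1], d[1] + dr)
    cs <- max(1, 1 + dc):min(d[2], d[2] + dc)
    out[rs - dr, cs - dc] <- sl[rs, cs]
    out
  }
  (pad(1, 0) == code) + (pad(-1, 0) == code) +
    (pad(0, 1) == code) + (pad(0, -1) == code)
}

#' Iterative interior smoothness filter
#'
#' Removes one-voxel-thick artifacts left by the skin/dense separation:
#' any `SKIN` voxel with at least 3 of its 4 in-plane neighbours outside
#' the skin class is relabelled to the majority neighbour class, and any
#' `DENSE` voxel in contact with skin with at least 3 of 4 neighbours
#' outside the dense class likewise. Updates are applied synchronously and
#' the filter iterates to a fixpoint (or `smooth_max_iter`), at which point
#' reapplication is the identity. Majority ties prefer `FAT` over
#' `BACKGROUND` over `DENSE` when relabelling skin (erring away from
#' inflating dense tissue) and `SKIN` over `FAT` over `BACKGROUND` when
#' relabelling dense.
#'
#' @param labels A [label_volume()].
#' @param params A [skin_params()].
#' @return Filtered [label_volume()].
#' @export
interior_smoothness <- function(labels, params = skin_params()) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  d <- dim(lab)
  for (s in seq_len(d[3])) {
    sl <- lab[, , s]
    if (!any(sl == SKIN | sl == DENSE)) next
    for (it in seq_len(params$smooth_max_iter)) {
      nb <- lapply(c(BG, SKIN, FAT, DENSE), function(k) count4(sl, k))
      names(nb) <- c("bg", "skin", "fat", "dense")
      new_sl <- sl

      flag_s <- sl == SKIN & (4 - nb$skin) >= 3
      if (any(flag_s)) {
        # majority among {FAT, BACKGROUND, DENSE}; which.max keeps the
        # first max, giving the documented tie preference
        cnt <- cbind(fat = nb$fat[flag_s], bg = nb$bg[flag_s],
                     dense = nb$dense[flag_s])
        pick <- c(FAT, BG, DENSE)[max.col(cnt, ties.method = "first")]
        new_sl[flag_s] <- pick
      }
      flag_d <- sl == DENSE & nb$skin >= 1 & (4 - nb$dense) >= 3
      if (any(flag_d)) {
        cnt <- cbind(skin = nb$skin[flag_d], fat = nb$fat[flag_d],
                     bg = nb$bg[flag_d])
        pick <- c(SKIN, FAT, BG)[max.col(cnt, ties.method = "first")]
        new_sl[flag_d] <- pick
      }
      if (identical(new_sl, sl)) break
      sl <- new_sl
    }
    lab[, , s] <- sl
  }
  label_volume(lab, labels$spacing)
}

#' Iterative 3D skin closure
#'
#' A 2D per-slice segmentation leaves the 3D reconstruction with holes
#' between slices; this stage repeatedly relabels any `FAT` or `DENSE`
#' voxel that is 3D-adjacent to `BACKGROUND` as `SKIN` until no internal
#' tissue touches the background. Voxels beyond the volume border are not
#' background (the border of a breast ROI is a crop, not exterior air), so
#' the closure acts only on true exposure.
#'
#' @param labels A [label_volume()].
#' @param params A [skin_params()] (supplies the 3D connectivity, 6 or 26).
#' @return Closed [label_volume()]; afterwards no `FAT`/`DENSE` voxel has a
#'   `BACKGROUND` neighbour under the chosen connectivity.
#' @export
close_skin_3d <- function(labels, params = skin_params()) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  d <- dim(lab)
  offs <- if (params$connectivity_3d == 6L) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    o <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
    o <- o[rowSums(abs(o)) > 0, ]
    lapply(seq_len(nrow(o)), function(i) as.numeric(o[i, ]))
  }
  max_iter <- sum(d)
  for (it in seq_len(max_iter + 1L)) {
    if (it > max_iter) stop("close_skin_3d failed to converge")
    bg <- lab == BG
    near_bg <- Reduce(`|`, lapply(offs, function(o)
      shift3(bg, o[1], o[2], o[3], pad = FALSE)))
    exposed <- (lab == FAT | lab == DENSE) & near_bg
    if (!any(exposed)) break
    lab[exposed] <- SKIN
  }
  label_volume(lab, labels$spacing)
}

#' Fixed-thickness baseline skin
#'
#' The classical comparison mode: skin defined as a uniform shell of the
#' given thickness measured inward from the breast boundary on every slice,
#' regardless of intensity. This is the approach the adaptive method
#' replaces — on thin-skinned breasts it labels far too much fat as skin.
#'
#' @param labels A [label_volume()] with foreground defined.
#' @param thickness_mm Shell thickness in mm (default 3).
#' @return [label_volume()] with the shell as `SKIN`; interior labels kept.
#' @export
fixed_thickness_skin <- function(labels, thickness_mm = 3) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  d <- dim(lab)
  sp <- labels$spacing
  cap <- ceiling(thickness_mm / min(sp[1:2]))
  for (s in seq_len(d[3])) {
    sl <- lab[, , s]
    fg <- sl != BG
    if (!any(fg)) next
    depth <- slice_depth(fg, sp)
    sl[fg & depth <= cap + 1e-9] <- SKIN
    lab[, , s] <- sl
  }
  label_volume(lab, labels$spacing)
}
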