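#' Specification of a synthetic T2 breast phantom
#'
#' Describes a synthetic axial T2-like breast volume: two spherical breast
#' bodies attached to a posterior axial/chest band, each wrapped in a thin
#' dark skin shell over bright fat that contains dark dense (fibroglandular)
#' blobs, with background noise outside. The T2 contrast is enforced by
#' construction: fat bright, skin and dense tissue dark with overlapping
#' intensity distributions (their means differ by less than half their
#' spread, which is the very confusion the segmentation pipeline exists to
#' resolve), background darkest.
#'
#' Noise has two components: `noise_sigma` is the thermal noise added to
#' every voxel, and `hetero_sigma` is the extra intensity heterogeneity of
#' the dark tissues (skin, dense, axial zone), which in real breasts comes
#' from tissue texture rather than the scanner. Optional flags introduce the
#' failure modes the geometric filters target: missing-skin slices
#' (inter-slice gaps), one-voxel dark filaments inside the fat and one-voxel
#' dense spurs on the skin, and a dense blob fused to the skin at the
#' nipple.
#'
#' @param shape Volume dimensions `(rows, cols, slices)`.
#' @param spacing Voxel spacing `(row_mm, col_mm, slice_mm)`.
#' @param breast_radius_mm Radius of each breast sphere in mm (length 1
#'   or 2).
#' @param breast_center_frac Column positions of the two breast centers as
#'   fractions of the width.
#' @param band_row_frac Fraction of rows anterior to the axial/chest band.
#' @param center_depth_mm How far the sphere centers sit inside the band
#'   (controls how broadly the breasts attach to the chest).
#' @param skin_thickness_mm Skin shell thickness in mm (1–3; length 2 gives
#'   a linear variation along the slice axis).
#' @param nipple_bulge Add a small anterior bump at each breast apex.
#' @param dense_fraction Target fraction of the breast interior occupied by
#'   dense tissue (0–1).
#' @param intensity_means Named list of mean intensities: `fat`, `dense`,
#'   `skin`, `background`, `axial`.
#' @param noise_sigma Thermal noise standard deviation.
#' @param hetero_sigma Extra dark-tissue heterogeneity standard deviation.
#' @param noise_model `"gaussian"` (additive, clamped at 0) or `"rician"`.
#' @param interslice_gap Integer slice indices whose skin is deleted,
#'   emulating the gaps a 2D segmentation leaves between slices.
#' @param skin_filaments Number of one-voxel dark filaments drawn from the
#'   skin into the fat (smoothness-filter fodder).
#' @param dense_spurs Number of single dense-intensity voxels attached to
#'   the skin.
#' @param dense_at_nipple Fuse one dense blob to the skin at the anterior
#'   pole (exercises the nipple-region depth limit).
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 40),
                         spacing = c(1, 1, 2),
                         breast_radius_mm = 25,
                         breast_center_frac = c(0.28, 0.72),
                         band_row_frac = 0.70,
                         center_depth_mm = 7,
                         skin_thickness_mm = 2,
                         nipple_bulge = FALSE,
                         dense_fraction = 0.2,
                         intensity_means = list(fat = 200, dense = 60,
                                                skin = 57, background = 2,
                                                axial = 90),
                         noise_sigma = 6,
                         hetero_sigma = 5,
                         noise_model = c("gaussian", "rician"),
                         interslice_gap = integer(0),
                         skin_filaments = 0L,
                         dense_spurs = 0L,
                         dense_at_nipple = FALSE,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (length(breast_radius_mm) == 1L) breast_radius_mm <- rep(breast_radius_mm, 2)
  if (length(skin_thickness_mm) == 1L) skin_thickness_mm <- rep(skin_thickness_mm, 2)
  m <- intensity_means
  if (!(m$fat > m$dense && m$fat > m$skin))
    stop("T2 contrast violated: fat mean must exceed dense and skin means")
  if (!(m$skin > m$background && m$dense > m$background))
    stop("skin and dense means must exceed the background mean")
  if (any(skin_thickness_mm < max(spacing[1:2])))
    stop("skin thickness must be at least one in-plane voxel at this spacing")
  if (dense_fraction < 0 || dense_fraction > 1)
    stop("dense_fraction must lie in [0, 1]")
  structure(
    list(shape = as.integer(shape), spacing = as.numeric(spacing),
         breast_radius_mm = breast_radius_mm,
         breast_center_frac = breast_center_frac,
         band_row_frac = band_row_frac, center_depth_mm = center_depth_mm,
         skin_thickness_mm = skin_thickness_mm, nipple_bulge = nipple_bulge,
         dense_fraction = dense_fraction, intensity_means = m,
         noise_sigma = noise_sigma, hetero_sigma = hetero_sigma,
         noise_model = noise_model,
         interslice_gap = as.integer(interslice_gap),
         skin_filaments = as.integer(skin_filaments),
         dense_spurs = as.integer(dense_spurs),
         dense_at_nipple = isTRUE(dense_at_nipple),
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Generate a synthetic breast volume with ground-truth labels
#'
#' Builds the geometry described by a [phantom_spec()] — two breast spheres
#' partially submerged in a posterior chest band, skin defined as the shell
#' of breast voxels within the skin thickness of the exterior (by exact
#' anisotropic Euclidean distance), dense blobs sampled inside the interior
#' until the target dense fraction is met — then paints class mean
#' intensities and adds noise. Deterministic for a fixed spec.
#'
#' The truth labels cover the breast classes only; the axial band is
#' labelled `BACKGROUND` (it is outside the segmentation target) and its
#' mask is returned in `meta$axial` so tests can distinguish true exterior
#' from chest.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` ([gray_volume()]), `truth` ([label_volume()])
#'   and `meta` (band start row, sphere centers in voxel coordinates, the
#'   axial mask, and the interior voxel count per breast).
#' @export
make_breast_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape; sp <- spec$spacing
  nr <- d[1]; nc <- d[2]; ns <- d[3]
  band_start <- round(spec$band_row_frac * nr)  # last row before the band
  r0 <- band_start + spec$center_depth_mm / sp[1]
  c0 <- spec$breast_center_frac * nc
  s0 <- (ns + 1) / 2
  R <- spec$breast_radius_mm

  rr <- (seq_len(nr) - 1) * sp[1]
  cc <- (seq_len(nc) - 1) * sp[2]
  ss <- (seq_len(ns) - 1) * sp[3]

  sphere <- function(center_vox, radius) {
    cx <- (center_vox - 1) * sp
    dr2 <- (rr - cx[1])^2
    dc2 <- (cc - cx[2])^2
    ds2 <- (ss - cx[3])^2
    outer(outer(dr2, dc2, `+`), ds2, `+`) <= radius^2
  }

  check_fit <- function(center_vox, radius) {
    cx <- (center_vox - 1) * sp
    lims <- c(cx[2] - radius, (nc - 1) * sp[2] - (cx[2] + radius),
              cx[3] - radius, (ns - 1) * sp[3] - (cx[3] + radius),
              cx[1] - radius)
    if (any(lims < sp[c(2, 2, 3, 3, 1)]))
      stop("breast overlaps the image border; enlarge the volume or shrink the radius")
  }
  check_fit(c(r0, c0[1], s0), R[1])
  check_fit(c(r0, c0[2], s0), R[2])

  sph <- list(sphere(c(r0, c0[1], s0), R[1]), sphere(c(r0, c0[2], s0), R[2]))
  if (spec$nipple_bulge) {
    for (b in 1:2) {
      pole <- c(r0 - R[b] / sp[1], c0[b], s0)
      sph[[b]] <- sph[[b]] | sphere(pole, 0.2 * R[b])
    }
  }
  band <- array(FALSE, d); band[(band_start + 1):nr, , ] <- TRUE
  tissue <- sph[[1]] | sph[[2]] | band

  edt <- distance_to_background(tissue, sp)
  anterior <- array(rep(seq_len(nr) <= band_start, nc * ns), d)
  breast <- (sph[[1]] | sph[[2]]) & anterior

  tmm <- spec$skin_thickness_mm
  if (ns > 1) {
    tprof <- tmm[1] + (tmm[2] - tmm[1]) * (seq_len(ns) - 1) / (ns - 1)
  } else tprof <- rep(tmm[1], 1)
  tmap <- aperm(array(rep(tprof, each = nr * nc), d), c(1, 2, 3))
  skin <- breast & (edt <= tmap + 1e-9)
  interior <- breast & !skin

  labels <- array(BG, d)
  labels[interior] <- FAT
  labels[skin] <- SKIN

  meta <- list(band_start = band_start,
               centers = list(c(r0, c0[1], s0), c(r0, c0[2], s0)),
               radius_mm = R, axial = band,
               interior_voxels = sum(interior))

  local_seed(spec$seed, {
    # dense blobs: random spheres kept inside the interior, a safety margin
    # away from the skin, trimmed so the target fraction is hit closely
    if (spec$dense_fraction > 0 && any(interior)) {
      margin <- tmap + 2 * min(sp[1:2])
      eligible <- which(interior & edt > margin)
      target <- round(spec$dense_fraction * sum(interior))
      dense_n <- 0L
      tries <- 0L
      while (dense_n < target && tries < 400L && length(eligible)) {
        tries <- tries + 1L
        ctr <- arrayInd(sample(eligible, 1L), d)
        rad <- runif(1, 3, 7)
        blob <- which(sphere(as.numeric(ctr), rad) & interior &
                        edt > margin & labels != DENSE)
        if (!length(blob)) next
        need <- target - dense_n
        if (length(blob) > need) {
          bx <- (arrayInd(blob, d) - rep(as.numeric(ctr), each = length(blob))) *
            rep(sp, each = length(blob))
          blob <- blob[order(rowSums(bx^2))][seq_len(need)]
        }
        labels[blob] <- DENSE
        dense_n <- dense_n + length(blob)
      }
    }
    if (spec$dense_at_nipple) {
      for (b in 1:2) {
        pole <- c(r0 - (R[b] - tmm[1] - 1) / sp[1], c0[b], s0)
        blob <- sphere(pole, 6) & interior
        labels[blob] <- DENSE
      }
    }

    m <- spec$intensity_means
    base <- array(m$background, d)
    base[band] <- m$axial
    base[labels == FAT] <- m$fat
    base[labels == DENSE] <- m$dense
    base[labels == SKIN] <- m$skin

    # artifact flags operate on intensity only; truth keeps the underlying class
    if (spec$skin_filaments > 0L) {
      inner <- which(interior & edt <= tmap + min(sp[1:2]) + 1e-9)
      if (length(inner)) {
        starts <- sample(inner, min(spec$skin_filaments, length(inner)))
        for (v in starts) {
          ix <- arrayInd(v, d)
          len <- sample(4:8, 1)
          dir <- if (ix[2] < mean(c0)) 1L else -1L  # march toward breast center
          cols_f <- ix[2] + dir * (0:(len - 1))
          cols_f <- cols_f[cols_f >= 1 & cols_f <= nc]
          sel <- cbind(ix[1], cols_f, ix[3])
          keep <- interior[sel]
          if (any(keep)) base[sel[keep, , drop = FALSE]] <- m$skin
        }
      }
    }
    if (spec$dense_spurs > 0L) {
      near <- which(interior & edt <= tmap + min(sp[1:2]) + 1e-9 & labels == FAT)
      if (length(near)) {
        sel <- sample(near, min(spec$dense_spurs, length(near)))
        base[sel] <- m$dense
      }
    }

    # inter-slice gaps: skin signal (and truth skin) missing on whole slices
    for (s in spec$interslice_gap) {
      if (s < 1 || s > ns) next
      sl <- labels[, , s]
      gap <- sl == SKIN
      sl[gap] <- BG
      labels[, , s] <- sl
      bs <- base[, , s]
      bs[gap] <- m$background
      base[, , s] <- bs
    }

    sdmap <- array(spec$noise_sigma, d)
    dark <- labels == SKIN | labels == DENSE | band
    sdmap[dark] <- sqrt(spec$noise_sigma^2 + spec$hetero_sigma^2)
    if (max(sdmap) > 0) {
      if (spec$noise_model == "gaussian") {
        vol <- pmax(base + array(rnorm(length(base), 0, 1), d) * sdmap, 0)
      } else {
        n1 <- array(rnorm(length(base), 0, 1), d) * sdmap
        n2 <- array(rnorm(length(base), 0, 1), d) * sdmap
        vol <- sqrt((base + n1)^2 + n2^2)
      }
    } else vol <- base

    list(volume = gray_volume(vol, sp),
         truth = label_volume(labels, sp),
         meta = meta)
  })
}

#' Per-class overlap scores against ground truth
#'
#' Computes Dice coefficient, precision and recall per class
#' (`dice = 2|A∩B| / (|A| + |B|)`). A class absent from both volumes scores
#' 1 in all three metrics.
#'
#' @param pred Predicted [label_volume()] (final classes only).
#' @param truth Ground-truth [label_volume()] of the same shape.
#' @return Data frame with one row per class: `class`, `code`, `dice`,
#'   `precision`, `recall`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  if (!identical(dim(pred$labels), dim(truth$labels)))
    stop("pred and truth have different shapes")
  codes <- label_codes()[c("BACKGROUND", "SKIN", "FAT", "DENSE")]
  res <- lapply(seq_along(codes), function(i) {
    k <- codes[i]
    p <- pred$labels == k
    t <- truth$labels == k
    np <- sum(p); nt <- sum(t); tp <- sum(p & t)
    if (np == 0 && nt == 0) {
      c(dice = 1, precision = 1, recall = 1)
    } else {
      c(dice = 2 * tp / (np + nt),
        precision = if (np > 0) tp / np else 0,
        recall = if (nt > 0) tp / nt else 0)
    }
  })
  out <- data.frame(class = tolower(names(codes)), code = unname(codes),
                    do.call(rbind, res))
  rownames(out) <- NULL
  out
}
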