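# 2-D RANO-style caliper measurements and 3-D volumes from binary masks.
#
# Conventions: voxel arrays are ordered slice x row x column, indices are
# 0-based in mm space (mm coordinate = index * spacing), and diameters are
# voxel-center-to-voxel-center distances. Center-based calipers underestimate
# an edge-to-edge reading by at most one in-plane pixel.

# threshold comparisons are inclusive at the printed boundary; the absolute
# tolerance absorbs binary-representation error (e.g. (14-9.8)/14 < 0.3 in
# doubles even though the decrease is exactly 30%)
.geq <- function(x, y, tol = 1e-9) !is.na(x) & x >= y - tol

#' Binary lesion mask with voxel spacing
#'
#' Container for one 3-D segmentation mask (contrast-enhancing tumor core on
#' post-contrast T1, or FLAIR-hyperintense peritumoral edema, which by
#' convention surrounds *and includes* the core). The first array axis is the
#' axial slice direction; reorient on load if your data differ (see
#' [read_mask_nifti()]).
#'
#' @param voxels 3-D array (slice x row x column) containing only 0/1 (or
#'   logical).
#' @param spacing Numeric length-3: slice thickness, row spacing, column
#'   spacing, all in mm and strictly positive.
#' @param label `"core"` or `"edema"`.
#' @return An object of class `mask_volume`.
#' @examples
#' vox <- array(0L, c(3, 12, 12)); vox[2, 6, 2:11] <- 1L
#' m <- mask_volume(vox, c(3, 1, 1), "core")
#' longest_axial_diameter(m)$ld_mm
#' @export
mask_volume <- function(voxels, spacing, label = c("core", "edema")) {
  label <- match.arg(label)
  if (is.logical(voxels)) {
    voxels <- array(as.integer(voxels), dim = dim(voxels))
  }
  if (length(dim(voxels)) != 3L) {
    stop("'voxels' must be a 3-D array (slice x row x column)")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop("'spacing' must be three strictly positive mm values")
  }
  if (!all(voxels == 0L | voxels == 1L)) {
    stop("mask voxels must be binary (0/1)")
  }
  structure(list(voxels = voxels, spacing = spacing, label = label),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume '%s'> %s voxels on %s grid, spacing %s mm\n",
              x$label, sum(x$voxels), paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

# Maximum center-to-center distance within one slice plus the perpendicular
# extent; points are (row_mm, col_mm). Convex-hull pruning for large slices,
# exact all-pairs otherwise -- the hull diameter equals the full diameter.
.slice_caliper <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) {
    return(list(ld = 0, perp = 0, endpoints = pts[c(1L, 1L), , drop = FALSE]))
  }
  cand <- pts
  if (n > 60L) {
    h <- tryCatch(grDevices::chull(pts[, 2L], pts[, 1L]),
                  error = function(e) NULL)
    if (length(h) >= 2L) cand <- pts[h, , drop = FALSE]
  }
  dx <- outer(cand[, 1L], cand[, 1L], "-")
  dy <- outer(cand[, 2L], cand[, 2L], "-")
  d2 <- dx * dx + dy * dy
  best <- max(d2)
  hit <- which(d2 == best, arr.ind = TRUE)
  hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
  # deterministic endpoints: order each pair, then take the lexicographic
  # smallest (row, col, row, col) quadruple among ties
  quads <- t(apply(hit, 1L, function(ij) {
    a <- cand[ij[1L], ]; b <- cand[ij[2L], ]
    if (a[1L] > b[1L] || (a[1L] == b[1L] && a[2L] > b[2L])) c(b, a) else c(a, b)
  }))
  o <- do.call(order, as.data.frame(quads))
  q <- quads[o[1L], ]
  e <- rbind(q[1:2], q[3:4])
  ld <- sqrt(best)
  perp <- 0
  if (ld > 0) {
    u <- (e[2L, ] - e[1L, ]) / ld
    nrm <- c(-u[2L], u[1L])
    proj <- pts[, 1L] * nrm[1L] + pts[, 2L] * nrm[2L]
    perp <- max(proj) - min(proj)
  }
  list(ld = ld, perp = perp, endpoints = e)
}

#' Longest axial diameter and perpendicular diameter of a lesion mask
#'
#' Measures the lesion the way RANO-BM prescribes: per axial slice, the
#' longest in-plane distance between voxel centers (in mm, using the in-plane
#' spacing, which may be anisotropic); the lesion LD is the maximum over
#' slices. The perpendicular diameter is the extent of that slice's voxel
#' centers projected onto the unit normal of the LD segment. Ties across
#' slices go to the lowest slice index; endpoint ties to lexicographic order.
#'
#' @param mask A [mask_volume()].
#' @return Object of class `diameter_measurement`: `ld_mm`, `perp_mm`,
#'   `slice_index` (0-based), `endpoints` (2 x 2 matrix of in-plane mm
#'   coordinates, rows = endpoints, columns = row/column axes).
#'   Masks with no in-plane extent (single voxel, or a line along the slice
#'   axis) yield 0 mm diameters with a sub-voxel lesion warning: such lesions
#'   are simply non-measurable.
#' @seealso [is_measurable()], [lesion_volume()]
#' @export
longest_axial_diameter <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  if (sum(mask$voxels) == 0L) stop("no lesion voxels")
  sp <- mask$spacing
  best <- NULL
  for (s in seq_len(dim(mask$voxels)[1L])) {
    idx <- which(mask$voxels[s, , , drop = FALSE] == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    pts <- cbind((idx[, 2L] - 1) * sp[2L], (idx[, 3L] - 1) * sp[3L])
    cal <- .slice_caliper(pts)
    if (is.null(best) || cal$ld > best$ld) {
      best <- cal
      best$slice <- s
    }
  }
  if (best$ld == 0) {
    warning("sub-voxel lesion: no in-plane extent, diameters set to 0 mm")
  }
  structure(list(ld_mm = best$ld, perp_mm = best$perp,
                 slice_index = best$slice - 1L, endpoints = best$endpoints),
            class = "diameter_measurement")
}

#' @export
print.diameter_measurement <- function(x, ...) {
  cat(sprintf("LD %.2f mm, perpendicular %.2f mm (slice %d)\n",
              x$ld_mm, x$perp_mm, x$slice_index))
  invisible(x)
}

#' Lesion volume from a binary mask
#'
#' Volume is the voxel count times the voxel volume:
#' `volume_cm3 = n_voxels * prod(spacing) / 1000`, exactly. An empty mask is
#' allowed and yields 0 (edema fully resolved).
#'
#' @param mask A [mask_volume()].
#' @return Object of class `volume_measurement` with `volume_cm3` and
#'   `voxel_count`.
#' @export
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  n <- sum(mask$voxels)
  structure(list(volume_cm3 = n * prod(mask$spacing) / 1000,
                 voxel_count = as.integer(n)),
            class = "volume_measurement")
}

#' @export
print.volume_measurement <- function(x, ...) {
  cat(sprintf("%.3f cm^3 (%d voxels)\n", x$volume_cm3, x$voxel_count))
  invisible(x)
}

#' RANO-BM measurability of a lesion
#'
#' A lesion is measurable when its longest axial diameter is at least 10 mm
#' and its perpendicular diameter at least 5 mm (both inclusive).
#'
#' @param d A `diameter_measurement`, or the LD in mm.
#' @param perp_mm Perpendicular diameter in mm (ignored when `d` is a
#'   `diameter_measurement`).
#' @param min_ld_mm,min_perp_mm Thresholds in mm (defaults 10 and 5).
#' @return Logical.
#' @export
is_measurable <- function(d, perp_mm = NULL, min_ld_mm = 10, min_perp_mm = 5) {
  if (inherits(d, "diameter_measurement")) {
    perp_mm <- d$perp_mm
    d <- d$ld_mm
  }
  .geq(d, min_ld_mm) & .geq(perp_mm, min_perp_mm)
}

#' Read a binary mask from a NIfTI file
#'
#' Reads the volume and voxel spacing from the header, binarizes at 0.5, and
#' reorients so the slice axis comes first (the package convention). Files
#' written by [write_mask_nifti()] use the conventional x/y/z
#' (column/row/slice) order and round-trip with the defaults.
#'
#' @param path Path to a NIfTI file.
#' @param label `"core"` or `"edema"`.
#' @param slice_axis Which file axis is the slice (axial) direction; default 3.
#' @param spacing Optional length-3 mm spacing (slice, row, column) overriding
#'   the header.
#' @return A [mask_volume()].
#' @export
read_mask_nifti <- function(path, label = c("core", "edema"), slice_axis = 3L,
                            spacing = NULL) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("cannot read mask file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) {
    # a single-slice volume: the file carries no through-plane extent
    warning("2-D mask file; treating as one axial slice -- supply 'spacing' ",
            "for the slice thickness (default 1 mm)")
    arr <- array(arr, c(dim(arr), 1L))
    sp <- c(RNifti::pixdim(img)[1:2], NA_real_)
  } else if (length(dim(arr)) == 3L) {
    sp <- RNifti::pixdim(img)[1:3]
  } else {
    stop("expected a 3-D mask volume: ", path)
  }
  # in-plane axes map (y, x) -> (row, column) under the conventional
  # x = column / y = row layout
  ord <- c(slice_axis, rev(setdiff(1:3, slice_axis)))
  arr <- aperm(arr, ord)
  sp <- if (is.null(spacing)) sp[ord] else as.numeric(spacing)
  if (is.na(sp[1L])) sp[1L] <- 1
  if (anyNA(sp) || any(sp <= 0)) {
    stop("missing or invalid voxel spacing in ", path,
         "; supply 'spacing' explicitly")
  }
  mask_volume(array(as.integer(arr > 0.5), dim(arr)), sp, label)
}

#' Write a binary mask to a NIfTI file
#'
#' Writes in conventional x/y/z (column/row/slice) axis order with the voxel
#' spacing in the header, so [read_mask_nifti()] with defaults recovers the
#' original mask.
#'
#' @param mask A [mask_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  arr <- aperm(mask$voxels, c(3L, 2L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$spacing[c(3L, 2L, 1L)]
  RNifti::writeNifti(img, path)
  invisible(path)
}
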