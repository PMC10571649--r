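# Geometric voxel phantoms: digitized spheres/ellipsoids standing in for
# manual core and edema segmentations, with analytic volumes as oracles.

#' Specify a core/edema phantom pair
#'
#' Describes two concentric analytic surfaces (sphere or ellipsoid): the
#' contrast-enhancing core and the surrounding edema, which must contain the
#' core componentwise -- mirroring the convention that the edema mask
#' surrounds and includes the tumor core.
#'
#' @param shape `"sphere"` or `"ellipsoid"`. A sphere is an ellipsoid with
#'   equal semi-axes; scalar semi-axes are recycled.
#' @param core_semi_axes_mm Semi-axes (slice, row, column) of the core, mm.
#' @param edema_semi_axes_mm Semi-axes of the edema, componentwise `>=` core.
#' @param spacing Voxel spacing (slice, row, column), mm.
#' @param center_mm Center in mm coordinates; default the grid center.
#' @param grid_shape Grid dimensions in voxels; default fits the edema with a
#'   two-voxel margin.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("sphere", "ellipsoid"),
                         core_semi_axes_mm,
                         edema_semi_axes_mm = core_semi_axes_mm,
                         spacing = c(1, 1, 1),
                         center_mm = NULL,
                         grid_shape = NULL) {
  shape <- match.arg(shape)
  core <- rep_len(as.numeric(core_semi_axes_mm), 3L)
  edema <- rep_len(as.numeric(edema_semi_axes_mm), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (shape == "sphere" &&
      (length(unique(core)) != 1L || length(unique(edema)) != 1L)) {
    stop("a sphere needs equal semi-axes; use shape = 'ellipsoid'")
  }
  if (any(core <= 0) || any(spacing <= 0)) {
    stop("semi-axes and spacing must be strictly positive")
  }
  if (any(edema < core)) {
    stop("edema semi-axes must be componentwise >= core semi-axes")
  }
  if (is.null(grid_shape)) {
    grid_shape <- ceiling(2 * edema / spacing) + 5L
  }
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  if (is.null(center_mm)) {
    center_mm <- (grid_shape - 1) * spacing / 2
  }
  center_mm <- rep_len(as.numeric(center_mm), 3L)
  structure(list(shape = shape, core = core, edema = edema,
                 spacing = spacing, center = center_mm, grid = grid_shape),
            class = "phantom_spec")
}

#' Generate a voxelized core/edema phantom pair
#'
#' A voxel belongs to a mask iff its center lies inside the analytic surface;
#' the edema mask is the union of the edema ellipsoid and the core, so it
#' always contains the core mask. Surfaces clipped by the grid boundary are
#' an error.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `core` and `edema`, both [mask_volume()]s.
#' @examples
#' ph <- generate_phantom(phantom_spec("sphere", 10))
#' lesion_volume(ph$core)$volume_cm3      # close to 4/3*pi*10^3 / 1000
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  extent <- (spec$grid - 1) * spec$spacing
  if (any(spec$center - spec$edema < 0) ||
      any(spec$center + spec$edema > extent)) {
    stop("phantom clipped by grid boundary; enlarge grid_shape")
  }
  inside <- function(axes) {
    q <- lapply(1:3, function(a) {
      (((seq_len(spec$grid[a]) - 1) * spec$spacing[a] - spec$center[a]) /
         axes[a])^2
    })
    outer(outer(q[[1L]], q[[2L]], "+"), q[[3L]], "+") <= 1
  }
  core <- inside(spec$core)
  edema <- inside(spec$edema) | core
  list(core = mask_volume(core, spec$spacing, "core"),
       edema = mask_volume(edema, spec$spacing, "edema"))
}

#' Analytic volumes of a phantom specification
#'
#' @param spec A [phantom_spec()].
#' @return List with `core_cm3` and `edema_cm3` (ellipsoid volume
#'   `4/3 * pi * a * b * c`, converted to cm^3).
#' @export
phantom_analytic_volumes <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  v <- function(a) 4 / 3 * pi * prod(a) / 1000
  list(core_cm3 = v(spec$core), edema_cm3 = v(spec$edema))
}
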