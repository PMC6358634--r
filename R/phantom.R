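#' Voxel grid
#'
#' Regular axis-aligned voxel grid. Coordinates are right-handed, in mm,
#' patient-centred: +x left, +y anterior, +z superior. Voxel indices are
#' 0-based in the external (file / JSON) representation; `origin` is the
#' position of the centre of voxel (0, 0, 0). Linear voxel order is
#' x-fastest (column-major over (ix, iy, iz)).
#'
#' @param shape integer triple (nx, ny, nz), all >= 1.
#' @param spacing mm triple, all > 0.
#' @param origin mm triple, centre of the first voxel.
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(shape, spacing, origin) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L)) stopf("grid shape must be 3 integers >= 1")
  if (length(spacing) != 3L || any(spacing <= 0)) stopf("grid spacing must be 3 positive values (mm)")
  if (length(origin) != 3L) stopf("grid origin must be a 3-vector (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

n_voxels <- function(grid) prod(grid$shape)

# Voxel centre coordinates as an (nvox x 3) matrix, x-fastest ordering.
voxel_centres <- function(grid) {
  ax <- lapply(1:3, function(k) grid$origin[k] + (seq_len(grid$shape[k]) - 1) * grid$spacing[k])
  cbind(
    rep(ax[[1]], times = grid$shape[2] * grid$shape[3]),
    rep(rep(ax[[2]], each = grid$shape[1]), times = grid$shape[3]),
    rep(ax[[3]], each = grid$shape[1] * grid$shape[2])
  )
}

voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

#' Structure specification
#'
#' Analytic solid plus labelling priority and optional dose objective.
#' Supported shapes: `sphere` (centre, radius), `cylinder` (z-aligned:
#' centre, radius, half_height), `box` (centre, half_size), and `annulus`
#' (a shell of given `width` around an existing structure `ref`, starting
#' `inner` mm outside its surface).
#'
#' Objectives follow the quadratic min/max-dose penalty: importance `a >= 0`,
#' and dose bounds in Gy. Targets carry both `d_min` and `d_max`; normal
#' tissues only `d_max`.
#'
#' @param name structure name (unique within a phantom).
#' @param priority integer; lower value = higher labelling priority.
#' @param shape one of "sphere", "cylinder", "box", "annulus".
#' @param params named list of geometry parameters (mm).
#' @param a importance factor (>= 0), or NULL for no objective.
#' @param d_min,d_max dose bounds in Gy (NULL if absent).
#' @return A `structure_spec` object.
#' @export
structure_spec <- function(name, priority, shape,
                           params = list(), a = NULL,
                           d_min = NULL, d_max = NULL) {
  shape <- match.arg(shape, c("sphere", "cylinder", "box", "annulus"))
  if (!is.null(a) && a < 0) stopf("importance factor a must be >= 0 (structure '%s')", name)
  if (!is.null(d_min) && is.null(d_max))
    stopf("structure '%s': d_min without d_max; only targets have a minimum bound and targets carry both", name)
  if (shape == "annulus") {
    if (is.null(params$ref)) stopf("annulus '%s' must reference an existing structure via params$ref", name)
    if (is.null(params$width) || params$width <= 0) stopf("annulus '%s' width must be > 0", name)
    params$inner <- params$inner %||% 0
  }
  structure(list(name = name, priority = as.integer(priority), shape = shape,
                 params = params, a = a, d_min = d_min, d_max = d_max),
            class = "structure_spec")
}

# Signed distance (mm) from points P (n x 3) to the surface of a primitive
# solid; negative inside. Used both for membership (centre-inclusion:
# sd <= 0) and to carve annular shells.
signed_distance <- function(spec, P, structures = NULL) {
  p <- spec$params
  switch(spec$shape,
    sphere = {
      sqrt(rowSums(sweep(P, 2, p$centre)^2)) - p$radius
    },
    cylinder = {
      dr <- sqrt((P[, 1] - p$centre[1])^2 + (P[, 2] - p$centre[2])^2) - p$radius
      dz <- abs(P[, 3] - p$centre[3]) - p$half_height
      inside <- pmax(dr, dz)
      out <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
      ifelse(dr <= 0 & dz <= 0, inside, out)
    },
    box = {
      d <- abs(sweep(P, 2, p$centre)) - matrix(p$half_size, nrow(P), 3, byrow = TRUE)
      inside <- pmax(d[, 1], pmax(d[, 2], d[, 3]))
      out <- sqrt(rowSums(pmax(d, 0)^2))
      ifelse(inside <= 0, inside, out)
    },
    annulus = {
      ref <- structures[[p$ref]]
      if (is.null(ref)) stopf("annulus '%s' references unknown structure '%s'", spec$name, p$ref)
      sd <- signed_distance(ref, P, structures)
      # shell (inner, inner + width] outside the reference surface; represent
      # membership via a pseudo signed distance (<= 0 inside the shell)
      mid <- p$inner + p$width / 2
      abs(sd - mid) - p$width / 2 - 1e-9
    }
  )
}

structure_contains <- function(spec, P, structures) signed_distance(spec, P, structures) <= 0

#' Build a voxel phantom
#'
#' Voxelises the analytic structures of a phantom specification by
#' centre-inclusion and resolves overlap by priority: each voxel receives
#' exactly one label, that of the highest-priority (lowest priority number)
#' structure containing its centre. Voxels outside the body solid are
#' labelled air (label 0) and excluded from all objectives; annular shells
#' are clipped to the body.
#'
#' @param spec list with elements `grid` (a [voxel_grid] or its arguments)
#'   and `structures` (list of [structure_spec]); must contain structures
#'   named "body" and "ptv".
#' @return A `voxel_phantom`: grid, integer `labels` (0 = air, otherwise the
#'   1-based position in `structures`), the structure list, and
#'   `target_point` (PTV centroid, the beam aim point).
#' @export
build_phantom <- function(spec) {
  grid <- spec$grid
  if (!inherits(grid, "voxel_grid")) grid <- voxel_grid(grid$shape, grid$spacing, grid$origin)
  structs <- spec$structures
  nms <- vapply(structs, `[[`, "", "name")
  if (anyDuplicated(nms)) stopf("structure names must be unique")
  names(structs) <- nms
  if (!"body" %in% nms) stopf("phantom must contain a structure named 'body'")
  if (!"ptv" %in% nms) stopf("phantom must contain a structure named 'ptv'")
  prios <- vapply(structs, `[[`, 1L, "priority")
  if (anyDuplicated(prios)) stopf("structure priorities must be unique within a phantom")

  P <- voxel_centres(grid)
  in_body <- structure_contains(structs[["body"]], P, structs)
  labels <- integer(nrow(P))  # 0 = air
  # assign in descending priority number (least important first), so higher
  # priority structures overwrite
  ord <- order(prios, decreasing = TRUE)
  for (k in ord) {
    inside <- structure_contains(structs[[k]], P, structs) & in_body
    labels[inside] <- k
  }
  ptv_id <- match("ptv", nms)
  ptv_vox <- labels == ptv_id
  if (!any(ptv_vox)) stopf("PTV contains no voxels (empty or outside body)")
  if (any(structure_contains(structs[[ptv_id]], P, structs) & !in_body))
    stopf("PTV extends outside the body")
  structure(list(grid = grid, labels = labels, structures = structs,
                 target_point = colMeans(P[ptv_vox, , drop = FALSE])),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("voxel_phantom: %d x %d x %d voxels at (%g, %g, %g) mm\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$spacing[1], x$grid$spacing[2], x$grid$spacing[3]))
  tab <- table(factor(x$labels, levels = 0:length(x$structures),
                      labels = c("air", names(x$structures))))
  for (nm in names(tab)) cat(sprintf("  %-10s %d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

structure_voxels <- function(phantom, name) {
  id <- match(name, names(phantom$structures))
  if (is.na(id)) stopf("unknown structure '%s'", name)
  which(phantom$labels == id)
}

#' Default phantom specification
#'
#' A cylindrical water-equivalent body (radius 120 mm, half-height 80 mm),
#' a spherical PTV of radius 25 mm offset 40 mm from the axis, a cylindrical
#' organ at risk abutting the PTV, and three 10 mm annular shells A1-A3
#' around the PTV used to shape the dose fall-off. Default voxel spacing is
#' 5 mm isotropic. Objectives (importance factors and Gy bounds) are chosen
#' for a 40 Gy prescription; see the package vignette for the rationale.
#'
#' @param spacing isotropic voxel spacing in mm.
#' @param body_radius,body_half_height,ptv_radius,ptv_offset,oar_radius
#'   geometry overrides in mm.
#' @param prescription prescription dose in Gy used to scale the default
#'   objective bounds.
#' @return A phantom specification list for [build_phantom].
#' @export
default_phantom_spec <- function(spacing = 5, body_radius = 120,
                                 body_half_height = 80, ptv_radius = 25,
                                 ptv_offset = 40, oar_radius = 15,
                                 prescription = 40) {
  half_extent <- c(body_radius + spacing, body_radius + spacing,
                   body_half_height + spacing)
  shape <- ceiling(2 * half_extent / spacing)
  origin <- -(shape - 1) / 2 * spacing
  p <- prescription
  list(
    grid = voxel_grid(shape, rep(spacing, 3), origin),
    structures = list(
      structure_spec("ptv", 1L, "sphere",
                     list(centre = c(ptv_offset, 0, 0), radius = ptv_radius),
                     a = 100, d_min = p, d_max = 1.1 * p),
      structure_spec("oar", 2L, "cylinder",
                     list(centre = c(0, 0, 0), radius = oar_radius,
                          half_height = min(50, body_half_height)),
                     a = 2, d_max = 0.5 * p),
      structure_spec("a1", 3L, "annulus", list(ref = "ptv", width = 10, inner = 0),
                     a = 0.5, d_max = p),
      structure_spec("a2", 4L, "annulus", list(ref = "ptv", width = 10, inner = 10),
                     a = 0.5, d_max = 0.7 * p),
      structure_spec("a3", 5L, "annulus", list(ref = "ptv", width = 10, inner = 20),
                     a = 0.5, d_max = 0.5 * p),
      structure_spec("body", 100L, "cylinder",
                     list(centre = c(0, 0, 0), radius = body_radius,
                          half_height = body_half_height),
                     a = 0.05, d_max = 0.4 * p)
    ),
    prescription = p
  )
}
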