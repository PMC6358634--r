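#' Pencil-kernel parameters
#'
#' The dose engine models each bixel as a divergent pencil beam with
#' exponential depth attenuation, an inverse-square factor and a Gaussian
#' lateral penumbra widening linearly with depth:
#' \deqn{D(r, z, l) = C \, (SAD/r)^2 \, e^{-\mu z} \, e^{-l^2 / 2\sigma(z)^2},
#'   \quad \sigma(z) = \sigma_0 + k z}
#' with r the distance from the source, z the depth inside the body along
#' the ray, and l the perpendicular distance from the bixel ray. The
#' calibration fixes the on-axis dose per unit bixel weight at a reference
#' depth (with the inverse-square factor at 1). Defaults are qualitatively
#' water-like for a 6 MV beam; all are configurable.
#'
#' @param mu effective linear attenuation, per mm.
#' @param sigma0 penumbra sigma at zero depth, mm.
#' @param k penumbra widening per mm depth (dimensionless).
#' @param calibration Gy per weight unit at `calibration_depth` on axis.
#' @param calibration_depth reference depth, mm.
#' @return A `kernel_params` object.
#' @export
kernel_params <- function(mu = 0.005, sigma0 = 2, k = 0.02,
                          calibration = 0.01, calibration_depth = 15) {
  if (mu <= 0 || sigma0 <= 0 || k < 0) stopf("kernel requires mu > 0, sigma0 > 0, k >= 0")
  structure(list(mu = mu, sigma0 = sigma0, k = k, calibration = calibration,
                 calibration_depth = calibration_depth,
                 c0 = calibration / exp(-mu * calibration_depth)),
            class = "kernel_params")
}

# Kernel dose for a voxel at source distance r, depth z inside the body and
# lateral offset l from the ray (all mm). Exposed internally for testing.
pencil_kernel_dose <- function(r, depth, ell, kernel, sad) {
  sg <- kernel$sigma0 + kernel$k * depth
  kernel$c0 * (sad / r)^2 * exp(-kernel$mu * depth) * exp(-ell^2 / (2 * sg^2))
}

#' MLC model
#'
#' Geometry of the multileaf collimator: 26 leaf pairs of width 3.85 mm,
#' maximum field 115 mm x 100 mm at 800 mm source-axis distance. One
#' fluence-grid row spans two adjacent leaf pairs (bixel height
#' 2 x leaf width = 7.7 mm), so at most 13 grid rows are deliverable.
#'
#' @param n_leaf_pairs,leaf_width_mm,max_field_mm MLC geometry.
#' @return An `mlc_model` object.
#' @export
mlc_model <- function(n_leaf_pairs = 26, leaf_width_mm = 3.85,
                      max_field_mm = c(115, 100)) {
  structure(list(n_leaf_pairs = n_leaf_pairs, leaf_width_mm = leaf_width_mm,
                 max_field_mm = max_field_mm,
                 max_rows = n_leaf_pairs %/% 2L),
            class = "mlc_model")
}

beam_basis <- function(dir) {
  zref <- if (abs(dir[3]) > 0.99) c(1, 0, 0) else c(0, 0, 1)
  e_col <- unit(cross3(dir, zref))   # leaf travel direction
  e_row <- cross3(dir, e_col)        # across-leaf direction
  list(u = dir, e_col = e_col, e_row = e_row)
}

#' Fluence grid in the beam's eye view
#'
#' Builds the bixel grid of one beam: the axis-aligned bounding box (in BEV
#' coordinates at isocentre distance) of the divergently projected PTV voxel
#' centres, expanded by `margin` and snapped outward to whole bixels.
#' Bixel size is (2 x MLC leaf width) across leaves by 5 mm along leaf
#' travel; rows map to pairs of MLC leaves, with collimator rotation fixed
#' at 0 degrees.
#'
#' @param beam one row of a `node_set` (or list with `x`, `y`, `z`).
#' @param phantom a `voxel_phantom`.
#' @param margin BEV margin around the projected PTV, mm.
#' @param mlc an [mlc_model].
#' @param along_mm bixel size along leaf travel, mm.
#' @return A `fluence_grid`: beam geometry, bixel sizes, row/col counts and
#'   BEV origin. Bixel (row r, col c) has linear index r + (c-1)*nrow.
#' @export
fluence_grid_for_beam <- function(beam, phantom, margin = 5,
                                  mlc = mlc_model(), along_mm = 5) {
  sad <- attr(beam, "sad") %||% 800
  source <- c(beam$x, beam$y, beam$z)
  dir <- unit(phantom$target_point - source)
  basis <- beam_basis(dir)
  ptv <- structure_voxels(phantom, "ptv")
  P <- voxel_centres(phantom$grid)[ptv, , drop = FALSE]
  Q <- sweep(P, 2, source)
  tpar <- Q %*% basis$u
  a <- sad * (Q %*% basis$e_col) / tpar  # along leaf travel
  b <- sad * (Q %*% basis$e_row) / tpar  # across leaves
  across_mm <- 2 * mlc$leaf_width_mm
  ar <- range(a) + c(-margin, margin)
  br <- range(b) + c(-margin, margin)
  if (diff(range(a)) < 1e-9 && diff(range(b)) < 1e-9)
    warnf("PTV projects to a point for beam %s; using a single-bixel grid",
          format(beam$index %||% ""))
  col0 <- floor(ar[1] / along_mm) * along_mm
  ncol <- max(1L, ceiling((ar[2] - col0) / along_mm))
  row0 <- floor(br[1] / across_mm) * across_mm
  nrow <- max(1L, ceiling((br[2] - row0) / across_mm))
  if (nrow > mlc$max_rows)
    stopf("fluence grid needs %d rows but the MLC supports %d (2 leaf pairs per row)",
          nrow, mlc$max_rows)
  structure(list(beam_index = beam$index %||% NA_integer_, source = source,
                 sad = sad, u = basis$u, e_col = basis$e_col, e_row = basis$e_row,
                 along_mm = along_mm, across_mm = across_mm,
                 nrow = as.integer(nrow), ncol = as.integer(ncol),
                 row0 = row0, col0 = col0),
            class = "fluence_grid")
}

n_bixels <- function(grid) grid$nrow * grid$ncol

# BEV centre coordinates (along, across) of every bixel, linear order
# row-fastest within column.
bixel_centres <- function(grid) {
  r <- seq_len(grid$nrow)
  c <- seq_len(grid$ncol)
  cbind(along = rep(grid$col0 + (c - 0.5) * grid$along_mm, each = grid$nrow),
        across = rep(grid$row0 + (r - 0.5) * grid$across_mm, times = grid$ncol))
}

#' Dose-influence block for one beam
#'
#' Computes the sparse dose matrix of one beam: entry (i, j) is the dose at
#' voxel i per unit weight of bixel j. For each bixel a ray is cast from the
#' source through the bixel centre at the isocentre plane; radiological
#' depth along the ray is obtained by uniform-step ray marching against the
#' body solid (step = half the smallest voxel spacing), and each in-body
#' voxel receives the pencil-kernel dose at its ray-projected depth and
#' perpendicular offset. Entries below `threshold` of the column maximum
#' are dropped (default 0.015%); air voxels are always zero.
#'
#' @param beam one row of a `node_set`.
#' @param grid the beam's [fluence_grid_for_beam] output.
#' @param phantom a `voxel_phantom`.
#' @param kernel a [kernel_params].
#' @param threshold per-column relative dose cutoff.
#' @param cutoff_sigma hard lateral support of the kernel, in sigmas.
#' @return A `dgCMatrix` of size (n voxels) x (n bixels).
#' @export
compute_dij <- function(beam, grid, phantom, kernel = kernel_params(),
                        threshold = 1.5e-4, cutoff_sigma = 5) {
  source <- grid$source
  sad <- grid$sad
  vox <- which(phantom$labels > 0L)
  P <- voxel_centres(phantom$grid)[vox, , drop = FALSE]
  Q <- sweep(P, 2, source)
  D2 <- rowSums(Q^2)
  tax <- as.numeric(Q %*% grid$u)

  # candidate voxels: within the projected field half-extent plus kernel support
  bc <- bixel_centres(grid)
  half_extent <- max(abs(range(bc[, 1]) + c(-0.5, 0.5) * grid$along_mm),
                     abs(range(bc[, 2]) + c(-0.5, 0.5) * grid$across_mm))
  lat_ax2 <- pmax(0, D2 - tax^2)
  body_diag <- vnorm(phantom$grid$shape * phantom$grid$spacing)
  sigma_max <- kernel$sigma0 + kernel$k * body_diag
  cut_mm <- cutoff_sigma * sigma_max
  cand <- which(lat_ax2 <= (half_extent * pmax(tax, 1) / sad + cut_mm + 5)^2)
  Qc <- Q[cand, , drop = FALSE]
  D2c <- D2[cand]
  rc <- sqrt(D2c)
  rows_global <- vox[cand]

  body <- phantom$structures[["body"]]
  step <- min(phantom$grid$spacing) / 2
  tgrid <- seq(max(0, min(tax) - 2 * step), max(tax) + 2 * step, by = step)

  nb <- n_bixels(grid)
  ii <- vector("list", nb); xx <- vector("list", nb)
  missed <- 0L
  for (j in seq_len(nb)) {
    centre <- source + sad * grid$u + bc[j, 1] * grid$e_col + bc[j, 2] * grid$e_row
    v <- unit(centre - source)
    # radiological depth along the ray by marching against the body solid
    S <- outer(tgrid, v)
    S[, 1] <- S[, 1] + source[1]; S[, 2] <- S[, 2] + source[2]; S[, 3] <- S[, 3] + source[3]
    inside <- structure_contains(body, S, phantom$structures)
    if (!any(inside)) { missed <- missed + 1L; ii[[j]] <- integer(0); xx[[j]] <- numeric(0); next }
    cumdepth <- cumsum(inside) * step
    tv <- as.numeric(Qc %*% v)
    l2 <- pmax(0, D2c - tv^2)
    sel <- which(l2 <= cut_mm^2)
    if (!length(sel)) { ii[[j]] <- integer(0); xx[[j]] <- numeric(0); next }
    depth <- approx(tgrid, cumdepth, xout = tv[sel], rule = 2)$y
    dose <- pencil_kernel_dose(rc[sel], depth, sqrt(l2[sel]), kernel, sad)
    keep <- dose >= threshold * max(dose)
    ii[[j]] <- rows_global[sel[keep]]
    xx[[j]] <- dose[keep]
  }
  if (missed > 0L)
    warnf("beam %s: %d bixel rays miss the body entirely (empty columns)",
          format(grid$beam_index), missed)
  lens <- lengths(ii)
  Matrix::sparseMatrix(i = unlist(ii), j = rep.int(seq_len(nb), lens),
                       x = unlist(xx), dims = c(n_voxels(phantom$grid), nb))
}

#' Assemble the dose-influence matrix for a node set
#'
#' Computes (or loads from cache) one sparse block per node. The cache key
#' is a content hash of (phantom, nodes, kernel, threshold); blocks are
#' stored as MatrixMarket text files with a JSON sidecar, so repeated
#' evaluations during beam selection reuse them. A corrupt cache is
#' recomputed with a warning.
#'
#' @param nodes a `node_set`.
#' @param phantom a `voxel_phantom`.
#' @param kernel a [kernel_params].
#' @param cache_dir directory for the on-disk cache, or NULL to disable.
#' @param threshold,margin passed to the per-beam computation.
#' @param verbose print progress.
#' @return A `dose_influence` object: list of per-beam `blocks`
#'   (dgCMatrix), the matching `grids`, `nodes` and `nvox`.
#' @export
assemble_dij <- function(nodes, phantom, kernel = kernel_params(),
                         cache_dir = NULL, threshold = 1.5e-4, margin = 5,
                         verbose = FALSE) {
  key <- content_hash(list(
    grid = phantom$grid, labels = phantom$labels,
    nodes = nodes[, c("index", "x", "y", "z")],
    sad = attr(nodes, "sad"), target = attr(nodes, "target"),
    kernel = kernel[c("mu", "sigma0", "k", "calibration", "calibration_depth")],
    threshold = threshold, margin = margin))
  if (!is.null(cache_dir)) {
    hit <- try(read_dij_cache(cache_dir, key, nrow(nodes)), silent = TRUE)
    if (!inherits(hit, "try-error") && !is.null(hit)) return(hit)
  }
  blocks <- vector("list", nrow(nodes))
  grids <- vector("list", nrow(nodes))
  for (b in seq_len(nrow(nodes))) {
    beam <- nodes[b, ]
    attr(beam, "sad") <- attr(nodes, "sad")
    grids[[b]] <- fluence_grid_for_beam(beam, phantom, margin = margin)
    blocks[[b]] <- compute_dij(beam, grids[[b]], phantom, kernel, threshold)
    if (verbose) message(sprintf("d_ij: beam %d/%d (%d bixels, %d entries)",
                                 b, nrow(nodes), ncol(blocks[[b]]),
                                 length(blocks[[b]]@x)))
  }
  dij <- structure(list(blocks = blocks, grids = grids, nodes = nodes,
                        nvox = n_voxels(phantom$grid), key = key),
                   class = "dose_influence")
  if (!is.null(cache_dir)) try(write_dij_cache(dij, cache_dir), silent = TRUE)
  dij
}

dij_cache_path <- function(cache_dir, key) file.path(cache_dir, paste0("dij-", key))

# MatrixMarket coordinate text at full double precision, so a cache hit is
# bit-identical to the fresh computation.
write_mm_full <- function(m, path) {
  tm <- as(m, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(tm@x))), con)
  writeLines(sprintf("%d %d %.17g", tm@i + 1L, tm@j + 1L, tm@x), con)
  invisible(path)
}

write_dij_cache <- function(dij, cache_dir) {
  dir <- dij_cache_path(cache_dir, dij$key)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in seq_along(dij$blocks))
    write_mm_full(dij$blocks[[b]], file.path(dir, sprintf("block-%04d.mtx", b)))
  meta <- list(hash = dij$key, n_beams = length(dij$blocks), nvox = dij$nvox,
               n_bixels = vapply(dij$blocks, ncol, 1L))
  jsonlite::write_json(meta, file.path(dir, "sidecar.json"), auto_unbox = TRUE)
  saveRDS(dij[c("grids", "nodes")], file.path(dir, "geometry.rds"), version = 2)
  invisible(dir)
}

read_dij_cache <- function(cache_dir, key, n_beams) {
  dir <- dij_cache_path(cache_dir, key)
  if (!file.exists(file.path(dir, "sidecar.json"))) return(NULL)
  meta <- jsonlite::read_json(file.path(dir, "sidecar.json"), simplifyVector = TRUE)
  if (!identical(meta$hash, key) || meta$n_beams != n_beams) {
    warnf("d_ij cache at %s is corrupt; recomputing", dir)
    return(NULL)
  }
  geom <- readRDS(file.path(dir, "geometry.rds"))
  blocks <- lapply(seq_len(n_beams), function(b) {
    m <- Matrix::readMM(file.path(dir, sprintf("block-%04d.mtx", b)))
    as(as(m, "CsparseMatrix"), "generalMatrix")
  })
  structure(list(blocks = blocks, grids = geom$grids, nodes = geom$nodes,
                 nvox = meta$nvox, key = key),
            class = "dose_influence")
}

# Column-bind the blocks of the given beams (1-based positions) into one
# sparse matrix; returns the matrix plus per-beam column offsets.
dij_submatrix <- function(dij, beams) {
  blocks <- dij$blocks[beams]
  ncols <- vapply(blocks, ncol, 1L)
  A <- do.call(cbind, blocks)
  list(A = A, beams = beams, ncols = ncols,
       offsets = cumsum(c(0L, head(ncols, -1L))))
}
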