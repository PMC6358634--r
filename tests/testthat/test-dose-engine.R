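test_that("the fluence grid covers the PTV beam's eye view with the margin", {
  # default-resolution phantom: spherical PTV radius 25 mm, 5 mm voxels
  ph <- build_phantom(default_phantom_spec())
  ns <- generate_nodeset(2, target = ph$target_point)
  beam <- ns[1, ]; attr(beam, "sad") <- 800
  g <- fluence_grid_for_beam(beam, ph, margin = 5)
  expect_gte(g$ncol * g$along_mm, 50 + 2 * 5)     # diameter + 2 x margin
  expect_gte(g$nrow * g$across_mm, 50 + 2 * 5)
  expect_lte(g$nrow, mlc_model()$max_rows)
  # margin 0: the grid covers the projected voxel centres only (plus snapping)
  g0 <- fluence_grid_for_beam(beam, ph, margin = 0)
  P <- mlcbos:::voxel_centres(ph$grid)[which(ph$labels == 1L), , drop = FALSE]
  Q <- sweep(P, 2, g0$source)
  tpar <- Q %*% g0$u
  a <- 800 * (Q %*% g0$e_col) / tpar
  expect_lte(g0$col0, min(a))
  expect_gte(g0$col0 + g0$ncol * g0$along_mm, max(a))
  expect_lte(g0$ncol * g0$along_mm, diff(range(a)) + 2 * g0$along_mm)
  expect_lte(g0$ncol, g$ncol)
})

test_that("opposed beams over a symmetric phantom get congruent grids", {
  ph <- small_phantom()
  tp <- ph$target_point
  up <- data.frame(index = 0L, x = tp[1], y = tp[2], z = tp[3] + 800)
  dn <- data.frame(index = 1L, x = tp[1], y = tp[2], z = tp[3] - 800)
  attr(up, "sad") <- attr(dn, "sad") <- 800
  gu <- fluence_grid_for_beam(up, ph)
  gd <- fluence_grid_for_beam(dn, ph)
  expect_identical(c(gu$nrow, gu$ncol), c(gd$nrow, gd$ncol))
})

test_that("the pencil kernel has the stated lateral and depth behaviour", {
  k <- kernel_params()
  # lateral: dose at offset sigma is exp(-1/2) of the axial dose at equal depth
  depth <- 30
  sg <- k$sigma0 + k$k * depth
  ratio <- mlcbos:::pencil_kernel_dose(800, depth, sg, k, 800) /
    mlcbos:::pencil_kernel_dose(800, depth, 0, k, 800)
  expect_equal(ratio, exp(-0.5), tolerance = 1e-12)
  # calibration: axial dose at the reference depth with unit inverse-square
  expect_equal(mlcbos:::pencil_kernel_dose(800, 15, 0, k, 800), 0.01, tolerance = 1e-12)
  # depth monotonicity after removing the inverse-square factor
  z <- seq(5, 200, by = 5)
  d <- mlcbos:::pencil_kernel_dose(800, z, 0, k, 800)
  expect_true(all(diff(d) < 0))
})

test_that("d_ij columns are positive, thresholded per column, and linear", {
  sc <- small_case()
  b <- sc$dij$blocks[[1]]
  expect_true(all(b@x > 0))
  for (j in sample(ncol(b), 5)) {
    v <- b[, j, drop = FALSE]@x
    if (length(v)) expect_gte(min(v) / max(v), 1.5e-4 - 1e-12)
  }
  # superposition: a two-bixel-open field equals the sum of the two columns
  w <- numeric(ncol(b)); w[c(1, 2)] <- c(1, 1)
  expect_equal(as.numeric(b %*% w), as.numeric(b[, 1] + b[, 2]), tolerance = 1e-12)
  # air voxels receive no dose
  ph <- sc$phantom
  dose <- as.numeric(b %*% rep(1, ncol(b)))
  expect_true(all(dose[ph$labels == 0L] == 0))
})

test_that("depth dose falls monotonically along the central axis after inverse-square removal", {
  ph <- small_phantom()
  tp <- ph$target_point
  beam <- data.frame(index = 0L, x = tp[1], y = tp[2], z = tp[3] + 800)
  attr(beam, "sad") <- 800
  g <- fluence_grid_for_beam(beam, ph)
  k <- kernel_params()
  blk <- compute_dij(beam, g, ph, k)
  # bixel whose ray passes through the PTV centre
  bc <- mlcbos:::bixel_centres(g)
  j <- which.min(bc[, 1]^2 + bc[, 2]^2)
  col <- as.numeric(blk[, j])
  P <- mlcbos:::voxel_centres(ph$grid)
  on_axis <- which(abs(P[, 1] - tp[1]) < 1 & abs(P[, 2] - tp[2]) < 1 & col > 0)
  on_axis <- on_axis[order(-P[on_axis, 3])]   # increasing depth from the top
  r2 <- (800 - (P[on_axis, 3] - tp[3]))^2
  corrected <- col[on_axis] * r2 / 800^2
  expect_true(all(diff(corrected) < 0))
})

test_that("the disk cache returns the assembled matrix byte-identically", {
  ph <- small_phantom()
  ns <- generate_nodeset(3, target = ph$target_point)
  dir <- withr::local_tempdir()
  fresh <- assemble_dij(ns, ph, cache_dir = dir)
  cached <- assemble_dij(ns, ph, cache_dir = dir)
  for (b in seq_along(fresh$blocks))
    expect_true(all(fresh$blocks[[b]] == cached$blocks[[b]]))
  # corrupting the sidecar forces a clean recomputation
  sidecar <- list.files(dir, pattern = "sidecar", recursive = TRUE, full.names = TRUE)
  writeLines('{"hash": "broken"}', sidecar)
  redo <- suppressWarnings(assemble_dij(ns, ph, cache_dir = dir))
  expect_true(all(fresh$blocks[[1]] == redo$blocks[[1]]))
})
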