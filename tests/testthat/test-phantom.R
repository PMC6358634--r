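test_that("overlap is resolved by priority with PTV on top and body at the bottom", {
  ph <- small_phantom()
  nms <- names(ph$structures)
  P <- mlcbos:::voxel_centres(ph$grid)
  # a voxel inside both the PTV and the abutting OAR solid must be PTV
  in_ptv <- mlcbos:::structure_contains(ph$structures[["ptv"]], P, ph$structures)
  in_oar <- mlcbos:::structure_contains(ph$structures[["oar"]], P, ph$structures)
  both <- which(in_ptv & in_oar)
  if (length(both)) expect_true(all(ph$labels[both] == match("ptv", nms)))
  expect_true(all(ph$labels[in_ptv] == match("ptv", nms)))
  # voxels inside the body and nothing else carry the body label
  others <- Reduce(`|`, lapply(setdiff(nms, "body"), function(s)
    mlcbos:::structure_contains(ph$structures[[s]], P, ph$structures)))
  in_body <- mlcbos:::structure_contains(ph$structures[["body"]], P, ph$structures)
  expect_true(all(ph$labels[in_body & !others] == match("body", nms)))
})

test_that("labels are a partition dominated by priority", {
  ph <- small_phantom()
  P <- mlcbos:::voxel_centres(ph$grid)
  in_body <- mlcbos:::structure_contains(ph$structures[["body"]], P, ph$structures)
  # every in-body voxel has exactly one non-air label; air voxels are outside
  expect_true(all(ph$labels[in_body] > 0L))
  expect_true(all(ph$labels[!in_body] == 0L))
  expect_identical(sum(table(ph$labels[ph$labels > 0L])), sum(in_body))
  # priority dominance: the label's priority is <= that of any containing structure
  prios <- vapply(ph$structures, `[[`, 1L, "priority")
  for (k in seq_along(ph$structures)) {
    inside <- which(mlcbos:::structure_contains(ph$structures[[k]], P, ph$structures) & in_body)
    expect_true(all(prios[ph$labels[inside]] <= prios[k]))
  }
})

test_that("a phantom without overlaps labels by naive membership", {
  spec <- list(
    grid = voxel_grid(c(12, 12, 8), rep(10, 3), c(-55, -55, -35)),
    structures = list(
      structure_spec("ptv", 1L, "sphere", list(centre = c(25, 0, 0), radius = 12),
                     a = 1, d_min = 40, d_max = 44),
      structure_spec("oar", 2L, "sphere", list(centre = c(-25, 0, 0), radius = 12),
                     a = 1, d_max = 20),
      structure_spec("body", 9L, "cylinder",
                     list(centre = c(0, 0, 0), radius = 55, half_height = 35),
                     a = 1, d_max = 30)))
  ph <- build_phantom(spec)
  P <- mlcbos:::voxel_centres(ph$grid)
  for (nm in c("ptv", "oar")) {
    inside <- mlcbos:::structure_contains(ph$structures[[nm]], P, ph$structures)
    expect_identical(which(ph$labels == match(nm, names(ph$structures))), which(inside))
  }
})

test_that("annular shells are concentric rings of the stated width around the PTV", {
  ph <- small_phantom()
  P <- mlcbos:::voxel_centres(ph$grid)
  ctr <- ph$structures[["ptv"]]$params$centre
  rad <- ph$structures[["ptv"]]$params$radius
  dist <- sqrt(rowSums(sweep(P, 2, ctr)^2)) - rad
  for (k in 1:3) {
    ring <- which(ph$labels == match(paste0("a", k), names(ph$structures)))
    expect_gt(length(ring), 0)
    expect_true(all(dist[ring] > (k - 1) * 10 - 1e-6))
    expect_true(all(dist[ring] <= k * 10 + 1e-6))
  }
})

test_that("invalid phantoms are rejected", {
  spec <- default_phantom_spec(spacing = 10, body_radius = 80,
                               body_half_height = 60, ptv_radius = 20,
                               ptv_offset = 25, oar_radius = 10)
  dup <- spec
  dup$structures[[2]]$priority <- 1L
  expect_error(build_phantom(dup), "unique")
  outside <- spec
  outside$structures[[1]]$params$centre <- c(150, 0, 0)
  expect_error(build_phantom(outside), "body|voxels")
  expect_error(structure_spec("bad", 1L, "sphere", list(centre = c(0, 0, 0), radius = 5),
                              a = -1), "a must be")
  expect_error(structure_spec("bad", 1L, "sphere", list(centre = c(0, 0, 0), radius = 5),
                              a = 1, d_min = 40), "d_min")
})
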