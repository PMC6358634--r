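test_that("DVH curves match brute-force voxel counting", {
  ph <- small_phantom()
  nvox <- prod(ph$grid$shape)
  # uniform dose: step function at D
  d <- numeric(nvox); d[ph$labels > 0] <- 10
  curve <- dvh(d, ph, "ptv", bin_width = 1)
  expect_true(all(curve$volume_fraction[curve$dose_Gy <= 10] == 1))
  expect_true(all(curve$volume_fraction[curve$dose_Gy > 10] == 0))
  expect_equal(curve$volume_fraction[1], 1)
  # half/half split
  ptv <- which(ph$labels == 1L)
  d2 <- numeric(nvox)
  d2[ptv[seq_len(floor(length(ptv) / 2))]] <- 10
  d2[setdiff(ptv, ptv[seq_len(floor(length(ptv) / 2))])] <- 20
  expect_equal(volume_at_dose(d2, ph, "ptv", 15),
               1 - floor(length(ptv) / 2) / length(ptv))
  # random doses: V(edge) equals direct counting at every edge; monotone
  set.seed(5)
  d3 <- numeric(nvox); d3[ptv] <- runif(length(ptv), 0, 30)
  curve3 <- dvh(d3, ph, "ptv", bin_width = 0.5)
  brute <- vapply(curve3$dose_Gy, function(e) sum(d3[ptv] >= e) / length(ptv), 1)
  expect_equal(curve3$volume_fraction, brute)
  expect_true(all(diff(curve3$volume_fraction) <= 0))
  expect_error(dvh(d3, ph, "nope"), "unknown")
})

test_that("conformity index is prescription volume over PTV volume", {
  ph <- small_phantom()
  nvox <- prod(ph$grid$shape)
  ptv <- which(ph$labels == 1L)
  d <- numeric(nvox); d[ptv] <- 40
  expect_equal(conformity_index(d, ph, 40), 1)
  expect_equal(conformity_index(numeric(nvox), ph, 40), 0)
  # prescription isodose covering the PTV plus an equal in-body volume -> 2
  extra <- setdiff(which(ph$labels > 0), ptv)[seq_along(ptv)]
  d[extra] <- 40
  expect_equal(conformity_index(d, ph, 40), 2)
})

test_that("monitor units scale linearly and the time model is additive", {
  shape <- matrix(c(1, 3), 1, 2)
  plan1 <- structure(list(beams = 1L,
                          apertures = list(list(shape = shape, weight = 100, beam = 1L)),
                          dose = numeric(0)), class = "treatment_plan")
  expect_equal(mu_per_gray(plan1, 10), 10)
  plan2 <- plan1; plan2$apertures[[1]]$weight <- 200
  expect_equal(mu_per_gray(plan2, 10), 20)
  empty <- structure(list(beams = integer(0), apertures = list(),
                          dose = numeric(0)), class = "treatment_plan")
  expect_equal(mu_per_gray(empty, 10), 0)
  tp <- time_model_params()
  expect_equal(estimate_treatment_time(empty, tp), tp$setup_min)
  # adding one node with one aperture adds traversal + imaging + reshape + MU time
  expect_equal(estimate_treatment_time(plan1, tp),
               tp$setup_min + (tp$traversal_s + tp$imaging_s) / 60 +
                 tp$reshape_s / 60 + 100 / tp$mu_rate)
  plan3 <- plan1
  plan3$apertures[[2]] <- list(shape = shape, weight = 50, beam = 2L)
  expect_equal(estimate_treatment_time(plan3, tp) - estimate_treatment_time(plan1, tp),
               (tp$traversal_s + tp$imaging_s) / 60 + tp$reshape_s / 60 + 50 / tp$mu_rate)
  expect_error(time_model_params(setup_min = -1), ">= 0")
})

test_that("constraint checking agrees with direct voxel counting", {
  ph <- small_phantom()
  nvox <- prod(ph$grid$shape)
  oar <- which(ph$labels == match("oar", names(ph$structures)))
  d <- numeric(nvox)
  d[oar[seq_len(floor(length(oar) / 2))]] <- 17   # half the OAR at 17 Gy
  cons <- data.frame(
    structure = c("oar", "oar", "ptv", "ghost"),
    type = c("max_dose_at_volume", "max_dose_at_absolute_volume",
             "min_dose_at_volume", "max_dose_at_volume"),
    dose_Gy = c(18.12, 10, 35, 1), volume = c(50, 2, 95, 10),
    volume_unit = c("percent", "cm3", "percent", "percent"))
  rep <- suppressWarnings(check_constraints(d, ph, cons))
  expect_true(rep$pass[1])                        # 0% of OAR >= 18.12 Gy
  vol_cm3 <- sum(d[oar] >= 10) * prod(ph$grid$spacing) / 1000
  expect_equal(rep$achieved[2], vol_cm3)
  expect_false(rep$pass[3])                       # uniform 0 fails a min constraint
  expect_true(is.na(rep$pass[4]))                 # unknown structure flagged, not fatal
  # all-zero dose passes any max constraint
  zero <- check_constraints(numeric(nvox), ph, cons[1, ])
  expect_true(zero$pass[1])
})

test_that("shipped protocol presets load and have the documented schema", {
  proto <- yaml::read_yaml(system.file("extdata", "protocols", "constraints.yaml",
                                       package = "mlcbos"))
  expect_setequal(names(proto), c("prostate_a", "prostate_b", "lung", "liver", "breast"))
  pb <- do.call(rbind, lapply(proto$prostate_b, as.data.frame))
  expect_true(all(c("structure", "type", "dose_Gy", "volume") %in% names(pb)))
  frac <- yaml::read_yaml(system.file("extdata", "protocols", "fractionation.yaml",
                                      package = "mlcbos"))
  expect_equal(frac$liver$total_dose_gy, 42.75)
  expect_equal(frac$prostate_b$fractions, 4)
})
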