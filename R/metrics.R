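#' Cumulative dose-volume histogram
#'
#' Fraction of a structure's volume receiving at least each dose level.
#'
#' @param dose dose per voxel (full phantom length), Gy.
#' @param phantom a `voxel_phantom`.
#' @param structure structure name.
#' @param bin_width histogram bin width, Gy.
#' @return data.frame(structure, dose_Gy, volume_fraction), monotone
#'   non-increasing, starting at 1 at dose 0.
#' @export
dvh <- function(dose, phantom, structure, bin_width = 0.05) {
  v <- dose[structure_voxels(phantom, structure)]
  if (!length(v)) stopf("structure '%s' is empty", structure)
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  frac <- vapply(edges, function(e) mean(v >= e), 1)
  data.frame(structure = structure, dose_Gy = edges, volume_fraction = frac)
}

#' Volume fraction at dose
#'
#' V(d): fraction of the structure receiving at least `d` Gy.
#' @inheritParams dvh
#' @param d dose level, Gy.
#' @export
volume_at_dose <- function(dose, phantom, structure, d) {
  v <- dose[structure_voxels(phantom, structure)]
  mean(v >= d)
}

#' Conformity index
#'
#' Volume receiving the prescription dose (anywhere in the body) divided by
#' the PTV volume.
#'
#' @param dose dose per voxel, Gy.
#' @param phantom a `voxel_phantom`.
#' @param prescription prescription dose, Gy.
#' @return Nonnegative ratio.
#' @export
conformity_index <- function(dose, phantom, prescription) {
  in_body <- phantom$labels > 0L
  sum(dose[in_body] >= prescription) / length(structure_voxels(phantom, "ptv"))
}

#' Monitor units per gray
#'
#' @param plan a `treatment_plan`.
#' @param prescription prescription dose, Gy.
#' @param mu_per_weight MU per fluence weight unit.
#' @export
mu_per_gray <- function(plan, prescription, mu_per_weight = 1) {
  total_mu(plan, mu_per_weight) / prescription
}

#' Treatment-time model parameters
#'
#' Components of the delivery-time estimate: initial setup, robot traversal
#' and imaging per node, MLC reshaping per aperture, and beam-on time from
#' total MU at a fixed delivery rate. The functional form is additive and
#' strictly increasing in each component count; the default parameters are
#' chosen to reproduce the qualitative ordering of delivery times across
#' full, preset-subset and orientation-selected paths, not any vendor's
#' absolute minutes.
#'
#' @param setup_min initial setup, minutes.
#' @param traversal_s robot traversal per node, seconds.
#' @param imaging_s imaging per node, seconds.
#' @param reshape_s MLC reshaping per aperture, seconds.
#' @param mu_rate MU per minute.
#' @return A `time_model_params` object.
#' @export
time_model_params <- function(setup_min = 5, traversal_s = 10, imaging_s = 5,
                              reshape_s = 3, mu_rate = 800) {
  p <- list(setup_min = setup_min, traversal_s = traversal_s,
            imaging_s = imaging_s, reshape_s = reshape_s, mu_rate = mu_rate)
  if (any(unlist(p) < 0)) stopf("time model parameters must be >= 0")
  structure(p, class = "time_model_params")
}

#' Estimated treatment time
#'
#' T = setup + n_nodes (traversal + imaging) + n_apertures x reshape
#' + MU / rate, in minutes.
#'
#' @param plan a `treatment_plan`.
#' @param params a [time_model_params].
#' @param mu_per_weight MU per fluence weight unit.
#' @return Minutes.
#' @export
estimate_treatment_time <- function(plan, params = time_model_params(),
                                    mu_per_weight = 1) {
  params$setup_min +
    n_active_nodes(plan) * (params$traversal_s + params$imaging_s) / 60 +
    length(plan$apertures) * params$reshape_s / 60 +
    total_mu(plan, mu_per_weight) / params$mu_rate
}

#' Clinical constraint report
#'
#' Evaluates each constraint against the dose distribution. Types:
#' `max_dose_at_volume` (V(dose) must not exceed volume %),
#' `min_dose_at_volume` (V(dose) must reach at least volume %), and
#' `max_dose_at_absolute_volume` (absolute volume in cm3 receiving >= dose
#' must not exceed the limit; uses the voxel volume from the grid spacing).
#' Unknown structures are flagged, not fatal.
#'
#' @param dose dose per voxel, Gy.
#' @param phantom a `voxel_phantom`.
#' @param constraints data.frame(structure, type, dose_Gy, volume,
#'   volume_unit) where volume_unit is "percent" or "cm3".
#' @return The constraints with columns `achieved` and `pass` (NA for
#'   unknown structures).
#' @export
check_constraints <- function(dose, phantom, constraints) {
  achieved <- numeric(nrow(constraints)); pass <- logical(nrow(constraints))
  for (r in seq_len(nrow(constraints))) {
    cs <- constraints[r, ]
    if (!cs$structure %in% names(phantom$structures)) {
      achieved[r] <- NA_real_; pass[r] <- NA
      warnf("constraint on unknown structure '%s' skipped", cs$structure)
      next
    }
    vf <- volume_at_dose(dose, phantom, cs$structure, cs$dose_Gy)
    if (identical(cs$type, "max_dose_at_absolute_volume")) {
      vol_cm3 <- vf * length(structure_voxels(phantom, cs$structure)) *
        voxel_volume_cm3(phantom$grid)
      achieved[r] <- vol_cm3
      pass[r] <- vol_cm3 <= cs$volume
    } else {
      achieved[r] <- 100 * vf
      pass[r] <- switch(cs$type,
        max_dose_at_volume = achieved[r] <= cs$volume,
        min_dose_at_volume = achieved[r] >= cs$volume,
        stopf("unknown constraint type '%s'", cs$type))
    }
  }
  cbind(constraints, achieved = achieved, pass = pass)
}

#' Plan metric summary
#'
#' @param plan a `treatment_plan`.
#' @param phantom a `voxel_phantom`.
#' @param prescription prescription dose, Gy.
#' @param time_params a [time_model_params].
#' @param mu_per_weight MU per fluence weight unit.
#' @return list of headline metrics.
#' @export
plan_metrics <- function(plan, phantom, prescription,
                         time_params = time_model_params(), mu_per_weight = 1) {
  list(
    n_nodes = n_active_nodes(plan),
    n_apertures = length(plan$apertures),
    objective_value = plan$objective_value,
    ptv_coverage = volume_at_dose(plan$dose, phantom, "ptv", prescription),
    conformity_index = conformity_index(plan$dose, phantom, prescription),
    mu_per_gray = mu_per_gray(plan, prescription, mu_per_weight),
    treatment_time_min = estimate_treatment_time(plan, time_params, mu_per_weight)
  )
}

#' Write DVH curves for all structures to CSV
#'
#' @param dose dose per voxel, Gy.
#' @param phantom a `voxel_phantom`.
#' @param path output CSV path.
#' @param bin_width DVH bin width, Gy.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dose, phantom, path, bin_width = 0.05) {
  present <- names(phantom$structures)[unique(phantom$labels[phantom$labels > 0L])]
  curves <- do.call(rbind, lapply(present, function(s) dvh(dose, phantom, s, bin_width)))
  write.csv(curves, path, row.names = FALSE)
  invisible(path)
}
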