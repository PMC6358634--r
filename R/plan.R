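#' Inverse-plan a fixed beam set
#'
#' The full inner pipeline for a fixed set of beams: projected L-BFGS
#' fluence optimisation from a uniform start, sweep sequencing of each
#' beam's fluence map into MLC apertures, and aperture-weight optimisation
#' (direct aperture optimisation with fixed shapes) by the same L-BFGS
#' machinery. Apertures with weight below 1e-6 of the largest weight are
#' pruned from the deliverable plan.
#'
#' @param dij a `dose_influence` over the candidate nodes.
#' @param beams 1-based positions of the selected beams in `dij`.
#' @param obj a [plan_objective].
#' @param prescription prescription dose (Gy), used to scale the uniform
#'   starting fluence.
#' @param ptv_idx voxel indices of the PTV.
#' @param fluence_iters,dao_iters iteration budgets of the two stages
#'   (40/40 for standalone reference plans, 20/20 inside beam selection).
#' @param max_apertures per-beam segment cap (5 by default, 3 for simple
#'   targets).
#' @param levels quantization levels (default max_apertures + 2).
#' @return A `treatment_plan`: beams, apertures (beam, shape, weight),
#'   fluence, dose vector, objective value and optimiser traces.
#' @export
plan_beams <- function(dij, beams, obj, prescription, ptv_idx,
                       fluence_iters = 40, dao_iters = 40,
                       max_apertures = 5, levels = NULL) {
  beams <- sort(unique(beams))
  if (!length(beams)) {
    d <- numeric(dij$nvox)
    return(structure(list(beams = integer(0), apertures = list(),
                          fluence = numeric(0), dose = d,
                          objective_value = objective_value(d, obj),
                          traces = list()),
                     class = "treatment_plan"))
  }
  sub <- dij_submatrix(dij, beams)
  w0 <- initial_fluence(sub$A, ptv_idx, prescription)
  fo <- optimize_fluence(sub$A, obj, w0, optimizer_config(max_iter = fluence_iters))

  apertures <- list()
  for (k in seq_along(beams)) {
    b <- beams[k]
    g <- dij$grids[[b]]
    wmap <- matrix(fo$w[(sub$offsets[k] + 1):(sub$offsets[k] + sub$ncols[k])],
                   g$nrow, g$ncol)
    aps <- sequence_beam(wmap, max_apertures = max_apertures, levels = levels)
    for (a in aps) apertures[[length(apertures) + 1L]] <- c(a, list(beam = b))
  }
  if (!length(apertures)) {
    d <- numeric(dij$nvox)
    return(structure(list(beams = beams, apertures = list(), fluence = fo$w,
                          dose = d, objective_value = objective_value(d, obj),
                          traces = list(fluence = fo$trace)),
                     class = "treatment_plan"))
  }
  dao <- optimize_aperture_weights(apertures, dij, obj,
                                   optimizer_config(max_iter = dao_iters))
  for (k in seq_along(apertures)) apertures[[k]]$weight <- dao$weights[k]
  keep <- dao$weights >= 1e-6 * max(dao$weights)
  dose <- as.numeric(dao$columns %*% ifelse(keep, dao$weights, 0))
  structure(list(beams = beams, apertures = apertures[keep], fluence = fo$w,
                 dose = dose, objective_value = objective_value(dose, obj),
                 traces = list(fluence = fo$trace, dao = dao$trace)),
            class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("treatment_plan: %d beams, %d apertures, F = %.4g\n",
              length(x$beams), length(x$apertures), x$objective_value))
  invisible(x)
}

n_active_nodes <- function(plan) length(unique(vapply(plan$apertures, `[[`, 1L, "beam")))

total_mu <- function(plan, mu_per_weight = 1) {
  if (!length(plan$apertures)) return(0)
  sum(vapply(plan$apertures, `[[`, 1, "weight")) * mu_per_weight
}

#' Export a plan as JSON
#'
#' Writes nodes, apertures (leaf edges in bixel indices and mm at the
#' isocentre plane), weights and total MU.
#'
#' @param plan a `treatment_plan`.
#' @param dij the `dose_influence` the plan was made on.
#' @param path output file.
#' @param mu_per_weight MU per fluence weight unit.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, dij, path, mu_per_weight = 1) {
  nodes <- dij$nodes[plan$beams, , drop = FALSE]
  aps <- lapply(plan$apertures, function(a) {
    g <- dij$grids[[a$beam]]
    open <- which(!is.na(a$shape[, 1]))
    list(node_index = dij$nodes$index[a$beam],
         weight = a$weight,
         rows = lapply(open, function(r) list(
           row = r,
           left_bixel = a$shape[r, 1], right_bixel = a$shape[r, 2],
           left_mm = g$col0 + (a$shape[r, 1] - 1) * g$along_mm,
           right_mm = g$col0 + (a$shape[r, 2] - 1) * g$along_mm)))
  })
  jsonlite::write_json(
    list(nodes = nodes[, c("index", "x", "y", "z")],
         objective_value = plan$objective_value,
         total_mu = total_mu(plan, mu_per_weight),
         apertures = aps),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
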