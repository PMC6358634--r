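#' Default run configuration
#'
#' Nested list of every tunable of the planning pipeline, matching the YAML
#' schema of [load_config]: phantom geometry, node-set generation, kernel,
#' objective overrides, optimiser, sequencer, EA and time-model parameters.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    phantom = list(spacing = 5, body_radius = 120, body_half_height = 80,
                   ptv_radius = 25, ptv_offset = 40, oar_radius = 15),
    prescription = 40,
    nodes = list(count = 110, sad = 800, cap_deg = 110, exclusion_deg = 30,
                 min_sep_deg = 5, seed = 0, preset_subset = 36, file = NULL),
    kernel = list(mu = 0.005, sigma0 = 2, k = 0.02, calibration = 0.01,
                  calibration_depth = 15),
    dij = list(threshold = 1.5e-4, margin = 5, cache_dir = NULL),
    objectives = NULL,  # optional list of {structure, a, d_min, d_max}
    optimizer = list(fluence_iters = 40, dao_iters = 40),
    sequencer = list(max_apertures = 5, levels = NULL),
    ea = list(population = 20, generations = 20, k = 15, crossover = 0.4,
              mutation = 0.05, parent_fraction = 0.1, fluence_iters = 20,
              dao_iters = 20, seed = 1),
    time_model = list(setup_min = 5, traversal_s = 10, imaging_s = 5,
                      reshape_s = 3, mu_rate = 800),
    mu_per_weight = 1
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stopf("unknown configuration key '%s'", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]]) && !key %in% c("objectives")) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (cfg$phantom$spacing <= 0) stopf("phantom.spacing must be > 0")
  if (cfg$prescription <= 0) stopf("prescription must be > 0 Gy")
  if (!is.null(cfg$objectives)) {
    for (o in cfg$objectives) {
      if (is.null(o$structure)) stopf("each objective entry needs a 'structure'")
      if (is.null(o$a) || o$a < 0)
        stopf("objective for '%s': importance factor 'a' must be >= 0", o$structure)
    }
  }
  with(cfg$ea, {
    if (crossover <= 0 || crossover >= 1) stopf("ea.crossover must be in (0, 1)")
    if (mutation < 0 || mutation > 1) stopf("ea.mutation must be in [0, 1]")
  })
  if (cfg$kernel$mu <= 0 || cfg$kernel$sigma0 <= 0 || cfg$kernel$k < 0)
    stopf("kernel requires mu > 0, sigma0 > 0, k >= 0")
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML configuration, fills defaults, rejects unknown keys (naming
#' the offending key) and validates parameter ranges. The file's md5 hash is
#' attached as attribute `provenance`.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("configuration file '%s' does not exist", path)
  user <- yaml::read_yaml(path)
  cfg <- validate_config(merge_config(default_config(), user %||% list()))
  attr(cfg, "provenance") <- list(file = normalizePath(path),
                                  md5 = unname(tools::md5sum(path)))
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  attributes(cfg) <- attributes(cfg)["names"]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Materialise the objects a run needs from a validated configuration.
config_instantiate <- function(cfg) {
  spec <- do.call(default_phantom_spec, c(cfg$phantom, list(prescription = cfg$prescription)))
  phantom <- build_phantom(spec)
  nodes <- if (!is.null(cfg$nodes$file)) {
    read_nodeset(cfg$nodes$file)
  } else {
    generate_nodeset(cfg$nodes$count, target = phantom$target_point,
                     sad = cfg$nodes$sad, cap_deg = cfg$nodes$cap_deg,
                     exclusion_deg = cfg$nodes$exclusion_deg,
                     min_sep_deg = cfg$nodes$min_sep_deg, seed = cfg$nodes$seed)
  }
  obj_table <- if (!is.null(cfg$objectives)) {
    do.call(rbind, lapply(cfg$objectives, function(o)
      data.frame(structure = o$structure, a = o$a,
                 d_min = o$d_min %||% NA_real_, d_max = o$d_max %||% NA_real_)))
  }
  kernel <- do.call(kernel_params, cfg$kernel)
  list(cfg = cfg, phantom = phantom, nodes = nodes, kernel = kernel,
       obj = plan_objective(phantom, obj_table),
       ptv_idx = structure_voxels(phantom, "ptv"),
       time_params = do.call(time_model_params, cfg$time_model))
}
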