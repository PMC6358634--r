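# End-to-end study fixtures shared by the acceptance-style tests: built once
# per test run. Problem sizes are the package's desk-scale study conditions
# (see the methods vignette): default 5 mm phantom with 40 candidate nodes
# for the main run, and a coarser 10 mm phantom with 20 candidates for the
# repeated statistical runs.
e2e_case <- function() get_fixture("e2e_case", function() {
  ph <- build_phantom(default_phantom_spec())
  ns <- generate_nodeset(40, target = ph$target_point)
  dij <- assemble_dij(ns, ph)
  list(phantom = ph, nodes = ns, dij = dij, obj = plan_objective(ph),
       ptv_idx = which(ph$labels == 1L), prescription = 40,
       inner = list(fluence = 8, dao = 8))
})

e2e_bos <- function() get_fixture("e2e_bos", function() {
  sc <- e2e_case()
  cfg <- ea_config(population = 10, generations = 10, k = 10,
                   fluence_iters = sc$inner$fluence, dao_iters = sc$inner$dao,
                   seed = 1)
  run_bos(cfg, sc$dij, sc$obj, sc$prescription, sc$ptv_idx)
})

reduced_case <- function() get_fixture("reduced_case", function() {
  ph <- build_phantom(default_phantom_spec(
    spacing = 10, body_radius = 80, body_half_height = 60,
    ptv_radius = 20, ptv_offset = 25, oar_radius = 10))
  ns <- generate_nodeset(20, target = ph$target_point)
  dij <- suppressWarnings(assemble_dij(ns, ph))
  list(phantom = ph, nodes = ns, dij = dij, obj = plan_objective(ph),
       ptv_idx = which(ph$labels == 1L), prescription = 40)
})

reduced_ea_run <- function(seed) {
  rc <- reduced_case()
  cfg <- ea_config(population = 10, generations = 6, k = 5,
                   fluence_iters = 3, dao_iters = 3, seed = seed)
  run_bos(cfg, rc$dij, rc$obj, rc$prescription, rc$ptv_idx)
}
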