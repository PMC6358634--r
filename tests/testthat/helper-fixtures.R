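# Shared fixtures, memoised so expensive geometry/dose objects are built
# once per test run.
.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Coarse phantom for fast unit tests: 10 mm voxels, small cylindrical body.
small_phantom <- function() get_fixture("small_phantom", function() {
  build_phantom(default_phantom_spec(
    spacing = 10, body_radius = 80, body_half_height = 60,
    ptv_radius = 20, ptv_offset = 25, oar_radius = 10))
})

# Coarse phantom + 20-node candidate set + dose-influence matrix + objective.
small_case <- function() get_fixture("small_case", function() {
  ph <- small_phantom()
  ns <- generate_nodeset(20, target = ph$target_point)
  dij <- suppressWarnings(assemble_dij(ns, ph))
  list(phantom = ph, nodes = ns, dij = dij,
       obj = plan_objective(ph), ptv_idx = which(ph$labels == 1L),
       prescription = 40)
})

# Bare synthetic objective over nv voxels (no phantom), for optimiser and
# DAO tests: random positive dose operator and random bounds.
rand_instance <- function(nv, nb, seed, infeasible = TRUE) {
  set.seed(seed)
  A <- matrix(runif(nv * nb, 0.1, 1), nv, nb)
  is_target <- runif(nv) < 0.5
  d_min <- ifelse(is_target, runif(nv, 2, 5), -Inf)
  d_max <- ifelse(is_target, d_min + runif(nv, 0.5, 2),
                  if (infeasible) runif(nv, 0.5, 3) else runif(nv, 3, 8))
  obj <- structure(list(idx = seq_len(nv), a = runif(nv, 0.5, 2),
                        d_min = d_min, d_max = d_max, nvox = nv),
                   class = "plan_objective")
  list(A = A, obj = obj, w0 = runif(nb, 0, 2))
}

objective_fn <- function(A, obj) {
  function(w) {
    d <- as.numeric(A %*% w)[obj$idx]
    sum(obj$a * (pmax(obj$d_min - d, 0)^2 + pmax(d - obj$d_max, 0)^2))
  }
}

objective_gr <- function(A, obj) {
  function(w) {
    d <- as.numeric(A %*% w)[obj$idx]
    gd <- 2 * obj$a * (pmax(d - obj$d_max, 0) - pmax(obj$d_min - d, 0))
    as.numeric(crossprod(A[obj$idx, , drop = FALSE], gd))
  }
}

# Independent bound-constrained convex solver (base R L-BFGS-B, a separate
# implementation from the package's projected L-BFGS).
oracle_minimum <- function(A, obj, w0) {
  fit <- optim(w0, objective_fn(A, obj), objective_gr(A, obj),
               method = "L-BFGS-B", lower = 0,
               control = list(maxit = 2000, factr = 1e1))
  fit$value
}

# Deterministic synthetic fitness landscape over subsets: lower is better,
# global optimum = the k candidates of largest quality.
subset_fitness <- function(quality) {
  f <- function(genome) 100 - sum(quality[sort(unique(genome)) + 1L])
  attr(f, "n_candidates") <- length(quality)
  f
}
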