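#' Evolutionary-algorithm configuration
#'
#' Defaults follow the beam-orientation-selection scheme: a population of 20
#' plans evolved for 20 generations, genomes of K = 15 beam indices,
#' position-wise crossover taking each gene from one parent with probability
#' 0.4 (else the other), a one-retry rule for duplicate genes (accepted on
#' the second collision), per-gene mutation with probability 0.05, parents
#' drawn from the fittest tenth of the population (at least 2), generational
#' replacement, and best-ever elitism. Every individual is evaluated by a
#' full inner plan (20 fluence + 20 aperture-weight iterations).
#'
#' @param population,generations,k EA dimensions.
#' @param crossover probability of drawing a gene from the first parent.
#' @param mutation per-gene mutation probability.
#' @param parent_fraction fraction of the population forming the parent pool.
#' @param fluence_iters,dao_iters inner-plan iteration budgets.
#' @param max_apertures per-beam segment cap of inner plans.
#' @param seed RNG seed of the run.
#' @return An `ea_config` object.
#' @export
ea_config <- function(population = 20, generations = 20, k = 15,
                      crossover = 0.4, mutation = 0.05,
                      parent_fraction = 0.1, fluence_iters = 20,
                      dao_iters = 20, max_apertures = 5, seed = 1) {
  if (crossover <= 0 || crossover >= 1) stopf("crossover ratio must be in (0, 1)")
  if (mutation < 0 || mutation > 1) stopf("mutation probability must be in [0, 1]")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations), k = as.integer(k),
                 crossover = crossover, mutation = mutation,
                 parent_fraction = parent_fraction,
                 fluence_iters = fluence_iters, dao_iters = dao_iters,
                 max_apertures = max_apertures, seed = as.integer(seed)),
            class = "ea_config")
}

#' Initial population
#'
#' Each genome is K distinct candidate indices (0-based) drawn uniformly
#' without replacement; reproducible for a given seed.
#'
#' @param cfg an [ea_config].
#' @param n_candidates number of candidate beams.
#' @return List of integer genomes.
#' @export
init_population <- function(cfg, n_candidates) {
  if (cfg$k > n_candidates)
    stopf("cannot select %d beams from %d candidates", cfg$k, n_candidates)
  with_seed(cfg$seed, lapply(seq_len(cfg$population), function(i)
    sample.int(n_candidates, cfg$k) - 1L))
}

#' Crossover and mutation
#'
#' Gene k is drawn from parent A with probability `crossover`, else B. A
#' drawn gene that duplicates an already-placed gene is redrawn once by the
#' same rule; a second collision is accepted anyway (duplicates are later
#' collapsed for planning). Each gene then mutates with probability
#' `mutation` into a uniform random candidate index.
#'
#' @param pa,pb parent genomes (0-based integer vectors).
#' @param cfg an [ea_config].
#' @param n_candidates number of candidate beams.
#' @return Offspring genome. Uses the current RNG stream.
#' @export
make_offspring <- function(pa, pb, cfg, n_candidates) {
  k <- length(pa)
  child <- integer(k)
  for (i in seq_len(k)) {
    draw <- function() if (runif(1) < cfg$crossover) pa[i] else pb[i]
    g <- draw()
    if (i > 1L && g %in% child[seq_len(i - 1L)]) g <- draw()  # retry once, then accept
    child[i] <- g
  }
  mut <- runif(k) < cfg$mutation
  if (any(mut)) child[mut] <- sample.int(n_candidates, sum(mut), replace = TRUE) - 1L
  child
}

#' Evaluate an individual
#'
#' Fitness is the objective value F of the full inner plan (fluence
#' optimisation, sequencing, aperture-weight optimisation) restricted to
#' the genome's unique beams; deterministic given the genome. An empty
#' unique-beam set scores the objective of zero dose.
#'
#' @param genome 0-based candidate indices (duplicates allowed).
#' @param dij a `dose_influence` over all candidates.
#' @param obj a [plan_objective].
#' @param cfg an [ea_config].
#' @param prescription,ptv_idx passed to [plan_beams].
#' @param cache optional environment memoising fitness by unique-beam set.
#' @return list(fitness, plan).
#' @export
evaluate_individual <- function(genome, dij, obj, cfg, prescription, ptv_idx,
                                cache = NULL) {
  beams <- sort(unique(genome)) + 1L
  key <- paste(beams, collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  plan <- plan_beams(dij, beams, obj, prescription, ptv_idx,
                     fluence_iters = cfg$fluence_iters,
                     dao_iters = cfg$dao_iters,
                     max_apertures = cfg$max_apertures)
  out <- list(fitness = plan$objective_value, plan = plan)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Run beam orientation selection
#'
#' The nested evolutionary algorithm: every generation identifies the
#' fittest `parent_fraction` of the population (at least 2 individuals),
#' generates population-many offspring from randomly drawn parent pairs in
#' that pool, evaluates each offspring with a full inner plan, and replaces
#' the population wholesale. The returned optimum is the fittest individual
#' found in any generation (best-ever elitism), and per-generation fitness
#' statistics (median, quartiles, range) are recorded for convergence plots.
#'
#' @param cfg an [ea_config].
#' @param dij a `dose_influence` over the candidate node set.
#' @param obj a [plan_objective].
#' @param prescription prescription dose, Gy.
#' @param ptv_idx PTV voxel indices.
#' @param fitness_fn optional deterministic function(genome) -> fitness
#'   replacing the inner-plan evaluation (for benchmarks on synthetic
#'   fitness landscapes).
#' @param verbose print one line per generation.
#' @return An `ea_result`: best genome/fitness/plan, generation of the best,
#'   `stats` data.frame (generation 0 = initial population), the best-ever
#'   trace, final population and evaluation count.
#' @export
run_bos <- function(cfg, dij = NULL, obj = NULL, prescription = NULL,
                    ptv_idx = NULL, fitness_fn = NULL, verbose = FALSE) {
  n_cand <- if (!is.null(fitness_fn)) {
    attr(fitness_fn, "n_candidates") %||% stop("fitness_fn needs attr 'n_candidates'")
  } else length(dij$blocks)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  eval_one <- function(genome) {
    n_evals <<- n_evals + 1L
    if (!is.null(fitness_fn)) return(list(fitness = fitness_fn(genome), plan = NULL))
    evaluate_individual(genome, dij, obj, cfg, prescription, ptv_idx, cache)
  }
  with_seed(cfg$seed, {
    pop <- lapply(seq_len(cfg$population), function(i) sample.int(n_cand, cfg$k) - 1L)
    evals <- lapply(pop, eval_one)
    fit <- vapply(evals, `[[`, 1, "fitness")
    best <- which.min(fit)
    best_ind <- list(genome = pop[[best]], fitness = fit[best],
                     plan = evals[[best]]$plan, generation = 0L)
    stats <- gen_stats(0L, fit)
    best_trace <- best_ind$fitness
    for (gen in seq_len(cfg$generations)) {
      pool <- order(fit)[seq_len(max(2L, ceiling(cfg$population * cfg$parent_fraction)))]
      newpop <- vector("list", cfg$population)
      for (i in seq_len(cfg$population)) {
        pr <- sample(pool, 2L)
        newpop[[i]] <- make_offspring(pop[[pr[1]]], pop[[pr[2]]], cfg, n_cand)
      }
      pop <- newpop
      evals <- lapply(pop, eval_one)
      fit <- vapply(evals, `[[`, 1, "fitness")
      gb <- which.min(fit)
      if (fit[gb] < best_ind$fitness)
        best_ind <- list(genome = pop[[gb]], fitness = fit[gb],
                         plan = evals[[gb]]$plan, generation = gen)
      stats <- rbind(stats, gen_stats(gen, fit))
      best_trace <- c(best_trace, best_ind$fitness)
      if (verbose)
        message(sprintf("generation %d: median F = %.4g, best-ever F = %.4g",
                        gen, median(fit), best_ind$fitness))
    }
    structure(list(best = best_ind, stats = stats, best_trace = best_trace,
                   population = pop, fitness = fit, n_evals = n_evals,
                   config = cfg),
              class = "ea_result")
  })
}

gen_stats <- function(gen, fit) {
  data.frame(generation = gen, median = median(fit),
             q25 = unname(quantile(fit, 0.25)), q75 = unname(quantile(fit, 0.75)),
             min = min(fit), max = max(fit))
}

#' @export
print.ea_result <- function(x, ...) {
  cat(sprintf("ea_result: best F = %.4g found in generation %d (%d evaluations)\n",
              x$best$fitness, x$best$generation, x$n_evals))
  invisible(x)
}

#' Parameter perturbation sweep
#'
#' Re-runs the beam selection for each perturbation of the EA parameters
#' (crossover ratio, mutation probability, population/generations, repeat
#' count), reporting per run the final-generation median and range and the
#' lowest objective found; with repeats > 1 the medians and ranges are taken
#' across the repeats' final medians.
#'
#' @param base an [ea_config]; each perturbation row overrides its fields.
#' @param perturbations data.frame with any of columns population,
#'   generations, crossover, mutation, repeats.
#' @param ... arguments passed on to [run_bos] (dij, obj, prescription,
#'   ptv_idx or fitness_fn).
#' @return data.frame, one row per perturbation.
#' @export
run_parameter_sweep <- function(base, perturbations, ...) {
  out <- NULL
  for (r in seq_len(nrow(perturbations))) {
    p <- perturbations[r, , drop = FALSE]
    cfg <- base
    for (f in intersect(names(p), c("population", "generations", "crossover", "mutation")))
      if (is.finite(p[[f]])) cfg[[f]] <- p[[f]]
    reps <- if ("repeats" %in% names(p) && is.finite(p$repeats)) p$repeats else 1L
    finals <- numeric(reps); lowest <- numeric(reps)
    fmin <- numeric(reps); fmax <- numeric(reps)
    for (s in seq_len(reps)) {
      cfg$seed <- base$seed + (s - 1L)
      res <- run_bos(cfg, ...)
      last <- res$stats[nrow(res$stats), ]
      finals[s] <- last$median; fmin[s] <- last$min; fmax[s] <- last$max
      lowest[s] <- res$best$fitness
    }
    row <- data.frame(run = r, population = cfg$population,
                      generations = cfg$generations, repeats = reps,
                      crossover = cfg$crossover, mutation = cfg$mutation,
                      final_median = median(finals),
                      final_min = if (reps > 1) min(finals) else fmin[1],
                      final_max = if (reps > 1) max(finals) else fmax[1],
                      lowest = min(lowest))
    out <- rbind(out, row)
  }
  out
}
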