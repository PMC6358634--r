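test_that("initial populations are uniform, distinct-gene and reproducible", {
  cfg <- ea_config(population = 20, k = 15, seed = 4)
  pop <- init_population(cfg, 110)
  expect_length(pop, 20)
  for (g in pop) {
    expect_length(g, 15)
    expect_equal(anyDuplicated(g), 0)
    expect_true(all(g >= 0 & g < 110))
  }
  expect_identical(pop, init_population(cfg, 110))
  # K = number of candidates forces every genome to be a permutation
  cfg2 <- ea_config(population = 5, k = 8, seed = 1)
  for (g in init_population(cfg2, 8)) expect_setequal(g, 0:7)
  expect_error(init_population(ea_config(k = 10), 5), "cannot select")
})

test_that("crossover follows the parent-probability and duplicate-retry rules", {
  cfg <- ea_config(k = 3, crossover = 0.4, mutation = 0)
  pa <- c(1L, 2L, 3L)
  set.seed(1)
  expect_identical(make_offspring(pa, pa, cfg, 8), pa)
  # degenerate ratio ~ 1: child is always the first parent
  cfg1 <- ea_config(k = 3, crossover = 1 - 1e-12, mutation = 0)
  set.seed(2)
  expect_identical(make_offspring(c(1L, 2L, 3L), c(4L, 5L, 6L), cfg1, 8), c(1L, 2L, 3L))
  # full mutation: empirical gene distribution uniform over candidates
  cfgm <- ea_config(k = 4, crossover = 0.4, mutation = 1)
  set.seed(3)
  genes <- unlist(lapply(1:2500, function(i)
    make_offspring(c(0L, 1L, 2L, 3L), c(4L, 5L, 6L, 7L), cfgm, 10)))
  tab <- table(factor(genes, levels = 0:9))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("fitness ignores duplicate genes and extra beams cannot hurt at convergence", {
  sc <- small_case()
  cfg <- ea_config(fluence_iters = 30, dao_iters = 30, max_apertures = Inf)
  a <- evaluate_individual(c(0L, 3L, 5L), sc$dij, sc$obj, cfg, sc$prescription, sc$ptv_idx)
  b <- evaluate_individual(c(0L, 3L, 5L, 3L, 0L), sc$dij, sc$obj, cfg,
                           sc$prescription, sc$ptv_idx)
  expect_equal(a$fitness, b$fitness)
  # a superset of beams evaluated at convergence is at least as good
  sup <- evaluate_individual(c(0L, 3L, 5L, 9L), sc$dij, sc$obj, cfg,
                             sc$prescription, sc$ptv_idx)
  expect_lte(sup$fitness, a$fitness * 1.05 + 1e-6)
  # empty unique-beam set scores the zero-dose objective
  empty <- evaluate_individual(integer(0), sc$dij, sc$obj, cfg,
                               sc$prescription, sc$ptv_idx)
  expect_equal(empty$fitness, objective_value(numeric(sc$dij$nvox), sc$obj))
})

test_that("the EA run is reproducible, keeps population size and is elitist", {
  q <- c(5, 1, 8, 2, 9, 3, 7, 4)
  fit <- subset_fitness(q)
  cfg <- ea_config(population = 10, generations = 8, k = 3, seed = 11)
  r1 <- run_bos(cfg, fitness_fn = fit)
  r2 <- run_bos(cfg, fitness_fn = fit)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$stats, r2$stats)
  expect_length(r1$population, 10)
  expect_true(all(diff(r1$best_trace) <= 0))
  expect_lte(r1$best$fitness, min(r1$stats$min))
  # zero generations returns the best of the initial population
  r0 <- run_bos(ea_config(population = 10, generations = 0, k = 3, seed = 11),
                fitness_fn = fit)
  expect_equal(r0$best$generation, 0L)
  expect_equal(nrow(r0$stats), 1L)
})

test_that("the parameter sweep reproduces the base run and reports repeats", {
  fit <- subset_fitness(c(5, 1, 8, 2, 9, 3, 7, 4))
  base <- ea_config(population = 10, generations = 6, k = 3, seed = 2)
  tab <- run_parameter_sweep(base, data.frame(crossover = 0.4, mutation = 0.05),
                             fitness_fn = fit)
  ref <- run_bos(base, fitness_fn = fit)
  last <- ref$stats[nrow(ref$stats), ]
  expect_equal(tab$final_median, last$median)
  expect_equal(tab$lowest, ref$best$fitness)
  reps <- run_parameter_sweep(base, data.frame(crossover = 0.4, mutation = 0.05,
                                               repeats = 3), fitness_fn = fit)
  expect_equal(reps$repeats, 3)
  expect_gte(reps$final_max, reps$final_min)
})

test_that("full mutation degrades convergence to random search", {
  fit <- subset_fitness(c(3.1, 7.4, 1.2, 9.8, 2.5, 6.3, 4.7, 8.6))
  worse <- 0
  for (s in 1:5) {
    base <- ea_config(population = 10, generations = 10, k = 3, seed = s)
    high <- base; high$mutation <- 1
    rb <- run_bos(base, fitness_fn = fit)
    rh <- run_bos(high, fitness_fn = fit)
    if (rh$stats$median[nrow(rh$stats)] >= rb$stats$median[nrow(rb$stats)])
      worse <- worse + 1
  }
  expect_gte(worse, 4)
})
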