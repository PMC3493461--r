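# Shared small setup: all-in-all target, noise-free database.
evolve_fixture <- function(seed = 2, n_exposed = 4) {
  target <- build_target_network("all_in_all")
  set.seed(seed)
  db <- build_database(target, protocol("afh"))
  db$exposed <- which(db$records$tag == "training")[seq_len(n_exposed)]
  list(target = target, db = db,
       primordial = build_all_in_all_mesh("latex"))
}

test_that("accepted hill-climb steps never increase a model's training error", {
  fx <- evolve_fixture()
  set.seed(3)
  pop <- lapply(1:2, function(i) stringnet:::init_model(fx$primordial))
  hc <- hill_climb(pop, fx$db,
                   counters = evolution_counters(G_min = 150,
                                                 hard_iteration_limit = 600,
                                                 stagnation_window = 300))
  expect_gt(nrow(hc$history), 0)
  for (m in unique(hc$history$model)) {
    e <- hc$history$e_training[hc$history$model == m]
    expect_true(all(diff(e) <= 0))
  }
  # final errors match the last accepted value per model
  for (m in seq_along(pop)) {
    e <- hc$history$e_training[hc$history$model == m]
    if (length(e)) expect_equal(hc$errors[m], min(e))
  }
})

test_that("a model seeded at the target's parameters terminates immediately", {
  fx <- evolve_fixture()
  set.seed(4)
  hc <- hill_climb(list(fx$target), fx$db,
                   counters = evolution_counters(G_min = 100,
                                                 hard_iteration_limit = 500))
  expect_identical(hc$iterations, 0L)
  expect_lt(hc$errors[1], 0.5)
})

test_that("hill climbing is reproducible under a fixed seed", {
  fx <- evolve_fixture()
  run_once <- function() {
    set.seed(11)
    pop <- lapply(1:2, function(i) stringnet:::init_model(fx$primordial))
    hill_climb(pop, fx$db,
               counters = evolution_counters(G_min = 50,
                                             hard_iteration_limit = 150,
                                             stagnation_window = 100))
  }
  h1 <- run_once()
  h2 <- run_once()
  expect_identical(h1$errors, h2$errors)
  expect_identical(h1$history, h2$history)
})

test_that("the G > 2 G_L rule stops a stagnant search", {
  fx <- evolve_fixture()
  set.seed(5)
  # a population already at a strong optimum improves rarely; tiny G_min
  # forces an early stop well before the hard limit
  pop <- list(fx$target)
  pop[[1]]$strings$A <- pop[[1]]$strings$A * 1.001
  hc <- hill_climb(pop, fx$db,
                   counters = evolution_counters(G_min = 20,
                                                 hard_iteration_limit = 5000,
                                                 stagnation_window = 1e6))
  expect_lt(hc$iterations, 5000)
  expect_true(hc$G > 2 * hc$G_L || hc$errors[1] < 0.5)
})

test_that("an identical population makes every test uninformative", {
  fx <- evolve_fixture()
  m <- stringnet:::init_model(fx$primordial)
  set.seed(6)
  cand <- evolve_informative_test(list(m, m), c(-135, -90, -45),
                                  max_iter = 50, G_min = 10)
  expect_equal(cand$e_test, 0)
  expect_true(cand$flagged)
  expect_true(all(cand$magnitudes >= 0 & cand$magnitudes <= 5))
})

test_that("accepted e_test values are non-decreasing and candidates stay in bounds", {
  fx <- evolve_fixture()
  set.seed(7)
  models <- lapply(1:3, function(i) stringnet:::init_model(fx$primordial))
  cand <- evolve_informative_test(models, c(-135, -90, -45),
                                  max_iter = 300, G_min = 60)
  expect_true(all(diff(cand$trace) >= 0))
  expect_gt(cand$e_test, 0)
  expect_true(all(cand$magnitudes >= 0 & cand$magnitudes <= 5))
})

test_that("the evolved test dominates a coarse exhaustive grid search", {
  target <- build_target_network("all_in_all")
  m2 <- target
  set.seed(8)
  m2$strings$A <- m2$strings$A * stats::runif(6, 0.6, 1.4)
  models <- list(target, m2)
  angles <- c(-135, -90, -45)
  grid <- expand.grid(F1 = seq(0.5, 5, by = 0.5),
                      F2 = seq(0.5, 5, by = 0.5),
                      F3 = seq(0.5, 5, by = 0.5))
  best_grid <- max(vapply(seq_len(nrow(grid)), function(k)
    test_informativeness(models, as.numeric(grid[k, ]), angles)$e_test, 0))
  cand <- evolve_informative_test(models, angles, max_iter = 600,
                                  G_min = 150, init = c(2.5, 2.5, 2.5))
  expect_gte(cand$e_test, 0.95 * best_grid)
})

test_that("topology readout keeps taut strings and drops slack ones", {
  target <- build_target_network("all_in_all")
  # string 1 made slack under every test: enormous rest length
  m <- target
  m$strings$l_max[1] <- 500
  m$strings$l0[1] <- 500
  tests <- data.frame(F1 = c(1.25, 5), F2 = c(2.5, 5), F3 = c(1.25, 5))
  topo <- extract_topology(m, tests, angles = c(-135, -90, -45))
  expect_false(1L %in% topo)
  expect_setequal(topo, 2:6)
  # with the target itself all six strings engage
  topo_full <- extract_topology(target, tests, angles = c(-135, -90, -45))
  expect_setequal(topo_full, 1:6)
  # an empty test list yields an empty topology
  expect_identical(extract_topology(m, tests[0, ],
                                    angles = c(-135, -90, -45)),
                   integer(0))
})
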