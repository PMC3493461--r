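test_that("string_length measures the displaced chord", {
  pos <- rbind(c(0, 0), c(100, 0))
  el <- data.frame(i = 1, j = 2)
  expect_equal(string_length(pos, el, matrix(0, 2, 2)), 100)
  pos2 <- rbind(c(0, 0), c(3, 0))
  u <- rbind(c(0, 0), c(1, 0))
  expect_equal(string_length(pos2, el, u), 4)
  # displaced perpendicular: 3-4-5 triangle
  u2 <- rbind(c(0, 0), c(0, 4))
  expect_equal(string_length(pos2, el, u2), sqrt(3^2 + 4^2))
})

test_that("element response is tension-only with sigma * A axial force", {
  el <- data.frame(l0 = 100, A = 4)
  latex <- material_linear(1.62)
  expect_equal(element_response(el, latex, 100)$axial_force, 0)
  slack <- element_response(el, latex, 90)
  expect_equal(slack$axial_force, 0)
  expect_equal(slack$nodal_force_vector, c(0, 0, 0, 0))
  taut <- element_response(el, latex, 115.432)
  eps <- (115.432 - 100) / 100
  expect_equal(taut$strain, eps)
  expect_equal(taut$axial_force, 1.62 * 4 * eps)
  expect_equal(taut$axial_force, 1.0, tolerance = 1e-4)
  # equal and opposite at the two nodes
  expect_equal(taut$nodal_force_vector[1:2], -taut$nodal_force_vector[3:4])
})

test_that("single-string pull reproduces the closed-form elongation", {
  mesh <- one_string_mesh(E = 1.62, A = 4, l0 = 100)
  Fext <- matrix(0, 2, 2); Fext[2, 1] <- 1
  st <- solve_equilibrium(mesh, Fext)
  expect_true(st$converged)
  # eps = T / (E A) -> u = l0 * T / (E A)
  expect_equal(st$displacements[2, 1], 100 * 1 / (1.62 * 4),
               tolerance = 1e-9)
  expect_equal(st$reactions, 1, tolerance = 1e-7)
  # doubling E halves the elongation, reaction unchanged
  st2 <- solve_equilibrium(one_string_mesh(E = 3.24, A = 4, l0 = 100), Fext)
  expect_equal(st2$displacements[2, 1], st$displacements[2, 1] / 2,
               tolerance = 1e-6)
  expect_equal(st2$reactions, st$reactions, tolerance = 1e-7)
})

test_that("zero load is a trivial equilibrium", {
  mesh <- build_target_network("awr")
  n <- nrow(mesh$nodes)
  st <- solve_equilibrium(mesh, matrix(0, n, 2))
  expect_true(st$converged)
  expect_equal(st$displacements, matrix(0, n, 2))
  expect_lte(st$iterations, 1L)
  out <- simulate_loadset(mesh, c(0, 0, 0), c(-105, -90, -75))
  expect_equal(out$reactions, c(0, 0))
  expect_equal(out$distances, unname(rest_distances(mesh)))
})

test_that("V-mesh equilibrium matches the energy-minimization oracle", {
  mesh <- v_mesh()
  n <- nrow(mesh$nodes)
  Fext <- matrix(0, n, 2)
  Fext[3, 2] <- -2         # 2 N straight down on the tip
  st <- solve_equilibrium(mesh, Fext)
  expect_true(st$converged)
  or <- oracle_equilibrium(mesh, Fext)
  expect_lt(max(abs(st$displacements - or$displacements)) /
              max(abs(or$displacements)), 1e-6)
  # symmetry: tip stays on the center line
  expect_lt(abs(st$displacements[3, 1]), 1e-8)
})

test_that("Newton equilibria match energy minimization on random networks", {
  set.seed(101)
  n_match <- 0L
  for (k in 1:12) {
    mesh <- random_small_network()
    Fext <- random_load(mesh)
    st <- solve_equilibrium(mesh, Fext)
    or <- oracle_equilibrium(mesh, Fext)
    expect_true(st$converged)
    denom <- max(abs(or$displacements), 1e-8)
    expect_lt(max(abs(st$displacements - or$displacements)) / denom, 1e-6)
    n_match <- n_match + 1L
  }
  expect_identical(n_match, 12L)
})

test_that("converged solves balance applied and reaction forces", {
  set.seed(77)
  for (k in 1:10) {
    mesh <- random_small_network()
    Fext <- random_load(mesh)
    st <- solve_equilibrium(mesh, Fext)
    expect_true(st$converged)
    # internal forces at grounded nodes carry the whole applied load
    ground <- mesh$nodes$grounded
    net <- colSums(st$internal_force[ground, , drop = FALSE]) +
      colSums(Fext[!ground, , drop = FALSE])
    expect_lt(max(abs(net)), 1e-6)
    # tension-only: no negative element force
    expect_true(all(st$elements$tension >= 0))
  }
})

test_that("residuals of the final iterations decay at least quadratically", {
  # smooth problem: all strings taut at the solution, no status switching
  mesh <- v_mesh()
  Fext <- matrix(0, 3, 2); Fext[3, 2] <- -2
  st <- solve_equilibrium(mesh, Fext, solver_config(tol_N = 1e-12))
  expect_true(st$converged)
  h <- st$residual_history
  h <- h[h > 1e-14 & h < 1e-1]
  expect_gte(length(h), 2)
  for (k in seq_len(length(h) - 1)) {
    expect_lt(h[k + 1], 10 * h[k]^1.8)
  }
})

test_that("single string to ground transmits the pull as its reaction", {
  # input node connected straight down to a grounded node, pulled along
  # the string: two-node chain force balance
  nodes <- data.frame(id = 1:2, x = c(0, 0), y = c(100, 0),
                      role = c("output", "input"),
                      grounded = c(TRUE, FALSE))
  strings <- data.frame(id = 1, i = 1, j = 2, l0 = 100, A = 4,
                        l_min = 0.01, l_max = 300, A_min = 0.01, A_max = 5)
  mesh <- new_mesh(nodes, strings, material_linear(1.62), "chain")
  Fext <- matrix(0, 2, 2); Fext[2, 2] <- -1     # pull straight down
  st <- solve_equilibrium(mesh, Fext)
  expect_true(st$converged)
  expect_equal(st$reactions, 1, tolerance = 1e-7)
})

test_that("slack strings keep the solve regular and report zero force", {
  mesh <- v_mesh()
  mesh$strings$l0 <- mesh$strings$l0 * 1.4    # both strings start slack
  Fext <- matrix(0, 3, 2); Fext[3, 2] <- -1
  st <- solve_equilibrium(mesh, Fext)
  expect_true(st$converged)
  expect_true(all(st$elements$tension >= 0))
  # pulled down, the tip falls until the strings engage
  expect_lt(st$displacements[3, 2], 0)
})

test_that("compiled and reference Newton kernels agree to machine precision", {
  set.seed(202)
  ctrl <- solver_config()
  for (k in 1:6) {
    mesh <- random_small_network()
    Fext <- random_load(mesh)
    cm <- stringnet:::compile_mesh(mesh)
    r_sol <- stringnet:::cm_newton(cm, Fext[, 1], Fext[, 2], ctrl)
    c_sol <- stringnet:::cm_newton_dispatch(cm, Fext[, 1], Fext[, 2], ctrl)
    expect_identical(r_sol$converged, c_sol$converged)
    expect_lt(max(abs(r_sol$ux - c_sol$ux), abs(r_sol$uy - c_sol$uy)),
              1e-10)
  }
})

test_that("deformation snapshots serialize positions and statuses", {
  mesh <- v_mesh()
  Fext <- matrix(0, 3, 2); Fext[3, 2] <- -2
  st <- solve_equilibrium(mesh, Fext)
  path <- withr::local_tempfile(fileext = ".json")
  deformation_snapshot(mesh, st, path)
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(snap$converged)
  expect_identical(nrow(snap$elements), 2L)
  expect_true(all(snap$elements$taut))
})
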