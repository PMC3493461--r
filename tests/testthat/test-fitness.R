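# Database generated noise-free from a known target; shared across blocks.
local_target_db <- function(seed = 5) {
  target <- build_target_network("all_in_all")
  set.seed(seed)
  db <- build_database(target, protocol("afh"))
  list(target = target, db = db)
}

test_that("a model identical to the target has (near) zero errors", {
  td <- local_target_db()
  fit <- training_error(td$target, td$db)
  expect_lt(fit$error, 1e-6)
  expect_lt(fit$obj_R, 1e-6)
  expect_lt(fit$obj_D, 1e-6)
  expect_lt(cross_validation_error(td$target, td$db), 1e-5)
})

test_that("error is the arithmetic mean of obj_R and obj_D", {
  td <- local_target_db()
  # scale measurements so every relative discrepancy is exactly 4% / 2%
  db <- td$db
  db$records$R1 <- db$records$R1 / 1.04
  db$records$R2 <- db$records$R2 / 1.04
  for (col in c("d11", "d12", "d21", "d22", "d31", "d32"))
    db$records[[col]] <- db$records[[col]] / 1.02
  fit <- training_error(td$target, db)
  expect_equal(fit$obj_R, 4, tolerance = 1e-4)
  expect_equal(fit$obj_D, 2, tolerance = 1e-4)
  expect_equal(fit$error, (fit$obj_R + fit$obj_D) / 2)
  expect_equal(fit$error, 3, tolerance = 1e-4)
  # force-only mode ignores the deformation information
  fit_f <- training_error(td$target, db, mode = "force_only")
  expect_equal(fit_f$error, fit_f$obj_R)
})

test_that("training error is invariant under load-set permutation", {
  td <- local_target_db()
  model <- td$target
  model$strings$A <- model$strings$A * 1.1
  e1 <- training_error(model, td$db)$error
  db2 <- td$db
  set.seed(9)
  db2$records <- db2$records[sample.int(nrow(db2$records)), ]
  e2 <- training_error(model, db2)$error
  expect_equal(e1, e2)
})

test_that("cross-validation error equals the brute-force maximum and dominates the mean", {
  td <- local_target_db()
  set.seed(31)
  for (k in 1:5) {
    model <- td$target
    model$strings$A <- model$strings$A * stats::runif(6, 0.7, 1.3)
    model$strings$l0 <- model$strings$l0 * stats::runif(6, 0.95, 1.05)
    e <- cross_validation_error(model, td$db)
    # independent enumeration over cross-validation sets and components
    cvr <- td$db$records[td$db$records$tag == "cross_validation", ]
    relR <- c(); relD <- c()
    for (r in seq_len(nrow(cvr))) {
      out <- simulate_loadset(model, as.numeric(cvr[r, c("F1", "F2", "F3")]),
                              as.numeric(cvr[r, c("ang1", "ang2", "ang3")]))
      expect_true(out$converged)
      meas_R <- as.numeric(cvr[r, c("R1", "R2")])
      meas_D <- as.numeric(cvr[r, c("d11", "d12", "d21", "d22",
                                    "d31", "d32")])
      relR <- c(relR, abs(out$reactions - meas_R) / pmax(abs(meas_R), 1e-3))
      relD <- c(relD, abs(out$distances - meas_D) / pmax(abs(meas_D), 1e-3))
    }
    brute <- 100 * (max(relR) + max(relD)) / 2
    expect_equal(e, brute, tolerance = 1e-9)
    mean_based <- 100 * (mean(relR) + mean(relD)) / 2
    expect_gte(e, mean_based)
  }
})

test_that("e_test is zero for identical models and grows with disagreement", {
  base <- build_target_network("all_in_all")
  angles <- c(-135, -90, -45)
  s0 <- test_informativeness(list(base, base), c(2.5, 2.5, 2.5), angles)
  expect_equal(s0$e_test, 0)
  # disagreement strictly increasing with the parameter gap
  deltas <- c(1.05, 1.2, 1.5)
  scores <- vapply(deltas, function(f) {
    m2 <- base
    m2$strings$A <- m2$strings$A * f
    test_informativeness(list(base, m2), c(2.5, 2.5, 2.5), angles)$e_test
  }, 0)
  expect_true(all(diff(scores) > 0))
  expect_true(all(scores > 0))
})

test_that("e_test equals the hand-computed dispersion for three models", {
  base <- build_target_network("all_in_all")
  angles <- c(-135, -90, -45)
  models <- lapply(c(0.8, 1.0, 1.3), function(f) {
    m <- base; m$strings$A <- m$strings$A * f; m
  })
  mags <- c(3, 1, 4)
  sc <- test_informativeness(models, mags, angles)
  # direct arithmetic on the simulated outputs
  outs <- lapply(models, simulate_loadset, input_magnitudes = mags,
                 input_angles = angles)
  R <- do.call(rbind, lapply(outs, `[[`, "reactions"))
  D <- do.call(rbind, lapply(outs, `[[`, "distances"))
  rngR <- apply(R, 2, function(x) max(x) - min(x))
  rngD <- apply(D, 2, function(x) max(x) - min(x))
  expected <- 100 * (mean(rngR / 5) + mean(rngD / mean(abs(D)))) / 2
  expect_equal(sc$e_test, expected, tolerance = 1e-12)
  expect_equal(sc$per_component_variance$reactions, rngR)
  # invariant under permutation of the model list
  sc2 <- test_informativeness(models[c(3, 1, 2)], mags, angles)
  expect_equal(sc2$e_test, sc$e_test)
})

test_that("duplicating a model never increases per-component dispersions", {
  base <- build_target_network("all_in_all")
  angles <- c(-135, -90, -45)
  set.seed(17)
  for (k in 1:5) {
    models <- lapply(1:3, function(i) {
      m <- base
      m$strings$A <- m$strings$A * stats::runif(6, 0.7, 1.4)
      m
    })
    mags <- stats::runif(3, 0.5, 5)
    s1 <- test_informativeness(models, mags, angles)
    dup <- c(models, models[sample.int(3, 1)])
    s2 <- test_informativeness(dup, mags, angles)
    expect_true(all(s2$per_component_variance$reactions <=
                    s1$per_component_variance$reactions + 1e-12))
    expect_true(all(s2$per_component_variance$distances <=
                    s1$per_component_variance$distances + 1e-12))
  }
})

test_that("ablation reproduces the intact error and flags structural strings", {
  td <- local_target_db()
  model <- td$target
  # add a string that stays slack under every load (rest length at bound)
  extra <- model$strings[1, ]
  extra$id <- 99L
  extra$l_max <- 500
  extra$l0 <- 500          # far beyond any deformed chord: never taut
  model$strings <- rbind(model$strings, extra)
  tab <- ablate_strings(model, td$db)
  expect_identical(nrow(tab), nrow(model$strings) + 1L)
  intact <- tab$e_cross[is.na(tab$removed_string)]
  expect_equal(intact, cross_validation_error(model, td$db))
  # removing the always-slack string leaves e_cross unchanged
  slack_row <- tab$e_cross[which(tab$removed_string == 99L)]
  expect_equal(slack_row, intact, tolerance = 1e-9)
  # removing a load-bearing string degrades the fit
  worst <- max(tab$e_cross[!is.na(tab$removed_string) &
                           tab$removed_string != 99L])
  expect_gt(worst, intact + 1)
})

test_that("losing the only load path yields a sentinel or huge error", {
  target <- build_target_network("all_in_all")
  set.seed(6)
  proto <- protocol("afh")
  db <- build_database(target, proto)
  model <- single_path_mesh()
  # its only string removed: inputs cannot equilibrate under load
  m2 <- model
  m2$strings <- m2$strings[0, ]
  e <- tryCatch(cross_validation_error(m2, db), error = function(e) Inf)
  expect_gte(e, 1e5)
})
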