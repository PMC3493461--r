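# Large finite sentinel (percent) assigned when a candidate model's
# nonlinear analysis fails to converge, so the hill climber can discard it
# without crashing on a discontinuity of the design space.
SENTINEL_ERROR <- 1e6

# Division guards for percent discrepancies (measured-value denominators).
FLOOR_FORCE <- 1e-3     # N
FLOOR_DIST <- 1e-3      # mm

# Characteristic force scale for the test-informativeness score: the upper
# force bound F_U of the loading protocol (dynamometer full scale), N.
FORCE_SCALE <- 5

# Precompute the numeric arrays of a record batch once, so repeated fitness
# evaluations inside the hill climber stay cheap.
records_batch <- function(rec) {
  list(
    n = nrow(rec),
    mags = as.matrix(rec[, c("F1", "F2", "F3")]),
    angles = as.numeric(rec[1, c("ang1", "ang2", "ang3")]),
    R = as.matrix(rec[, c("R1", "R2")]),
    D = as.matrix(rec[, c("d11", "d12", "d21", "d22", "d31", "d32")]),
    set_id = rec$set_id
  )
}

# Simulate a batch on a compiled mesh.  The compiled kernel handles the
# whole batch; sets it fails to converge are retried with the full solve
# (energy fallback).  Returns NULL on any remaining non-convergence.
cm_batch_outputs <- function(cm, batch, ctrl) {
  if (cm$matpar$kind >= 0L) {
    out <- .cpp_simulate_batch(cm, batch$mags, batch$angles, cm$input_idx,
                               cm$grounded_idx, ctrl$tol_N,
                               as.integer(ctrl$max_iter),
                               ctrl$stiffness_floor, ctrl$step_cap,
                               as.integer(ctrl$max_halvings))
    R <- out$R
    D <- out$D
    retry <- which(!out$converged)
  } else {
    R <- matrix(NA_real_, batch$n, 2L)
    D <- matrix(NA_real_, batch$n, 6L)
    retry <- seq_len(batch$n)
  }
  for (k in retry) {
    s <- cm_simulate(cm, batch$mags[k, ], batch$angles, ctrl)
    if (!s$converged) return(NULL)
    R[k, ] <- s$reactions
    D[k, ] <- s$distances
  }
  list(R = R, D = D)
}

rel_disc <- function(model, measured, floor) {
  abs(model - measured) / pmax(abs(measured), floor)
}

# Mean-based percent errors of a simulated batch against measurements.
batch_errors <- function(sim, batch, mode) {
  relR <- rel_disc(sim$R, batch$R, FLOOR_FORCE)
  relD <- rel_disc(sim$D, batch$D, FLOOR_DIST)
  obj_R <- 100 * mean(relR)
  obj_D <- 100 * mean(relD)
  error <- if (mode == "force_only") obj_R else (obj_R + obj_D) / 2
  list(obj_R = obj_R, obj_D = obj_D, error = error, relR = relR, relD = relD)
}

# Fast internal scalar used by the evolutionary loop.
cm_training_error <- function(cm, batch, ctrl,
                              mode = c("force_and_distance", "force_only")) {
  mode <- match.arg(mode)
  sim <- cm_batch_outputs(cm, batch, ctrl)
  if (is.null(sim)) return(SENTINEL_ERROR)
  batch_errors(sim, batch, mode)$error
}

#' Training-set error of a model
#'
#' Simulates every exposed training load set with the candidate model and
#' quantifies the percent discrepancy between predicted and measured
#' outputs: `obj_R` averages the relative reaction-force discrepancies over
#' all `N_R x N_DS` comparisons, `obj_D` the relative distance
#' discrepancies over `N_D x N_DS`, and the training error is their
#' arithmetic mean.  Denominators are the measured values, guarded by a
#' floor of 1e-3 N / 1e-3 mm.  `mode = "force_only"` discards the
#' deformation information (`error = obj_R`), the ablation showing that
#' force data alone under-determines the network.
#'
#' A model whose nonlinear analysis fails to converge for any set receives
#' the large finite sentinel error 1e6 (treated as unfit).
#'
#' @param model candidate `sn_mesh`.
#' @param db an `sn_loadset_db`; the exposed training records are used (all
#'   training records if none are marked exposed).
#' @param mode which information enters the error.
#' @param control solver configuration.
#' @return list of class `sn_fitness_report`: `obj_R`, `obj_D`, `error`
#'   (percent), `e_training` (= `error`), `converged`, and `per_set`
#'   breakdown.
#' @export
training_error <- function(model, db,
                           mode = c("force_and_distance", "force_only"),
                           control = solver_config()) {
  mode <- match.arg(mode)
  rec <- exposed_records(db)
  if (!nrow(rec)) stop("training_error: no training records", call. = FALSE)
  batch <- records_batch(rec)
  cm <- compile_mesh(model)
  sim <- cm_batch_outputs(cm, batch, control)
  if (is.null(sim)) {
    return(structure(list(obj_R = SENTINEL_ERROR, obj_D = SENTINEL_ERROR,
                          error = SENTINEL_ERROR, e_training = SENTINEL_ERROR,
                          converged = FALSE, mode = mode, per_set = NULL),
                     class = "sn_fitness_report"))
  }
  be <- batch_errors(sim, batch, mode)
  per_set <- data.frame(set_id = batch$set_id,
                        mean_rel_reaction_pct = 100 * rowMeans(be$relR),
                        mean_rel_distance_pct = 100 * rowMeans(be$relD))
  structure(list(obj_R = be$obj_R, obj_D = be$obj_D, error = be$error,
                 e_training = be$error, converged = TRUE, mode = mode,
                 per_set = per_set),
            class = "sn_fitness_report")
}

#' @export
print.sn_fitness_report <- function(x, ...) {
  cat(sprintf("<sn_fitness_report> obj_R = %.4g%%, obj_D = %.4g%%, error = %.4g%% (%s)\n",
              x$obj_R, x$obj_D, x$error, x$mode))
  invisible(x)
}

# Internal max-based cross-validation error on a precomputed batch.
cm_cross_validation_error <- function(cm, batch, ctrl,
                                      mode = "force_and_distance") {
  sim <- cm_batch_outputs(cm, batch, ctrl)
  if (is.null(sim)) return(SENTINEL_ERROR)
  relR <- rel_disc(sim$R, batch$R, FLOOR_FORCE)
  relD <- rel_disc(sim$D, batch$D, FLOOR_DIST)
  if (mode == "force_only") 100 * max(relR)
  else 100 * (max(relR) + max(relD)) / 2
}

#' Cross-validation error of a model
#'
#' The less conservative, max-based measure of generalization: over the
#' held-out cross-validation load sets, the worst relative reaction
#' discrepancy and the worst relative distance discrepancy are found and
#' averaged.  It quantifies the maximal functional disagreement between a
#' model and the target and is never smaller than the mean-based training
#' error computed on the same sets.
#'
#' @inheritParams training_error
#' @return percent error (scalar); the sentinel 1e6 on non-convergence.
#' @export
cross_validation_error <- function(model, db,
                                   mode = c("force_and_distance",
                                            "force_only"),
                                   control = solver_config()) {
  mode <- match.arg(mode)
  rec <- cv_records(db)
  if (!nrow(rec))
    stop("cross_validation_error: no cross-validation records",
         call. = FALSE)
  cm_cross_validation_error(compile_mesh(model), records_batch(rec),
                            control, mode)
}

#' Informativeness of a candidate test
#'
#' Simulates the candidate input tensions on every model of the population
#' and scores the across-model disagreement of the predicted outputs.  The
#' dispersion of each output component (2 reactions, 6 distances) is its
#' across-model range -- the sum of the extreme deviations about the
#' across-model mean.  Reaction dispersions are normalized by the 5 N force
#' bound (the dynamometer full scale) and distance dispersions by the
#' pooled across-model mean distance, so the score tracks absolute,
#' instrument-measurable disagreement; `e_test` is the mean reaction
#' dispersion and mean distance dispersion averaged, in percent.  `e_test`
#' is zero iff all models produce identical outputs, and a larger value
#' marks a more informative test.
#'
#' Models whose analysis does not converge for the candidate are excluded
#' and flagged; with fewer than two usable models the score is zero and
#' flagged uninformative.
#'
#' @param models list of `sn_mesh` candidates (>= 2).
#' @param candidate_magnitudes 3-vector of tensions within [0, 5] N.
#' @param angles 3-vector of fixed input angles, degrees.
#' @param control solver configuration.
#' @return list of class `sn_test_score`: `e_test`,
#'   `per_component_variance` (ranges for reactions and distances),
#'   `n_models_used`, `flagged`.
#' @export
test_informativeness <- function(models, candidate_magnitudes, angles,
                                 control = solver_config()) {
  stopifnot(length(models) >= 2)
  cms <- lapply(models, compile_mesh)
  test_informativeness_cm(cms, candidate_magnitudes, angles, control)
}

test_informativeness_cm <- function(cms, candidate_magnitudes, angles,
                                    control = solver_config()) {
  R <- matrix(NA_real_, length(cms), 2L)
  D <- matrix(NA_real_, length(cms), 6L)
  ok <- logical(length(cms))
  for (m in seq_along(cms)) {
    out <- cm_simulate(cms[[m]], candidate_magnitudes, angles, control)
    ok[m] <- out$converged
    if (ok[m]) { R[m, ] <- out$reactions; D[m, ] <- out$distances }
  }
  if (sum(ok) < 2) {
    return(structure(list(e_test = 0,
                          per_component_variance = list(
                            reactions = rep(0, 2), distances = rep(0, 6)),
                          n_models_used = sum(ok), flagged = TRUE),
                     class = "sn_test_score"))
  }
  R <- R[ok, , drop = FALSE]
  D <- D[ok, , drop = FALSE]
  rngR <- apply(R, 2, function(x) diff(range(x)))
  rngD <- apply(D, 2, function(x) diff(range(x)))
  # scale-aware pooled normalization: reactions against the force bound
  # F_U (the dynamometer full scale), distances against the pooled
  # across-model mean distance, so e_test tracks absolute, measurable
  # disagreement rather than ratios of vanishing outputs
  relR <- rngR / max(FORCE_SCALE, FLOOR_FORCE)
  relD <- rngD / max(mean(abs(D)), FLOOR_DIST)
  structure(list(e_test = 100 * (mean(relR) + mean(relD)) / 2,
                 per_component_variance = list(reactions = rngR,
                                               distances = rngD),
                 n_models_used = sum(ok), flagged = !all(ok)),
            class = "sn_test_score")
}

#' @export
print.sn_test_score <- function(x, ...) {
  cat(sprintf("<sn_test_score> e_test = %.4g (%d models%s)\n", x$e_test,
              x$n_models_used, if (x$flagged) ", flagged" else ""))
  invisible(x)
}

#' String-ablation analysis
#'
#' Removes one string at a time from a model and re-evaluates the
#' cross-validation error, revealing which strings are functionally
#' relevant: removing a string that stays slack under every
#' cross-validation test leaves the error unchanged, while removing a
#' load-bearing string degrades it (or breaks convergence, reported as the
#' sentinel).  The first row is the intact model.
#'
#' @inheritParams training_error
#' @return data.frame with columns `removed_string` (NA for the intact
#'   row), `e_cross`, `converged`.
#' @export
ablate_strings <- function(model, db, control = solver_config()) {
  stopifnot(nrow(model$strings) >= 1)
  batch <- records_batch(cv_records(db))
  intact <- cm_cross_validation_error(compile_mesh(model), batch, control)
  rows <- data.frame(removed_string = NA_integer_, e_cross = intact,
                     converged = intact < SENTINEL_ERROR)
  for (k in seq_len(nrow(model$strings))) {
    m2 <- model
    m2$strings <- model$strings[-k, ]
    e <- cm_cross_validation_error(compile_mesh(m2), batch, control)
    rows <- rbind(rows, data.frame(removed_string = model$strings$id[k],
                                   e_cross = e,
                                   converged = e < SENTINEL_ERROR))
  }
  rownames(rows) <- NULL
  rows
}
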