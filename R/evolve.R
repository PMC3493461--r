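#' Termination counters for model evolution
#'
#' Model evolution stops when (a) a model's training error falls below
#' `training_threshold` (that model stops; a fully explained population
#' stops the run), (b) the no-improvement streak `G` exceeds twice the
#' favorable-change count `G_L` with `G` at least `G_min`, or (c) the hard
#' iteration limit is reached.  `stagnation_window` is the number of
#' iterations without improvement of the worst model after which it is
#' crossed over with a randomly chosen other model.
#'
#' @param G_min minimum no-improvement streak before criterion (b) can
#'   fire.
#' @param hard_iteration_limit cap on hill-climb iterations.
#' @param training_threshold percent training error regarded as explaining
#'   the target accurately.
#' @param stagnation_window crossover trigger for the worst model.
#' @return list of class `sn_counters`.
#' @export
evolution_counters <- function(G_min = 5000, hard_iteration_limit = 100000,
                               training_threshold = 0.5,
                               stagnation_window = 2000) {
  structure(list(G_min = G_min, hard_iteration_limit = hard_iteration_limit,
                 training_threshold = training_threshold,
                 stagnation_window = stagnation_window),
            class = "sn_counters")
}

# Write mutated parameter vectors back into an sn_mesh.
cm_to_mesh <- function(model, l0, A) {
  model$strings$l0 <- l0
  model$strings$A <- A
  model
}

#' Evolve a population of models by random-mutation hill climbing
#'
#' Each model independently proposes a mutation of its string rest lengths
#' and cross-sections per iteration (regime chosen by the spec's strategy
#' weights) and accepts it iff its training error strictly decreases; no
#' information is exchanged between models except the stagnation crossover
#' of the worst model.  Counters: an iteration in which any model improves
#' resets `G` to 0 and increments `G_L`; otherwise `G` increments.
#'
#' @param population list of `sn_mesh` candidates (all sharing a
#'   primordial connectivity).
#' @param db an `sn_loadset_db`; exposed training records drive the error.
#' @param spec a [mutation_spec()].
#' @param counters an [evolution_counters()].
#' @param mode information mode passed to the training error.
#' @param control solver configuration.
#' @return list with `population` (evolved meshes), `errors` (final
#'   per-model e_training, percent), `history` (data.frame of accepted
#'   events: iteration, model, e_training, G, G_L), `iterations`,
#'   `n_evaluations`, `G`, `G_L`.
#' @export
hill_climb <- function(population, db, spec = mutation_spec(),
                       counters = evolution_counters(),
                       mode = c("force_and_distance", "force_only"),
                       control = solver_config()) {
  mode <- match.arg(mode)
  if (!length(population)) stop("empty population", call. = FALSE)
  rec <- exposed_records(db)
  if (!nrow(rec)) stop("hill_climb: no exposed training records",
                       call. = FALSE)
  batch <- records_batch(rec)
  n_pop <- length(population)
  cms <- lapply(population, compile_mesh)
  lo_l <- lapply(population, function(m) m$strings$l_min)
  hi_l <- lapply(population, function(m) m$strings$l_max)
  lo_A <- lapply(population, function(m) m$strings$A_min)
  hi_A <- lapply(population, function(m) m$strings$A_max)
  errors <- vapply(cms, cm_training_error, 0, batch = batch, ctrl = control,
                   mode = mode)
  n_evals <- n_pop
  G <- 0L
  G_L <- 0L
  worst_streak <- 0L
  strategies <- c("standard", "fine", "coarse")
  hist_it <- integer(0); hist_model <- integer(0); hist_err <- numeric(0)
  hist_G <- integer(0); hist_GL <- integer(0); hist_event <- character(0)
  log_event <- function(it, m, e, event) {
    hist_it <<- c(hist_it, it); hist_model <<- c(hist_model, m)
    hist_err <<- c(hist_err, e); hist_G <<- c(hist_G, G)
    hist_GL <<- c(hist_GL, G_L); hist_event <<- c(hist_event, event)
  }
  iter <- 0L
  repeat {
    active <- errors >= counters$training_threshold
    if (!any(active)) break
    if (iter >= counters$hard_iteration_limit) break
    if (G > 2 * G_L && G >= counters$G_min) break
    iter <- iter + 1L
    improved <- FALSE
    for (m in which(active)) {
      strategy <- sample(strategies, 1, prob = spec$strategy_weights)
      l0_new <- mutate_vector(cms[[m]]$l0, lo_l[[m]], hi_l[[m]], spec,
                              strategy)
      A_new <- mutate_vector(cms[[m]]$A, lo_A[[m]], hi_A[[m]], spec,
                             strategy)
      if (identical(l0_new, cms[[m]]$l0) && identical(A_new, cms[[m]]$A))
        next
      cand <- cms[[m]]
      cand$l0 <- l0_new
      cand$A <- A_new
      e_new <- cm_training_error(cand, batch, control, mode)
      n_evals <- n_evals + 1L
      if (e_new < errors[m]) {
        cms[[m]] <- cand
        errors[m] <- e_new
        improved <- TRUE
        log_event(iter, m, e_new, "accept")
      }
    }
    if (improved) { G <- 0L; G_L <- G_L + 1L } else G <- G + 1L
    # stagnation crossover: uniform per-string parameter exchange between
    # the worst model and a random other one, kept only if it improves the
    # worst model
    worst <- which.max(errors)
    worst_streak <- if (improved) 0L else worst_streak + 1L
    if (n_pop > 1 && worst_streak >= counters$stagnation_window) {
      worst_streak <- 0L
      other <- sample(setdiff(seq_len(n_pop), worst), 1)
      pick <- stats::runif(length(cms[[worst]]$l0)) < 0.5
      cand <- cms[[worst]]
      cand$l0[pick] <- cms[[other]]$l0[pick]
      cand$A[pick] <- cms[[other]]$A[pick]
      e_new <- cm_training_error(cand, batch, control, mode)
      n_evals <- n_evals + 1L
      if (e_new < errors[worst]) {
        cms[[worst]] <- cand
        errors[worst] <- e_new
        G <- 0L; G_L <- G_L + 1L
        log_event(iter, worst, e_new, "crossover")
      }
    }
  }
  population <- mapply(function(m, cm) cm_to_mesh(m, cm$l0, cm$A),
                       population, cms, SIMPLIFY = FALSE)
  history <- data.frame(iteration = hist_it, model = hist_model,
                        e_training = hist_err, G = hist_G, G_L = hist_GL,
                        event = hist_event)
  list(population = population, errors = errors, history = history,
       iterations = iter, n_evaluations = n_evals, G = G, G_L = G_L)
}

#' Evolve the most informative next test
#'
#' Hill-climbs the three input-force magnitudes (angles are fixed) to
#' maximize the across-model disagreement [test_informativeness()].  An
#' altered test replaces the current one iff its `e_test` is strictly
#' higher.  Termination mirrors the model-evolution criteria with the
#' training threshold replaced by an iteration budget.
#'
#' @param models list of `sn_mesh` (>= 2).
#' @param angles fixed 3-vector of input angles, degrees.
#' @param spec a [mutation_spec()].
#' @param bounds force bounds `[F_L, F_U]`, N.
#' @param max_iter proposal budget.
#' @param G_min minimum stagnation streak before the `G > 2 G_L` stop.
#' @param init starting magnitudes (default random within bounds).
#' @param control solver configuration.
#' @return list of class `sn_test_candidate`: `magnitudes`, `e_test`,
#'   `flagged` (TRUE when the models never disagreed), `trace` (accepted
#'   e_test values, non-decreasing), `iterations`.
#' @export
evolve_informative_test <- function(models, angles, spec = mutation_spec(),
                                    bounds = c(0, 5), max_iter = 20000,
                                    G_min = 500, init = NULL,
                                    control = solver_config()) {
  stopifnot(length(models) >= 2)
  cms <- lapply(models, compile_mesh)
  F <- if (is.null(init)) stats::runif(3, bounds[1], bounds[2])
       else pmin(pmax(rep_len(init, 3), bounds[1]), bounds[2])
  score <- test_informativeness_cm(cms, F, angles, control)
  e <- score$e_test
  trace <- e
  G <- 0L; G_L <- 0L
  iter <- 0L
  while (iter < max_iter && !(G > 2 * G_L && G >= G_min)) {
    iter <- iter + 1L
    sel <- stats::runif(3) < spec$p_rate
    if (!any(sel)) sel[sample.int(3, 1)] <- TRUE
    Fn <- F
    k <- sum(sel)
    r <- stats::runif(k)
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    Fn[sel] <- Fn[sel] + sgn * (bounds[2] - bounds[1]) *
      exp(spec$R1 + r * spec$R2)
    Fn <- pmin(pmax(Fn, bounds[1]), bounds[2])
    sn <- test_informativeness_cm(cms, Fn, angles, control)
    if (sn$e_test > e) {
      F <- Fn; e <- sn$e_test; score <- sn
      trace <- c(trace, e)
      G <- 0L; G_L <- G_L + 1L
    } else G <- G + 1L
  }
  structure(list(magnitudes = F, e_test = e, flagged = e <= 0,
                 trace = trace, iterations = iter, score = score),
            class = "sn_test_candidate")
}

#' Read out the participating topology of a model
#'
#' A string belongs to the model topology iff it becomes taut (carries
#' tension) in at least one of the given simulated tests; strings slack
#' under every test do not participate but remain in the model, since they
#' may become taut at a later inference stage.
#'
#' @param model an `sn_mesh`.
#' @param tests data.frame (or list) of tests with magnitudes `F1`, `F2`,
#'   `F3`; angles taken from `ang1..ang3` columns if present, else from
#'   `angles`.
#' @param angles fallback fixed angles.
#' @param tension_tol tension (N) above which a string counts as taut.
#' @param control solver configuration.
#' @return sorted integer vector of participating string ids.
#' @export
extract_topology <- function(model, tests, angles = NULL,
                             tension_tol = 1e-9,
                             control = solver_config()) {
  tests <- as.data.frame(tests)
  cm <- compile_mesh(model)
  taut_ids <- integer(0)
  for (k in seq_len(nrow(tests))) {
    mags <- as.numeric(tests[k, c("F1", "F2", "F3")])
    ang <- if (all(c("ang1", "ang2", "ang3") %in% names(tests)))
      as.numeric(tests[k, c("ang1", "ang2", "ang3")]) else angles
    if (is.null(ang)) stop("extract_topology: angles not supplied",
                           call. = FALSE)
    Fext <- cm_applied_forces(cm, mags, ang)
    sol <- cm_solve(cm, Fext, control)
    if (!sol$converged) {
      warning("extract_topology: test ", k, " did not converge; skipped")
      next
    }
    taut_ids <- union(taut_ids,
                      cm$sid[sol$element_state$taut &
                             sol$element_state$N > tension_tol])
  }
  sort(taut_ids)
}
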