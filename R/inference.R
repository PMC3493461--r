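#' Configuration of an inference run
#'
#' Collects every tunable of the estimation-exploration loop.  The study
#' defaults are a population of 8 models for Latex-style targets (5 for
#' the extensor) exposed to at most 20 informative load sets; the
#' iteration budgets here default to much smaller values suited to
#' in-silico validation runs, and can be raised to the study-scale
#' settings through `counters` and `test_max_iter`.
#'
#' @param target a target `sn_mesh`, or a kind accepted by
#'   [build_target_network()].
#' @param target_seed seed for `target = "random"`.
#' @param primordial a primordial `sn_mesh`, a kind accepted by
#'   [build_primordial_mesh()], or `"all_in_all_latex"` /
#'   `"all_in_all_extensor"`.
#' @param proto an [protocol()].
#' @param population_size number of independently evolved models.
#' @param max_informative_sets training records exposed before stopping
#'   (at most the training-grid size).
#' @param mode `"informative"` (Stage III evolves each next test),
#'   `"random_tests"` (next test drawn uniformly without replacement) or
#'   `"parametric_only"` (informative tests on the fixed all-in-all
#'   6-string topology).
#' @param information_mode which measurements enter the training error.
#' @param spec a [mutation_spec()].
#' @param counters per-cycle [evolution_counters()].
#' @param control a [solver_config()].
#' @param test_max_iter,test_G_min Stage III budget and stagnation floor.
#' @param with_replacement allow a physical load set to be served twice.
#' @param serve_mode `"nearest"` answers an informative request with the
#'   nearest precollected training record (the bench protocol);
#'   `"oracle"` measures the exact requested tensions on the target, as a
#'   fully automated rig would.
#' @return list of class `sn_run_config`.
#' @export
run_config <- function(target = "awr", target_seed = 1,
                       primordial = "awr", proto = protocol("awr"),
                       population_size = 8, max_informative_sets = 20,
                       mode = c("informative", "random_tests",
                                "parametric_only"),
                       information_mode = c("force_and_distance",
                                            "force_only"),
                       spec = mutation_spec(),
                       counters = evolution_counters(G_min = 200,
                                                     hard_iteration_limit = 1000,
                                                     stagnation_window = 400),
                       control = solver_config(),
                       test_max_iter = 300, test_G_min = 60,
                       with_replacement = FALSE,
                       serve_mode = c("nearest", "oracle")) {
  mode <- match.arg(mode)
  serve_mode <- match.arg(serve_mode)
  information_mode <- match.arg(information_mode)
  stopifnot(population_size >= 1)
  n_train <- length(proto$training_levels)^3
  if (max_informative_sets > n_train)
    stop("run_config: max_informative_sets exceeds the training grid",
         call. = FALSE)
  structure(list(target = target, target_seed = target_seed,
                 primordial = primordial, proto = proto,
                 population_size = population_size,
                 max_informative_sets = max_informative_sets, mode = mode,
                 information_mode = information_mode, spec = spec,
                 counters = counters, control = control,
                 test_max_iter = test_max_iter, test_G_min = test_G_min,
                 with_replacement = with_replacement,
                 serve_mode = serve_mode),
            class = "sn_run_config")
}

resolve_target <- function(config) {
  if (inherits(config$target, "sn_mesh")) return(config$target)
  build_target_network(config$target, rng_seed = config$target_seed)
}

resolve_primordial <- function(config) {
  p <- config$primordial
  if (config$mode == "parametric_only")
    p <- if (identical(config$proto$experiment, "extensor"))
      "all_in_all_extensor" else "all_in_all_latex"
  if (inherits(p, "sn_mesh")) return(p)
  if (identical(p, "all_in_all_latex")) return(build_all_in_all_mesh("latex"))
  if (identical(p, "all_in_all_extensor"))
    return(build_all_in_all_mesh("extensor"))
  build_primordial_mesh(p)
}

# Random initial parameters around the drawn geometry: slack-leaning rest
# lengths, cross-sections uniform within bounds.
init_model <- function(primordial) {
  st <- primordial$strings
  nd <- primordial$nodes
  chord <- sqrt((nd$x[match(st$j, nd$id)] - nd$x[match(st$i, nd$id)])^2 +
                (nd$y[match(st$j, nd$id)] - nd$y[match(st$i, nd$id)])^2)
  lo <- pmax(st$l_min, 0.9 * chord)
  hi <- pmax(lo + 1e-6, pmin(st$l_max, 1.5 * chord))
  st$l0 <- stats::runif(nrow(st), lo, hi)
  st$A <- stats::runif(nrow(st), st$A_min, st$A_max)
  primordial$strings <- st
  primordial
}

#' Run the full estimation-exploration loop
#'
#' Stage I seeds the database with one random training record; then,
#' cyclically: Stage II evolves the model population against the exposed
#' records by [hill_climb()], each model is cross-validated on the
#' held-out grid, and Stage III evolves the next most informative test
#' (or draws a random one) which is answered by the nearest available
#' precollected record, until `max_informative_sets` records are exposed.
#' All randomness derives from `seed`.
#'
#' @param config an [run_config()].
#' @param seed integer run seed.
#' @return list of class `sn_run_report` with `curves` (per cycle x model
#'   e_training / e_cross), `tests` (served records and their e_test),
#'   `population`, `final_errors`, `final_e_cross`, `topologies` (per
#'   model participating string ids under the served tests), `history`
#'   (accepted hill-climb events per cycle), `n_evaluations`, `db`,
#'   `target`, `config`, `seed`.
#' @export
run_inference <- function(config, seed = 1) {
  stopifnot(inherits(config, "sn_run_config"))
  set.seed(seed)
  target <- resolve_target(config)
  proto <- config$proto
  db <- build_database(target, proto, control = config$control)
  db <- seed_database(db)
  primordial <- resolve_primordial(config)
  population <- lapply(seq_len(config$population_size),
                       function(i) init_model(primordial))
  cv_batch <- records_batch(cv_records(db))
  curves <- NULL
  tests <- NULL
  history <- NULL
  n_evals <- 0L
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    hc <- hill_climb(population, db, spec = config$spec,
                     counters = config$counters,
                     mode = config$information_mode,
                     control = config$control)
    population <- hc$population
    n_evals <- n_evals + hc$n_evaluations
    e_cross <- vapply(population, function(m)
      cm_cross_validation_error(compile_mesh(m), cv_batch, config$control,
                                config$information_mode), 0)
    curves <- rbind(curves, data.frame(
      cycle = cycle, n_exposed = length(db$exposed),
      model = seq_along(population), e_training = hc$errors,
      e_cross = e_cross))
    if (nrow(hc$history))
      history <- rbind(history, data.frame(cycle = cycle, hc$history))
    if (length(db$exposed) >= config$max_informative_sets) break
    exclude <- if (config$with_replacement) integer(0) else db$exposed
    if (config$mode == "random_tests") {
      avail <- setdiff(which(db$records$tag == "training"), exclude)
      idx <- avail[sample.int(length(avail), 1)]
      served <- db$records[idx, ]
      e_test <- NA_real_
      requested <- as.numeric(served[c("F1", "F2", "F3")])
    } else {
      cand <- evolve_informative_test(population, proto$angles,
                                      spec = config$spec,
                                      max_iter = config$test_max_iter,
                                      G_min = config$test_G_min,
                                      control = config$control)
      requested <- cand$magnitudes
      e_test <- cand$e_test
      n_evals <- n_evals + (cand$iterations + 1L) * length(population)
      if (identical(config$serve_mode, "oracle")) {
        # fully automated rig: measure the exact requested test
        rec <- measure(target, requested, proto,
                       set_id = max(db$records$set_id) + 1L,
                       control = config$control)
        db$records <- rbind(db$records, rec)
        idx <- nrow(db$records)
        served <- rec
      } else {
        nat <- nearest_available_test(requested, db, exclude = exclude)
        idx <- nat$index
        served <- nat$record
      }
    }
    db$exposed <- c(db$exposed, idx)
    tests <- rbind(tests, data.frame(
      cycle = cycle, requested_F1 = requested[1],
      requested_F2 = requested[2], requested_F3 = requested[3],
      e_test = e_test, served_set_id = served$set_id,
      served_F1 = served$F1, served_F2 = served$F2, served_F3 = served$F3))
  }
  served_tests <- db$records[db$exposed, ]
  topologies <- lapply(population, extract_topology, tests = served_tests,
                       angles = proto$angles, control = config$control)
  final <- curves[curves$cycle == cycle, ]
  structure(list(curves = curves, tests = tests, population = population,
                 final_errors = final$e_training,
                 final_e_cross = final$e_cross,
                 topologies = topologies, history = history,
                 n_evaluations = n_evals, db = db, target = target,
                 config = config, seed = seed),
            class = "sn_run_report")
}

#' @export
print.sn_run_report <- function(x, ...) {
  cat(sprintf("<sn_run_report> seed %d, %d models, %d exposed sets; best e_training = %.3g%%, best e_cross = %.3g%%\n",
              x$seed, length(x$population),
              length(x$db$exposed), min(x$final_errors),
              min(x$final_e_cross)))
  invisible(x)
}

#' Parametric-only inference on the all-in-all topology
#'
#' Runs the identical machinery with the fixed 6-string all-in-all mesh
#' (12 free parameters), the baseline in which the topology is assumed and
#' only parameters are fitted.
#'
#' @inheritParams run_inference
#' @return an `sn_run_report`.
#' @export
run_parametric_only <- function(config, seed = 1) {
  config$mode <- "parametric_only"
  run_inference(config, seed)
}

#' Compare informative against random testing across seeds
#'
#' Runs the inference loop under each requested mode on identical targets
#' and paired seeds and summarizes the per-cycle population-mean errors as
#' mean +/- standard error across seeds.
#'
#' @param config an [run_config()] (its `mode` is overridden).
#' @param n_seeds number of paired seeds (>= 3 for a standard error).
#' @param seeds explicit seeds (default `1:n_seeds`).
#' @param modes which modes to run.
#' @return list with `summary` (data.frame: mode, n_exposed, mean/se of
#'   e_training and e_cross across seeds) and `runs` (nested reports).
#' @export
compare_protocols <- function(config, n_seeds = 3, seeds = seq_len(n_seeds),
                              modes = c("informative", "random_tests")) {
  stopifnot(length(seeds) >= 3)
  runs <- list()
  rows <- NULL
  for (mode in modes) {
    cfg <- config
    cfg$mode <- mode
    for (s in seeds) {
      rep_ <- run_inference(cfg, seed = s)
      runs[[paste(mode, s, sep = "_")]] <- rep_
      agg <- stats::aggregate(cbind(e_training, e_cross) ~ n_exposed,
                              data = rep_$curves, FUN = mean)
      rows <- rbind(rows, data.frame(mode = mode, seed = s, agg))
    }
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- do.call(rbind, lapply(split(rows, rows[c("mode", "n_exposed")],
                                         drop = TRUE), function(d)
    data.frame(mode = d$mode[1], n_exposed = d$n_exposed[1],
               e_training_mean = mean(d$e_training),
               e_training_se = se(d$e_training),
               e_cross_mean = mean(d$e_cross),
               e_cross_se = se(d$e_cross))))
  summary <- summary[order(summary$mode, summary$n_exposed), ]
  rownames(summary) <- NULL
  list(summary = summary, runs = runs, seeds = seeds)
}

#' Write the artifacts of a completed run
#'
#' Emits the error curves and served tests as CSV, the final population
#' and resolved configuration as JSON, an ablation CSV for the best model
#' (lowest e_cross, e_training tie-break), and a line-oriented run log.
#'
#' @param run an `sn_run_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
report <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$curves, file.path(outdir, "curves.csv"),
                   row.names = FALSE)
  if (!is.null(run$tests))
    utils::write.csv(run$tests, file.path(outdir, "tests.csv"),
                     row.names = FALSE)
  if (!is.null(run$history))
    utils::write.csv(run$history, file.path(outdir, "history.csv"),
                     row.names = FALSE)
  for (m in seq_along(run$population))
    save_mesh(run$population[[m]],
              file.path(outdir, sprintf("model_%02d.json", m)))
  best <- order(run$final_e_cross, run$final_errors)[1]
  abl <- ablate_strings(run$population[[best]], run$db,
                        control = run$config$control)
  utils::write.csv(abl, file.path(outdir, "ablation_best_model.csv"),
                   row.names = FALSE)
  save_loadsets(run$db, file.path(outdir, "loadsets.json"))
  cfg <- run$config
  cfg_list <- list(mode = cfg$mode, information_mode = cfg$information_mode,
                   population_size = cfg$population_size,
                   max_informative_sets = cfg$max_informative_sets,
                   experiment = cfg$proto$experiment, seed = run$seed,
                   n_evaluations = run$n_evaluations)
  jsonlite::write_json(cfg_list, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_lines <- c(
    sprintf("INFO run seed=%d mode=%s models=%d", run$seed, cfg$mode,
            length(run$population)),
    if (!is.null(run$tests))
      sprintf("INFO cycle=%d served_set=%d e_test=%s", run$tests$cycle,
              run$tests$served_set_id,
              formatC(run$tests$e_test, format = "g")),
    sprintf("INFO final best_e_training=%.6g best_e_cross=%.6g",
            min(run$final_errors), min(run$final_e_cross)))
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(outdir)
}
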