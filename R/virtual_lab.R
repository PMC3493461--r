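#' Measurement protocol
#'
#' The virtual laboratory's stand-in for the physical measurement session:
#' a full-factorial training grid of input tensions, a smaller
#' cross-validation grid interspersed with it, experiment-specific input
#' angles, and the instrument resolutions (electronic dynamometers with
#' 2 g resolution, dial caliper reading to 1 mm).
#'
#' Defaults follow the study protocol: training levels 1.25/2.50/3.75/5.00 N
#' per input (4^3 = 64 combinations), cross-validation levels 1.9/4.4 N
#' (2^3 = 8), angles -135/-90/-45 degrees for the "afh" setup,
#' -105/-90/-75 for "awr", -115/-90/-75 for "extensor".  Noise defaults to
#' zero; `quantize = TRUE` switches on the instrument resolutions.
#'
#' @param experiment which angle set to use.
#' @param training_levels,cv_levels force levels (N) whose full factorials
#'   form the two grids.
#' @param angles override the 3 input angles (degrees from horizontal).
#' @param quantize apply instrument quantization to measured outputs.
#' @param force_quantum dynamometer resolution, N (2 g under standard
#'   gravity = 0.0196 N).
#' @param distance_quantum caliper resolution, mm.
#' @param noise_sd_force,noise_sd_distance Gaussian measurement noise
#'   standard deviations (N, mm), added before quantization.
#' @return a list of class `sn_protocol`.
#' @export
protocol <- function(experiment = c("afh", "awr", "extensor"),
                     training_levels = c(1.25, 2.50, 3.75, 5.00),
                     cv_levels = c(1.9, 4.4),
                     angles = NULL,
                     quantize = FALSE,
                     force_quantum = 0.002 * 9.80665,
                     distance_quantum = 1,
                     noise_sd_force = 0, noise_sd_distance = 0) {
  experiment <- match.arg(experiment)
  if (is.null(angles))
    angles <- switch(experiment,
                     afh = c(-135, -90, -45),
                     awr = c(-105, -90, -75),
                     extensor = c(-115, -90, -75))
  stopifnot(length(angles) == 3,
            all(training_levels >= 0 & training_levels <= 5),
            all(cv_levels >= 0 & cv_levels <= 5),
            force_quantum >= 0, distance_quantum >= 0)
  structure(list(experiment = experiment,
                 training_levels = training_levels, cv_levels = cv_levels,
                 angles = angles, quantize = quantize,
                 force_quantum = force_quantum,
                 distance_quantum = distance_quantum,
                 noise_sd_force = noise_sd_force,
                 noise_sd_distance = noise_sd_distance),
            class = "sn_protocol")
}

#' Experiment design grid
#'
#' Full factorial of the training force levels (tagged `"training"`)
#' followed by the full factorial of the cross-validation levels (tagged
#' `"cross_validation"`), in deterministic order (first input varies
#' fastest).
#'
#' @param proto an [protocol()].
#' @return data.frame with columns `F1`, `F2`, `F3`, `tag`.
#' @export
design_grid <- function(proto) {
  tr <- expand.grid(F1 = proto$training_levels, F2 = proto$training_levels,
                    F3 = proto$training_levels)
  cv <- expand.grid(F1 = proto$cv_levels, F2 = proto$cv_levels,
                    F3 = proto$cv_levels)
  rbind(data.frame(tr, tag = "training"),
        data.frame(cv, tag = "cross_validation"))
}

quantize_to <- function(x, q) if (q > 0) round(x / q) * q else x

#' Measure one load set on a ground-truth network
#'
#' Simulates the commanded tensions on the target, optionally perturbs the
#' outputs with Gaussian noise, then quantizes reactions to the
#' dynamometer resolution and distances to the caliper resolution.  The
#' recorded inputs are the commanded magnitudes.
#'
#' @param target ground-truth `sn_mesh`.
#' @param magnitudes 3-vector of commanded tensions, N.
#' @param proto an [protocol()].
#' @param tag record tag.
#' @param set_id record identifier.
#' @param control solver configuration.
#' @return one-row data.frame in the load-set record schema.
#' @export
measure <- function(target, magnitudes, proto, tag = "training",
                    set_id = 1L, control = solver_config()) {
  sim <- simulate_loadset(target, magnitudes, proto$angles, control)
  if (!sim$converged)
    stop("virtual lab: ground-truth simulation did not converge for (",
         paste(signif(magnitudes, 4), collapse = ", "), ") N", call. = FALSE)
  R <- sim$reactions
  d <- sim$distances
  if (proto$noise_sd_force > 0)
    R <- R + stats::rnorm(length(R), 0, proto$noise_sd_force)
  if (proto$noise_sd_distance > 0)
    d <- d + stats::rnorm(length(d), 0, proto$noise_sd_distance)
  if (proto$quantize) {
    R <- quantize_to(R, proto$force_quantum)
    d <- quantize_to(d, proto$distance_quantum)
  }
  R <- pmax(R, 0)
  d <- pmax(d, if (proto$quantize) max(proto$distance_quantum, 1e-6) else 1e-6)
  data.frame(set_id = set_id, tag = tag,
             F1 = magnitudes[1], F2 = magnitudes[2], F3 = magnitudes[3],
             ang1 = proto$angles[1], ang2 = proto$angles[2],
             ang3 = proto$angles[3],
             R1 = R[1], R2 = R[2],
             d11 = d[1], d12 = d[2], d21 = d[3], d22 = d[4],
             d31 = d[5], d32 = d[6])
}

#' Collect the whole measurement session
#'
#' Measures every point of the design grid on the target and shuffles the
#' record order (the physical session applied the 72 combinations in
#' random order to prevent loading-order bias).  Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param target ground-truth `sn_mesh`.
#' @param proto an [protocol()].
#' @param shuffle permute record order.
#' @param control solver configuration.
#' @return an `sn_loadset_db` with no exposed records.
#' @export
build_database <- function(target, proto, shuffle = TRUE,
                           control = solver_config()) {
  grid <- design_grid(proto)
  rows <- lapply(seq_len(nrow(grid)), function(k)
    measure(target, as.numeric(grid[k, c("F1", "F2", "F3")]), proto,
            tag = as.character(grid$tag[k]), set_id = k, control = control))
  rec <- do.call(rbind, rows)
  if (shuffle) rec <- rec[sample.int(nrow(rec)), ]
  rownames(rec) <- NULL
  new_loadset_db(rec)
}

#' Serve the nearest available training load set
#'
#' The physical sessions precollected the training grid, so a requested
#' (most informative) test is answered with the training record nearest in
#' input-magnitude space (least squares).  Ties break to the
#' lexicographically smallest magnitudes.
#'
#' @param requested 3-vector of requested tensions, N.
#' @param db an `sn_loadset_db`.
#' @param exclude row indices (e.g. already-served records) to skip.
#' @return list `record` (one-row data.frame) and `index` (row index into
#'   `db$records`).
#' @export
nearest_available_test <- function(requested, db, exclude = integer(0)) {
  rec <- db$records
  cand <- which(rec$tag == "training")
  cand <- setdiff(cand, exclude)
  if (!length(cand)) stop("no available training records", call. = FALSE)
  F <- as.matrix(rec[cand, c("F1", "F2", "F3")])
  d2 <- colSums((t(F) - requested)^2)
  best <- cand[d2 <= min(d2) + 1e-12]
  if (length(best) > 1) {
    Fb <- rec[best, c("F1", "F2", "F3")]
    best <- best[order(Fb$F1, Fb$F2, Fb$F3)]
  }
  list(record = rec[best[1], ], index = best[1])
}

#' Seed the database with one random training record
#'
#' Marks a single uniformly chosen training record as the initially
#' exposed load set (Stage I of the inference loop).
#'
#' @param db an `sn_loadset_db`.
#' @return the database with `exposed` of length 1.
#' @export
seed_database <- function(db) {
  tr <- which(db$records$tag == "training")
  if (!length(tr)) stop("seed_database: no training records", call. = FALSE)
  db$exposed <- tr[sample.int(length(tr), 1L)]
  db
}
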