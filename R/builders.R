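#' Primordial string meshes
#'
#' The over-complete starting fabrics from which models evolve.  The three
#' kinds mirror the study setups: `"afh"` (36 strings, length bounds
#' [0.01, 100] mm, area bounds [0.01, 5] mm^2, Latex material), `"awr"`
#' (54 strings, length bounds [0.01, 70] mm, same area bounds) and
#' `"extensor"` (71 strings, length bounds [0.01, 33] mm, area bounds
#' [0.01, 11] mm^2, tendon material).  Each has 3 input nodes and
#' 2 grounded output nodes, with the grounded-node spacing equal to the
#' corresponding target's.  Node coordinates follow a regular layered
#' layout spanning the experiment footprint (the published fabrics are
#' given only graphically); the layout is recorded in the serialized mesh
#' so results are reproducible.
#'
#' Strings start slack (rest length 10% above the chord, capped at the
#' upper length bound), so a freshly built mesh carries no pretension.
#'
#' @param kind `"afh"`, `"awr"` or `"extensor"`.
#' @return an `sn_mesh`.
#' @examples
#' m <- build_primordial_mesh("afh")
#' nrow(m$strings)  # 36
#' @export
build_primordial_mesh <- function(kind = c("afh", "awr", "extensor")) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    afh = list(
      rows = list(
        list(x = c(10, 50, 90), y = 0, role = "input"),
        list(x = seq(10, 90, length.out = 4), y = 100 / 3, role = "internal"),
        list(x = seq(10, 90, length.out = 4), y = 200 / 3, role = "internal"),
        list(x = c(30, 70), y = 100, role = "output")
      ),
      horiz = integer(0),
      l_bounds = c(0.01, 100), A_bounds = c(0.01, 5),
      material = material_linear(1.62)
    ),
    awr = list(
      rows = list(
        list(x = c(10, 50, 90), y = 0, role = "input"),
        list(x = seq(10, 90, length.out = 5), y = 100 / 3, role = "internal"),
        list(x = seq(10, 90, length.out = 5), y = 200 / 3, role = "internal"),
        list(x = c(30, 70), y = 100, role = "output")
      ),
      horiz = 2L,          # adjacent pairs within row 2
      l_bounds = c(0.01, 70), A_bounds = c(0.01, 5),
      material = material_linear(1.62)
    ),
    extensor = list(
      rows = list(
        list(x = c(2.5, 12.5, 22.5), y = 0, role = "input"),
        list(x = seq(0, 25, length.out = 6), y = 50 / 3, role = "internal"),
        list(x = seq(0, 25, length.out = 6), y = 100 / 3, role = "internal"),
        list(x = c(7.5, 17.5), y = 50, role = "output")
      ),
      horiz = 2L,
      l_bounds = c(0.01, 33), A_bounds = c(0.01, 11),
      material = material_tendon()
    )
  )
  nodes <- do.call(rbind, lapply(spec$rows, function(r)
    data.frame(x = r$x, y = r$y, role = r$role)))
  nodes <- data.frame(id = seq_len(nrow(nodes)), x = nodes$x, y = nodes$y,
                      role = nodes$role,
                      grounded = nodes$role == "output")
  row_ids <- split(nodes$id, rep(seq_along(spec$rows),
                                 vapply(spec$rows, function(r) length(r$x), 0L)))
  edges <- NULL
  for (r in seq_len(length(row_ids) - 1)) {
    edges <- rbind(edges, expand.grid(i = row_ids[[r]], j = row_ids[[r + 1]]))
  }
  for (r in spec$horiz) {
    ids <- row_ids[[r]]
    edges <- rbind(edges, data.frame(i = ids[-length(ids)], j = ids[-1]))
  }
  chord <- sqrt((nodes$x[edges$j] - nodes$x[edges$i])^2 +
                (nodes$y[edges$j] - nodes$y[edges$i])^2)
  strings <- data.frame(
    id = seq_len(nrow(edges)), i = edges$i, j = edges$j,
    l0 = pmin(spec$l_bounds[2], 1.1 * chord),
    A = min(spec$A_bounds[2], 4),
    l_min = spec$l_bounds[1], l_max = spec$l_bounds[2],
    A_min = spec$A_bounds[1], A_max = spec$A_bounds[2]
  )
  new_mesh(nodes, strings, spec$material,
           name = paste0("primordial_", kind))
}

latex_bounds <- function(chords) {
  list(l = c(0.01, max(100, 1.05 * max(chords))), A = c(0.01, 5))
}

target_from_edges <- function(nodes, edges, material, name,
                              l_bounds = NULL, A_bounds = c(0.01, 5),
                              A = 4) {
  chord <- sqrt((nodes$x[match(edges$i, nodes$id)] -
                 nodes$x[match(edges$j, nodes$id)])^2 +
                (nodes$y[match(edges$i, nodes$id)] -
                 nodes$y[match(edges$j, nodes$id)])^2)
  if (is.null(l_bounds)) l_bounds <- c(0.01, max(100, 1.05 * max(chord)))
  strings <- data.frame(
    id = seq_len(nrow(edges)), i = edges$i, j = edges$j,
    l0 = chord, A = A,
    l_min = l_bounds[1], l_max = l_bounds[2],
    A_min = A_bounds[1], A_max = A_bounds[2]
  )
  new_mesh(nodes, strings, material, name = name)
}

#' Ground-truth target networks
#'
#' In-silico string networks used as known targets for validating the
#' inference loop.  Latex-style targets fit a 100 x 100 mm footprint with
#' inputs at the bottom and the two grounded nodes at the top, 4 mm^2
#' cross-sections (4 mm wide x 1 mm thick Latex) and rest lengths equal to
#' the as-drawn chord (taut but unstressed at rest).  The published targets
#' are known only from figures, so these are synthetic stand-ins that keep
#' the footprint, node counts, grounded spacing and material of each
#' experiment.
#'
#' Kinds: `"a_letter"` (7 strings shaped like an 'A'), `"afh"` (11
#' strings), `"awr"` and `"extensor_rhombus"` (9-string rhombus with
#' crossing offshoots; the latter uses tendon material on the smaller
#' extensor footprint), `"all_in_all"` (the basic 6-string topology joining
#' every input to every output, also used for parametric-only inference)
#' and `"random"` (seeded random connected network).
#'
#' @param kind target kind, see Details.
#' @param rng_seed integer seed; required for (and only used by)
#'   `kind = "random"`.
#' @return an `sn_mesh`, deterministic given `kind` (and seed).
#' @export
build_target_network <- function(kind = c("a_letter", "afh", "awr",
                                          "extensor_rhombus", "all_in_all",
                                          "random"),
                                 rng_seed = NULL) {
  kind <- match.arg(kind)
  latex <- material_linear(1.62)
  latex_nodes <- function(internal) {
    base <- data.frame(
      id = 1:5,
      x = c(10, 50, 90, 30, 70), y = c(0, 0, 0, 100, 100),
      role = c("input", "input", "input", "output", "output"),
      grounded = c(FALSE, FALSE, FALSE, TRUE, TRUE)
    )
    if (!is.null(internal)) {
      internal$id <- 5 + seq_len(nrow(internal))
      internal$role <- "internal"
      internal$grounded <- FALSE
      base <- rbind(base, internal[names(base)])
    }
    base
  }
  if (kind == "a_letter") {
    nodes <- latex_nodes(data.frame(x = c(35, 65), y = c(55, 55)))
    edges <- data.frame(i = c(1, 2, 2, 3, 6, 6, 7),
                        j = c(6, 6, 7, 7, 7, 4, 5))
    return(target_from_edges(nodes, edges, latex, "target_a_letter"))
  }
  if (kind == "afh") {
    nodes <- latex_nodes(data.frame(x = c(30, 50, 70), y = c(40, 60, 40)))
    edges <- data.frame(i = c(1, 2, 2, 3, 6, 8, 2, 6, 8, 7, 7),
                        j = c(6, 6, 8, 8, 7, 7, 7, 4, 5, 4, 5))
    return(target_from_edges(nodes, edges, latex, "target_afh"))
  }
  if (kind == "awr") {
    nodes <- latex_nodes(data.frame(x = c(30, 50, 70), y = c(50, 45, 50)))
    edges <- data.frame(i = c(1, 2, 3, 7, 7, 6, 8, 6, 8),
                        j = c(6, 7, 8, 6, 8, 4, 5, 5, 4))
    return(target_from_edges(nodes, edges, latex, "target_awr"))
  }
  if (kind == "extensor_rhombus") {
    nodes <- data.frame(
      id = 1:8,
      x = c(2.5, 12.5, 22.5, 7.5, 17.5, 6, 12.5, 19),
      y = c(0, 0, 0, 50, 50, 28, 25, 28),
      role = c("input", "input", "input", "output", "output",
               "internal", "internal", "internal"),
      grounded = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
    )
    edges <- data.frame(i = c(1, 2, 3, 7, 7, 6, 8, 6, 8),
                        j = c(6, 7, 8, 6, 8, 4, 5, 5, 4))
    return(target_from_edges(nodes, edges, material_tendon(),
                             "target_extensor_rhombus",
                             l_bounds = c(0.01, 33), A_bounds = c(0.01, 11)))
  }
  if (kind == "all_in_all") {
    nodes <- latex_nodes(NULL)
    edges <- expand.grid(i = 1:3, j = 4:5)
    return(target_from_edges(nodes, edges, latex, "target_all_in_all",
                             l_bounds = c(0.01, 130)))
  }
  # random: seeded connected network on the Latex footprint
  if (is.null(rng_seed)) stop("kind = 'random' requires rng_seed",
                              call. = FALSE)
  with_local_seed(rng_seed, {
    n_int <- sample(2:4, 1)
    internal <- data.frame(x = stats::runif(n_int, 15, 85),
                           y = stats::runif(n_int, 25, 75))
    nodes <- latex_nodes(internal)
    int_ids <- nodes$id[nodes$role == "internal"]
    edges <- rbind(
      data.frame(i = 1:3, j = sample(int_ids, 3, replace = TRUE)),
      data.frame(i = sample(int_ids, 2, replace = TRUE), j = 4:5)
    )
    if (length(int_ids) > 1)
      edges <- rbind(edges, data.frame(i = int_ids[-length(int_ids)],
                                       j = int_ids[-1]))
    n_extra <- sample(1:3, 1)
    for (k in seq_len(n_extra)) {
      pair <- sample(nodes$id, 2)
      edges <- rbind(edges, data.frame(i = pair[1], j = pair[2]))
    }
    edges <- unique(edges[edges$i != edges$j, ])
    target_from_edges(nodes, edges, latex,
                      sprintf("target_random_%d", rng_seed))
  })
}

#' Basic all-in-all mesh for parametric-only inference
#'
#' The fixed 6-string topology connecting each of the three input nodes to
#' both grounded output nodes (12 free parameters: 6 rest lengths + 6
#' cross-sections).  `experiment = "latex"` uses the 100 x 100 mm footprint
#' and Latex material; `"extensor"` the extensor footprint and tendon
#' material.
#'
#' @param experiment `"latex"` or `"extensor"`.
#' @return an `sn_mesh` with slack initial strings, ready for evolution.
#' @export
build_all_in_all_mesh <- function(experiment = c("latex", "extensor")) {
  experiment <- match.arg(experiment)
  tgt <- if (experiment == "latex") build_target_network("all_in_all") else {
    nodes <- data.frame(
      id = 1:5,
      x = c(2.5, 12.5, 22.5, 7.5, 17.5), y = c(0, 0, 0, 50, 50),
      role = c("input", "input", "input", "output", "output"),
      grounded = c(FALSE, FALSE, FALSE, TRUE, TRUE)
    )
    edges <- expand.grid(i = 1:3, j = 4:5)
    target_from_edges(nodes, edges, material_tendon(), "target_all_in_all_ext",
                      l_bounds = c(0.01, 60), A_bounds = c(0.01, 11))
  }
  tgt$strings$l0 <- pmin(tgt$strings$l_max, 1.1 * tgt$strings$l0)
  tgt$name <- paste0("all_in_all_", experiment)
  validate_mesh(tgt)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
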