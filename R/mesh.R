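#' String-network meshes
#'
#' A mesh is the package's central container: a set of nodes in the plane
#' (millimetres), a set of tension-only string elements connecting them, and
#' a material law shared by all strings.  Three input nodes (where tensions
#' are applied along fixed lines of action) and two grounded output nodes
#' (where reaction forces are read out) are distinguished by the `role` and
#' `grounded` columns.  Strings that cross without sharing a node do not
#' interact mechanically.
#'
#' @param nodes data.frame with columns `id` (integer), `x`, `y` (mm),
#'   `role` (one of `"input"`, `"output"`, `"internal"`) and `grounded`
#'   (logical).
#' @param strings data.frame with columns `id`, `i`, `j` (node ids),
#'   `l0` (rest length, mm), `A` (cross-section, mm^2), `l_min`, `l_max`,
#'   `A_min`, `A_max` (evolution bounds).
#' @param material an [material_linear()] / [material_tendon()] object.
#' @param name label carried through serialization and reports.
#' @return an object of class `sn_mesh`.
#' @seealso [build_primordial_mesh()], [build_target_network()],
#'   [load_mesh()], [save_mesh()]
#' @export
new_mesh <- function(nodes, strings, material, name = "mesh") {
  nodes <- as.data.frame(nodes)
  strings <- as.data.frame(strings)
  mesh <- structure(list(nodes = nodes, strings = strings,
                         material = material, name = name),
                    class = "sn_mesh")
  validate_mesh(mesh)
}

#' Validate a mesh against its structural invariants
#'
#' Checks node/string schema, finite positions, dangling endpoint
#' references, positive bounds, and that parameters lie within their bounds.
#' Grounded nodes must have role `"output"`.
#'
#' @param mesh an `sn_mesh`.
#' @return the mesh, invisibly usable in pipelines; errors describe the
#'   offending field.
#' @export
validate_mesh <- function(mesh) {
  nd <- mesh$nodes
  st <- mesh$strings
  need_n <- c("id", "x", "y", "role", "grounded")
  if (!all(need_n %in% names(nd)))
    stop("mesh validation: nodes missing column(s): ",
         paste(setdiff(need_n, names(nd)), collapse = ", "), call. = FALSE)
  need_s <- c("id", "i", "j", "l0", "A", "l_min", "l_max", "A_min", "A_max")
  if (!all(need_s %in% names(st)))
    stop("mesh validation: strings missing column(s): ",
         paste(setdiff(need_s, names(st)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(nd$id))
    stop("mesh validation: duplicate node id", call. = FALSE)
  if (!all(is.finite(nd$x)) || !all(is.finite(nd$y)))
    stop("mesh validation: non-finite node position", call. = FALSE)
  if (!all(nd$role %in% c("input", "output", "internal")))
    stop("mesh validation: node role must be input/output/internal",
         call. = FALSE)
  if (any(nd$grounded & nd$role != "output"))
    stop("mesh validation: grounded node must have role 'output'",
         call. = FALSE)
  if (nrow(st)) {
    bad <- setdiff(c(st$i, st$j), nd$id)
    if (length(bad))
      stop("mesh structural error: string endpoint references missing node id ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(st$i == st$j))
      stop("mesh validation: string with identical endpoints", call. = FALSE)
    if (anyDuplicated(st$id))
      stop("mesh validation: duplicate string id", call. = FALSE)
    if (any(!(st$l_min > 0) | !(st$A_min > 0)))
      stop("mesh validation: bounds must be strictly positive", call. = FALSE)
    if (any(st$l_min >= st$l_max) || any(st$A_min >= st$A_max))
      stop("mesh validation: lower bound must be below upper bound",
           call. = FALSE)
    eps <- 1e-9
    if (any(st$l0 < st$l_min - eps) || any(st$l0 > st$l_max + eps))
      stop("mesh validation: rest length l0 outside length_bounds",
           call. = FALSE)
    if (any(st$A < st$A_min - eps) || any(st$A > st$A_max + eps))
      stop("mesh validation: cross-section A outside area_bounds",
           call. = FALSE)
  }
  if (!inherits(mesh$material, "sn_material"))
    stop("mesh validation: material must be an sn_material", call. = FALSE)
  mesh
}

#' @export
print.sn_mesh <- function(x, ...) {
  cat(sprintf("<sn_mesh> '%s': %d nodes (%d input, %d grounded), %d strings, %s material\n",
              x$name, nrow(x$nodes), sum(x$nodes$role == "input"),
              sum(x$nodes$grounded), nrow(x$strings), x$material$kind))
  invisible(x)
}

#' Node-id helpers
#'
#' @param mesh an `sn_mesh`.
#' @return integer node ids of the three input nodes / two grounded output
#'   nodes, in mesh order.
#' @export
input_nodes <- function(mesh) mesh$nodes$id[mesh$nodes$role == "input"]

#' @rdname input_nodes
#' @export
grounded_nodes <- function(mesh) mesh$nodes$id[mesh$nodes$grounded]

#' Read / write a mesh as JSON
#'
#' The schema is `{name, material:{kind, E_MPa | tendon params},
#' nodes:[{id, x_mm, y_mm, role, grounded}], strings:[{id, i, j, l0_mm,
#' A_mm2, l_bounds, A_bounds}]}`.  The round trip is lossless.
#'
#' @param mesh an `sn_mesh`.
#' @param path file path.
#' @return `load_mesh` returns a validated `sn_mesh`; `save_mesh` returns
#'   `path` invisibly.
#' @export
save_mesh <- function(mesh, path) {
  validate_mesh(mesh)
  nd <- mesh$nodes
  st <- mesh$strings
  obj <- list(
    name = mesh$name,
    material = material_to_list(mesh$material),
    nodes = data.frame(id = nd$id, x_mm = nd$x, y_mm = nd$y,
                       role = nd$role, grounded = nd$grounded),
    strings = lapply(seq_len(nrow(st)), function(k) list(
      id = st$id[k], i = st$i[k], j = st$j[k],
      l0_mm = st$l0[k], A_mm2 = st$A[k],
      l_bounds = c(st$l_min[k], st$l_max[k]),
      A_bounds = c(st$A_min[k], st$A_max[k])
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_mesh
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  for (f in c("name", "material", "nodes", "strings"))
    if (is.null(obj[[f]]))
      stop("mesh schema violation: missing field '", f, "'", call. = FALSE)
  nd <- obj$nodes
  for (f in c("id", "x_mm", "y_mm", "role", "grounded"))
    if (is.null(nd[[f]]))
      stop("mesh schema violation: nodes missing field '", f, "'",
           call. = FALSE)
  st <- obj$strings
  if (is.data.frame(st)) {
    strings <- data.frame(
      id = as.integer(st$id), i = as.integer(st$i), j = as.integer(st$j),
      l0 = as.numeric(st$l0_mm), A = as.numeric(st$A_mm2),
      l_min = vapply(st$l_bounds, function(b) as.numeric(b[1]), 0),
      l_max = vapply(st$l_bounds, function(b) as.numeric(b[2]), 0),
      A_min = vapply(st$A_bounds, function(b) as.numeric(b[1]), 0),
      A_max = vapply(st$A_bounds, function(b) as.numeric(b[2]), 0)
    )
  } else {
    strings <- data.frame(id = integer(), i = integer(), j = integer(),
                          l0 = numeric(), A = numeric(), l_min = numeric(),
                          l_max = numeric(), A_min = numeric(),
                          A_max = numeric())
  }
  nodes <- data.frame(id = as.integer(nd$id), x = as.numeric(nd$x_mm),
                      y = as.numeric(nd$y_mm), role = as.character(nd$role),
                      grounded = as.logical(nd$grounded))
  new_mesh(nodes, strings, material_from_list(obj$material),
           name = as.character(obj$name))
}

#' Undeformed input-to-output node distances
#'
#' The six distances, in the fixed reporting order (input1-output1,
#' input1-output2, input2-output1, ..., input3-output2).
#'
#' @param mesh an `sn_mesh`.
#' @return numeric vector of length 6 (mm), named `d11` ... `d32`.
#' @export
rest_distances <- function(mesh) {
  inp <- input_nodes(mesh)
  out <- grounded_nodes(mesh)
  nd <- mesh$nodes
  pos <- function(id) c(nd$x[nd$id == id], nd$y[nd$id == id])
  d <- numeric(0)
  nms <- character(0)
  for (a in seq_along(inp)) for (b in seq_along(out)) {
    d <- c(d, sqrt(sum((pos(inp[a]) - pos(out[b]))^2)))
    nms <- c(nms, paste0("d", a, b))
  }
  stats::setNames(d, nms)
}
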