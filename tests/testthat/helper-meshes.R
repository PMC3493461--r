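# Small meshes built in code for the unit tests.

# One horizontal string, node 1 grounded, node 2 pulled.
one_string_mesh <- function(E = 1.62, A = 4, l0 = 100) {
  nodes <- data.frame(id = 1:2, x = c(0, l0), y = c(0, 0),
                      role = c("output", "input"),
                      grounded = c(TRUE, FALSE))
  strings <- data.frame(id = 1, i = 1, j = 2, l0 = l0, A = A,
                        l_min = 0.01, l_max = 2 * l0, A_min = 0.01,
                        A_max = 2 * A)
  new_mesh(nodes, strings, material_linear(E), "one_string")
}

# Symmetric two-string "V": grounded at (-50, 100) and (50, 100), tip at
# the origin.
v_mesh <- function(E = 1.62, A = 4) {
  nodes <- data.frame(id = 1:3, x = c(-50, 50, 0), y = c(100, 100, 0),
                      role = c("output", "output", "input"),
                      grounded = c(TRUE, TRUE, FALSE))
  chord <- sqrt(50^2 + 100^2)
  strings <- data.frame(id = 1:2, i = c(1, 2), j = c(3, 3), l0 = chord,
                        A = A, l_min = 0.01, l_max = 3 * chord,
                        A_min = 0.01, A_max = 2 * A)
  new_mesh(nodes, strings, material_linear(E), "v")
}

# A paper-style 5-node mesh (3 inputs, 2 grounded) with a single load path
# from input 2 to ground 1; inputs 1 and 3 are unconnected.
single_path_mesh <- function() {
  nodes <- data.frame(id = 1:5, x = c(10, 50, 90, 30, 70),
                      y = c(0, 0, 0, 100, 100),
                      role = c("input", "input", "input", "output", "output"),
                      grounded = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  chord <- sqrt(20^2 + 100^2)
  strings <- data.frame(id = 1, i = 2, j = 4, l0 = chord, A = 4,
                        l_min = 0.01, l_max = 200, A_min = 0.01, A_max = 5)
  new_mesh(nodes, strings, material_linear(1.62), "single_path")
}

# Random well-posed tension network with <= 6 free nodes: two grounded
# anchors on top, free nodes below, every free node tied to at least two
# earlier nodes with taut-biased rest lengths.
random_small_network <- function(n_free = sample(1:4, 1)) {
  nodes <- data.frame(id = 1:2, x = c(-40, 40), y = c(100, 100),
                      role = "output", grounded = TRUE)
  for (k in seq_len(n_free)) {
    nodes <- rbind(nodes, data.frame(id = 2 + k,
                                     x = stats::runif(1, -60, 60),
                                     y = stats::runif(1, 0, 90),
                                     role = "input", grounded = FALSE))
  }
  edges <- NULL
  for (k in seq_len(n_free)) {
    id <- 2 + k
    others <- setdiff(nodes$id, id)
    n_con <- min(length(others), sample(2:3, 1))
    to <- sample(others, n_con)
    edges <- rbind(edges, data.frame(i = to, j = id))
  }
  edges <- unique(edges)
  chord <- sqrt((nodes$x[match(edges$j, nodes$id)] -
                 nodes$x[match(edges$i, nodes$id)])^2 +
                (nodes$y[match(edges$j, nodes$id)] -
                 nodes$y[match(edges$i, nodes$id)])^2)
  strings <- data.frame(id = seq_len(nrow(edges)), i = edges$i, j = edges$j,
                        l0 = chord * stats::runif(nrow(edges), 0.75, 1.0),
                        A = stats::runif(nrow(edges), 1, 5),
                        l_min = 0.01, l_max = 400, A_min = 0.01, A_max = 10)
  new_mesh(nodes, strings, material_linear(1.62), "random_small")
}

# Random downward-biased load on the free nodes of a mesh.
random_load <- function(mesh, fmax = 3) {
  n <- nrow(mesh$nodes)
  Fext <- matrix(0, n, 2)
  free <- which(!mesh$nodes$grounded)
  for (k in free) {
    mag <- stats::runif(1, 0.2, fmax)
    th <- stats::runif(1, -pi, 0)       # pull sideways/down
    Fext[k, ] <- mag * c(cos(th), sin(th))
  }
  Fext
}
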