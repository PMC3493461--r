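#' Solver configuration
#'
#' Numerical controls for the Newton-Raphson equilibrium solver.
#'
#' @param tol_N convergence tolerance on the infinity norm of the force
#'   residual over free degrees of freedom, N.
#' @param max_iter maximum Newton iterations.
#' @param stiffness_floor small stiffness added to the diagonal of the free
#'   tangent stiffness, N/mm, keeping it nonsingular when nodes are held
#'   only by slack strings.
#' @param step_cap cap on the infinity norm of a single Newton displacement
#'   update, mm; large steps out of slack configurations are scaled down
#'   before the line search.
#' @param max_halvings backtracking line-search depth per iteration.
#' @param energy_fallback when the Newton line search stalls (slack/taut
#'   switching can cycle), minimize the total potential energy by
#'   L-BFGS-B and polish with a second Newton pass.
#' @param fallback_maxit iteration cap of the energy minimizer.
#' @return a list of class `sn_solver_config`.
#' @export
solver_config <- function(tol_N = 1e-8, max_iter = 100,
                          stiffness_floor = 1e-9, step_cap = 100,
                          max_halvings = 30, energy_fallback = TRUE,
                          fallback_maxit = 500) {
  structure(list(tol_N = tol_N, max_iter = max_iter,
                 stiffness_floor = stiffness_floor, step_cap = step_cap,
                 max_halvings = max_halvings,
                 energy_fallback = energy_fallback,
                 fallback_maxit = fallback_maxit),
            class = "sn_solver_config")
}

# Internal solver-ready representation of a mesh: plain matrices/vectors so
# the Newton loop avoids data.frame access.  l0 and A may be overwritten in
# place by the evolutionary operators.  DOF ordering is (x of all nodes,
# then y of all nodes).
compile_mesh <- function(mesh) {
  nd <- mesh$nodes
  st <- mesh$strings
  idx <- match(st$i, nd$id)
  jdx <- match(st$j, nd$id)
  n <- nrow(nd)
  m <- nrow(st)
  free_node <- !nd$grounded
  # signed incidence matrix: column e is -1 at node i(e), +1 at node j(e)
  M <- matrix(0, n, m)
  if (m) {
    M[cbind(idx, seq_len(m))] <- -1
    M[cbind(jdx, seq_len(m))] <- 1
  }
  list(
    x = nd$x, y = nd$y,
    ei = idx, ej = jdx, m = m,
    l0 = st$l0, A = st$A,
    sid = st$id,
    n = n, free_node = free_node, n_free = sum(free_node),
    M = M, Mf = M[free_node, , drop = FALSE],
    input_idx = which(nd$role == "input"),
    grounded_idx = which(nd$grounded),
    stress = mesh$material$stress,
    tangent = mesh$material$tangent,
    energy = mesh$material$energy,
    matpar = material_params(mesh$material)
  )
}

# Flat parameter block consumed by the compiled Newton kernel; kind -1
# marks a material it cannot represent (falls back to the R path).
material_params <- function(m) {
  zero <- list(kind = -1L, E = 0, a = 0, b = 0, eps_toe = 0, E_linear = 0,
               sigma_toe = 0)
  if (m$kind == "linear") {
    zero$kind <- 0L
    zero$E <- m$E
  } else if (m$kind == "tendon" && !is.null(m$a)) {
    zero$kind <- 1L
    zero$a <- m$a; zero$b <- m$b; zero$eps_toe <- m$eps_toe
    zero$E_linear <- m$E_linear
    zero$sigma_toe <- m$a * (exp(m$b * m$eps_toe) - 1)
  } else if (m$kind == "tendon" && !is.null(m$E)) {
    zero$kind <- 0L        # degenerate toe: linear
    zero$E <- m$E
  }
  zero
}

# Element kinematics and forces at displacement (ux, uy) (mm).
cm_element_state <- function(cm, ux, uy) {
  px <- cm$x + ux
  py <- cm$y + uy
  dx <- px[cm$ej] - px[cm$ei]
  dy <- py[cm$ej] - py[cm$ei]
  l <- sqrt(dx * dx + dy * dy)
  eps <- (l - cm$l0) / cm$l0
  taut <- l >= cm$l0 & l > 0
  N <- numeric(cm$m)
  if (any(taut)) N[taut] <- cm$stress(eps[taut]) * cm$A[taut]
  ls <- pmax(l, 1e-300)
  ex <- dx / ls
  ey <- dy / ls
  # internal force vector: element adds -N*e at node i, +N*e at node j
  Fx <- drop(cm$M %*% (N * ex))
  Fy <- drop(cm$M %*% (N * ey))
  list(l = l, eps = eps, taut = taut, N = N, ex = ex, ey = ey,
       Fx = Fx, Fy = Fy)
}

# Free-DOF tangent stiffness from taut elements:
# k_material = (A * Et / l0) e e^T, k_geometric = (N / l)(I - e e^T),
# assembled blockwise as Mf diag(w) Mf^T for w in {kxx, kxy, kyy}.
cm_tangent <- function(cm, es, floor_k) {
  w <- as.numeric(es$taut)
  Et <- numeric(cm$m)
  t_idx <- which(es$taut)
  if (length(t_idx)) Et[t_idx] <- cm$tangent(es$eps[t_idx])
  km <- w * cm$A * Et / cm$l0
  kg <- w * es$N / pmax(es$l, 1e-300)
  exx <- es$ex * es$ex
  eyy <- es$ey * es$ey
  exy <- es$ex * es$ey
  kxx <- km * exx + kg * (1 - exx)
  kyy <- km * eyy + kg * (1 - eyy)
  kxy <- (km - kg) * exy
  Mf <- cm$Mf
  tMf <- t(Mf)
  Kxx <- Mf %*% (kxx * tMf)
  Kyy <- Mf %*% (kyy * tMf)
  Kxy <- Mf %*% (kxy * tMf)
  Kff <- rbind(cbind(Kxx, Kxy), cbind(Kxy, Kyy))
  diag(Kff) <- diag(Kff) + floor_k
  Kff
}

# Newton-Raphson iteration from a given start; core of the solver.
cm_newton <- function(cm, fx, fy, ctrl, ux = numeric(cm$n),
                      uy = numeric(cm$n)) {
  free <- cm$free_node
  residual_history <- numeric(0)
  es <- cm_element_state(cm, ux, uy)
  gx <- es$Fx - fx
  gy <- es$Fy - fy
  gf <- c(gx[free], gy[free])
  normg <- max(abs(gf))
  converged <- normg <= ctrl$tol_N
  iter <- 0L
  singular <- FALSE
  nf <- cm$n_free
  while (!converged && iter < ctrl$max_iter) {
    iter <- iter + 1L
    Kff <- cm_tangent(cm, es, ctrl$stiffness_floor)
    dUf <- tryCatch(solve(Kff, -gf), error = function(e) NULL)
    if (is.null(dUf) || any(!is.finite(dUf))) { singular <- TRUE; break }
    s <- max(abs(dUf))
    if (s > ctrl$step_cap) dUf <- dUf * (ctrl$step_cap / s)
    dux <- numeric(cm$n); duy <- numeric(cm$n)
    dux[free] <- dUf[seq_len(nf)]
    duy[free] <- dUf[nf + seq_len(nf)]
    # backtracking on the residual norm; keep the best step seen
    alpha <- 1
    best <- NULL
    for (h in seq_len(ctrl$max_halvings)) {
      uxt <- ux + alpha * dux
      uyt <- uy + alpha * duy
      es_try <- cm_element_state(cm, uxt, uyt)
      gxt <- es_try$Fx - fx
      gyt <- es_try$Fy - fy
      ntry <- max(abs(c(gxt[free], gyt[free])))
      if (is.finite(ntry) && (is.null(best) || ntry < best$norm))
        best <- list(ux = uxt, uy = uyt, es = es_try, gx = gxt, gy = gyt,
                     norm = ntry)
      if (is.finite(ntry) && ntry < normg) break
      alpha <- alpha / 2
    }
    if (is.null(best) || best$norm >= normg) {
      # stalled: no step reduced the residual
      converged <- normg <= ctrl$tol_N
      break
    }
    ux <- best$ux; uy <- best$uy; es <- best$es
    gx <- best$gx; gy <- best$gy
    gf <- c(gx[free], gy[free])
    normg <- best$norm
    residual_history <- c(residual_history, normg)
    converged <- normg <= ctrl$tol_N
  }
  list(ux = ux, uy = uy, element_state = es,
       Fint = cbind(es$Fx, es$Fy), residual = cbind(gx, gy),
       residual_norm = normg, converged = converged,
       iterations = iter, singular = singular,
       residual_history = residual_history)
}

# Total potential energy and its free-DOF gradient (= residual), used by
# the quasi-Newton fallback when the Newton line search stalls on a
# slack/taut switching cycle.
cm_potential <- function(cm, uf, fx, fy) {
  nf <- cm$n_free
  ux <- numeric(cm$n); uy <- numeric(cm$n)
  ux[cm$free_node] <- uf[seq_len(nf)]
  uy[cm$free_node] <- uf[nf + seq_len(nf)]
  px <- cm$x + ux
  py <- cm$y + uy
  dx <- px[cm$ej] - px[cm$ei]
  dy <- py[cm$ej] - py[cm$ei]
  l <- sqrt(dx * dx + dy * dy)
  eps <- pmax((l - cm$l0) / cm$l0, 0)
  sum(cm$A * cm$l0 * cm$energy(eps)) -
    sum(fx[cm$free_node] * ux[cm$free_node]) -
    sum(fy[cm$free_node] * uy[cm$free_node])
}

cm_potential_grad <- function(cm, uf, fx, fy) {
  nf <- cm$n_free
  ux <- numeric(cm$n); uy <- numeric(cm$n)
  ux[cm$free_node] <- uf[seq_len(nf)]
  uy[cm$free_node] <- uf[nf + seq_len(nf)]
  es <- cm_element_state(cm, ux, uy)
  c((es$Fx - fx)[cm$free_node], (es$Fy - fy)[cm$free_node])
}

# Dispatch one Newton solve to the compiled kernel when the material is
# representable there, else to the R reference implementation.
cm_newton_dispatch <- function(cm, fx, fy, ctrl, ux = numeric(cm$n),
                               uy = numeric(cm$n)) {
  if (cm$matpar$kind < 0L)
    return(cm_newton(cm, fx, fy, ctrl, ux, uy))
  out <- .cpp_newton(cm, fx, fy, ctrl$tol_N, as.integer(ctrl$max_iter),
                     ctrl$stiffness_floor, ctrl$step_cap,
                     as.integer(ctrl$max_halvings), ux, uy)
  es <- list(l = out$l, eps = out$eps,
             taut = out$l >= cm$l0 & out$l > 0, N = out$N,
             Fx = out$Fx, Fy = out$Fy)
  gx <- out$Fx - fx
  gy <- out$Fy - fy
  list(ux = out$ux, uy = out$uy, element_state = es,
       Fint = cbind(out$Fx, out$Fy), residual = cbind(gx, gy),
       residual_norm = out$residual_norm, converged = out$converged,
       iterations = out$iterations, singular = FALSE,
       residual_history = out$residual_history)
}

# Full solve: Newton first; if it stalls or runs out of iterations,
# minimize the total potential energy (L-BFGS-B, analytic gradient) from
# the best point found and polish with a second Newton pass.
cm_solve_xy <- function(cm, fx, fy, ctrl = solver_config()) {
  sol <- cm_newton_dispatch(cm, fx, fy, ctrl)
  if (!sol$converged && ctrl$energy_fallback) {
    free <- cm$free_node
    nf <- cm$n_free
    par0 <- c(sol$ux[free], sol$uy[free])
    opt <- tryCatch(
      stats::optim(par0, fn = cm_potential, gr = cm_potential_grad,
                   cm = cm, fx = fx, fy = fy, method = "L-BFGS-B",
                   control = list(maxit = ctrl$fallback_maxit,
                                  factr = 10)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      ux <- numeric(cm$n); uy <- numeric(cm$n)
      ux[free] <- opt$par[seq_len(nf)]
      uy[free] <- opt$par[nf + seq_len(nf)]
      sol2 <- cm_newton_dispatch(cm, fx, fy, ctrl, ux, uy)
      sol2$iterations <- sol$iterations + sol2$iterations
      sol2$residual_history <- c(sol$residual_history,
                                 sol2$residual_history)
      if (sol2$converged || sol2$residual_norm < sol$residual_norm)
        sol <- sol2
    }
  }
  sol
}

# Matrix-interface wrapper kept for the public solver surface.
cm_solve <- function(cm, Fext, ctrl = solver_config()) {
  sol <- cm_solve_xy(cm, Fext[, 1L], Fext[, 2L], ctrl)
  sol$U <- cbind(sol$ux, sol$uy)
  sol$Fext <- Fext
  sol
}

cm_applied_forces <- function(cm, input_magnitudes, input_angles) {
  Fext <- matrix(0, cm$n, 2L)
  th <- input_angles * pi / 180
  Fext[cm$input_idx, 1L] <- input_magnitudes * cos(th)
  Fext[cm$input_idx, 2L] <- input_magnitudes * sin(th)
  Fext
}

cm_readout_xy <- function(cm, sol) {
  # reaction magnitude at each grounded node: norm of the net string force
  # transmitted to it (the dynamometers swivel, so a magnitude is read)
  es <- sol$element_state
  gi <- cm$grounded_idx
  R <- sqrt(es$Fx[gi]^2 + es$Fy[gi]^2)
  px <- cm$x + sol$ux
  py <- cm$y + sol$uy
  ii <- rep(cm$input_idx, each = length(gi))
  oo <- rep(gi, times = length(cm$input_idx))
  d <- sqrt((px[ii] - px[oo])^2 + (py[ii] - py[oo])^2)
  list(reactions = R, distances = d)
}

cm_simulate <- function(cm, input_magnitudes, input_angles,
                        ctrl = solver_config()) {
  th <- input_angles * pi / 180
  fx <- numeric(cm$n)
  fy <- numeric(cm$n)
  fx[cm$input_idx] <- input_magnitudes * cos(th)
  fy[cm$input_idx] <- input_magnitudes * sin(th)
  sol <- cm_solve_xy(cm, fx, fy, ctrl)
  ro <- cm_readout_xy(cm, sol)
  list(reactions = ro$reactions, distances = ro$distances,
       converged = sol$converged, state = sol)
}

#' Current length of a displaced string element
#'
#' Euclidean distance between the displaced endpoints of one element.
#'
#' @param positions n x 2 matrix of undeformed node positions (mm), rows in
#'   mesh node order.
#' @param element one row of a mesh's `strings` data.frame (needs `i`, `j`
#'   as row indices or node ids matching `node_ids`).
#' @param displacements n x 2 matrix of nodal displacements (mm).
#' @param node_ids node ids corresponding to the rows of `positions`;
#'   defaults to row numbers.
#' @return length in mm (>= 0).
#' @export
string_length <- function(positions, element, displacements,
                          node_ids = seq_len(nrow(positions))) {
  i <- match(element$i, node_ids)
  j <- match(element$j, node_ids)
  p <- positions + displacements
  sqrt(sum((p[j, ] - p[i, ])^2))
}

#' Tension-only element response
#'
#' Computes strain, stress and axial force of a string element at current
#' length `l`.  A string shorter than its rest length is slack and carries
#' no force; a taut string carries the tensile force `sigma(eps) * A` along
#' the displaced chord, equal and opposite at its two nodes.
#'
#' @param element one row of a `strings` data.frame (uses `l0`, `A`).
#' @param material an `sn_material`.
#' @param l current chord length, mm.
#' @param direction unit 2-vector from node i to node j in the displaced
#'   configuration (used only to orient the nodal force vector).
#' @return list with `current_length`, `strain`, `stress` (MPa),
#'   `axial_force` (N), and `nodal_force_vector` (internal force
#'   contributions `(f_ix, f_iy, f_jx, f_jy)`, N).
#' @export
element_response <- function(element, material, l, direction = c(1, 0)) {
  if (!is.finite(l) || l < 0) stop("non-finite or negative length",
                                   call. = FALSE)
  l0 <- element$l0
  A <- element$A
  if (l < l0 || l == 0) {
    return(list(current_length = l, strain = 0, stress = 0, axial_force = 0,
                nodal_force_vector = c(0, 0, 0, 0)))
  }
  eps <- (l - l0) / l0
  sig <- material$stress(eps)
  N <- sig * A
  e <- direction / sqrt(sum(direction^2))
  list(current_length = l, strain = eps, stress = sig, axial_force = N,
       nodal_force_vector = c(-N * e, N * e))
}

#' Solve static equilibrium of a string network
#'
#' Newton-Raphson iteration on the force residual `g(U) = F(U) - F_e`,
#' starting from `U = 0`, with slack/taut element status re-evaluated at
#' every trial state and the tangent stiffness assembled from taut elements
#' only.  Under-constrained configurations (all-slack nodes) are
#' regularized by a tiny stiffness floor; a singular tangent or exhausted
#' iteration budget is reported as `converged = FALSE`, never as an error.
#'
#' @param mesh an `sn_mesh`.
#' @param applied n x 2 matrix of external nodal forces (N), rows in mesh
#'   node order; forces on grounded nodes are ignored (their DOFs are
#'   constrained).
#' @param control a [solver_config()].
#' @return a list (class `sn_solver_state`) with `displacements` (n x 2,
#'   mm), `internal_force`, `external_force`, `residual` (n x 2, N),
#'   `converged`, `iterations`, `residual_history`, `reactions` (N, one per
#'   grounded node) and per-element `elements` (length, strain, tension,
#'   taut flag).
#' @export
solve_equilibrium <- function(mesh, applied, control = solver_config()) {
  cm <- compile_mesh(mesh)
  stopifnot(is.matrix(applied), nrow(applied) == cm$n, ncol(applied) == 2L)
  sol <- cm_solve(cm, applied, control)
  ro <- cm_readout_xy(cm, sol)
  es <- sol$element_state
  structure(list(
    displacements = sol$U,
    internal_force = sol$Fint,
    external_force = sol$Fext,
    residual = sol$residual,
    residual_norm = sol$residual_norm,
    residual_history = sol$residual_history,
    converged = sol$converged,
    iterations = sol$iterations,
    reactions = ro$reactions,
    distances = ro$distances,
    elements = data.frame(id = cm$sid, length = es$l, strain = es$eps,
                          tension = es$N, taut = es$taut)
  ), class = "sn_solver_state")
}

#' Simulate one load set on a network
#'
#' Applies the three input tensions along their fixed global directions
#' (the lines of action stay constant while the input nodes move), solves
#' for equilibrium and reads out the two grounded reaction magnitudes and
#' the six input-to-output inter-nodal distances in the fixed order
#' `d11, d12, d21, d22, d31, d32` (input index first).
#'
#' @param mesh an `sn_mesh` with 3 input and 2 grounded nodes.
#' @param input_magnitudes 3-vector of tensions, N.
#' @param input_angles 3-vector of angles from the horizontal, degrees
#'   (negative pulls downward, e.g. -90 is straight down).
#' @param control a [solver_config()].
#' @return list with `reactions` (2-vector, N), `distances` (6-vector, mm)
#'   and `converged`.
#' @export
simulate_loadset <- function(mesh, input_magnitudes, input_angles,
                             control = solver_config()) {
  stopifnot(length(input_magnitudes) == 3, length(input_angles) == 3)
  cm <- compile_mesh(mesh)
  out <- cm_simulate(cm, input_magnitudes, input_angles, control)
  out[c("reactions", "distances", "converged")]
}

#' Export a deformed-configuration snapshot
#'
#' Writes node positions and per-element slack/taut status of a solved
#' state as JSON, for plotting taut versus slack strings.
#'
#' @param mesh the solved `sn_mesh`.
#' @param state an `sn_solver_state` from [solve_equilibrium()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
deformation_snapshot <- function(mesh, state, path) {
  pos <- cbind(mesh$nodes$x, mesh$nodes$y) + state$displacements
  obj <- list(
    name = mesh$name,
    converged = state$converged,
    nodes = data.frame(id = mesh$nodes$id, x_mm = pos[, 1], y_mm = pos[, 2],
                       role = mesh$nodes$role, grounded = mesh$nodes$grounded),
    elements = state$elements
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
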