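# Independent oracles, written directly against the mesh data frames (not
# the package's solver internals).

# Equilibrium by direct minimization of the total potential energy over
# the free node positions.  Strain energy density of a linear tension-only
# string is E * eps^2 / 2 for eps > 0, zero otherwise.
oracle_equilibrium <- function(mesh, Fext, reltol = 1e-16, maxit = 20000) {
  nd <- mesh$nodes
  st <- mesh$strings
  E <- mesh$material$E
  stopifnot(!is.null(E))          # linear material only
  free <- which(!nd$grounded)
  p0 <- c(nd$x[free], nd$y[free])
  nf <- length(free)
  ii <- match(st$i, nd$id)
  jj <- match(st$j, nd$id)
  positions <- function(par) {
    x <- nd$x; y <- nd$y
    x[free] <- par[seq_len(nf)]
    y[free] <- par[nf + seq_len(nf)]
    cbind(x, y)
  }
  energy <- function(par) {
    p <- positions(par)
    l <- sqrt((p[jj, 1] - p[ii, 1])^2 + (p[jj, 2] - p[ii, 2])^2)
    eps <- pmax((l - st$l0) / st$l0, 0)
    elastic <- sum(st$A * st$l0 * 0.5 * E * eps^2)
    work <- sum(Fext[free, 1] * (p[free, 1] - nd$x[free])) +
      sum(Fext[free, 2] * (p[free, 2] - nd$y[free]))
    elastic - work
  }
  grad <- function(par) {
    p <- positions(par)
    dx <- p[jj, 1] - p[ii, 1]
    dy <- p[jj, 2] - p[ii, 2]
    l <- pmax(sqrt(dx^2 + dy^2), 1e-300)
    eps <- (l - st$l0) / st$l0
    N <- ifelse(eps > 0, st$A * E * eps, 0)
    gx <- rep(0, nrow(nd)); gy <- rep(0, nrow(nd))
    for (e in seq_along(N)) {
      ex <- dx[e] / l[e]; ey <- dy[e] / l[e]
      gx[jj[e]] <- gx[jj[e]] + N[e] * ex
      gy[jj[e]] <- gy[jj[e]] + N[e] * ey
      gx[ii[e]] <- gx[ii[e]] - N[e] * ex
      gy[ii[e]] <- gy[ii[e]] - N[e] * ey
    }
    c(gx[free] - Fext[free, 1], gy[free] - Fext[free, 2])
  }
  opt <- stats::optim(p0, energy, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  p <- positions(opt$par)
  U <- p - cbind(nd$x, nd$y)
  list(displacements = U, value = opt$value, convergence = opt$convergence)
}

# Dense grid search minimum of a 1-D function.
grid_minimum <- function(f, lower, upper, n = 200001) {
  xs <- seq(lower, upper, length.out = n)
  fs <- vapply(xs, f, 0)
  k <- which.min(fs)
  list(x = xs[k], value = fs[k])
}

# The multimodal demo objective minimized by the RMHC kernel.
rmhc_demo_f <- function(x) (1 + x^2) * (1 - 0.5 * sin(4 * x))
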