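#' Material models for string elements
#'
#' A material maps engineering strain to engineering stress for a string
#' loaded in tension.  Two kinds are supported: a linear elastic law
#' `sigma = E * eps` (synthetic Latex rubber, default E = 1.62 MPa), and a
#' nonlinear tendon law with an exponential toe region blending C1-smoothly
#' into a linear region (generic mammalian tendon: linear modulus about
#' 1.2 GPa beyond a toe ending near 1.27% strain).
#'
#' Units are MPa and dimensionless strain throughout, so that
#' stress (MPa) x area (mm^2) = force (N).
#'
#' @param E elastic modulus, MPa.
#' @param E_linear linear-region modulus of the tendon curve, MPa.
#' @param eps_toe strain at which the toe region ends.
#' @param toe_stress_fraction stress at the end of the toe expressed as a
#'   fraction of the linear extrapolation `E_linear * eps_toe`; must lie in
#'   (0, 1).  Controls the sharpness of the exponential toe.
#' @return an object of class `sn_material` with fields `kind`, parameter
#'   values, and closures `stress(eps)` and `tangent(eps)` (d sigma / d eps).
#' @examples
#' latex <- material_linear(1.62)
#' latex$stress(0.1)            # 0.162 MPa
#' tendon <- material_tendon()
#' tendon$stress(0.05)          # well into the linear region
#' @export
material_linear <- function(E = 1.62) {
  stopifnot(is.finite(E), E > 0)
  force(E)
  structure(list(
    kind = "linear",
    E = E,
    stress = function(eps) E * pmax(eps, 0),
    tangent = function(eps) ifelse(eps >= 0, E, 0),
    energy = function(eps) 0.5 * E * pmax(eps, 0)^2
  ), class = "sn_material")
}

#' @rdname material_linear
#' @export
material_tendon <- function(E_linear = 1200, eps_toe = 0.0127,
                            toe_stress_fraction = 0.5) {
  stopifnot(E_linear > 0, eps_toe >= 0, toe_stress_fraction > 0,
            toe_stress_fraction < 1)
  if (eps_toe < 1e-8) {
    # degenerate toe: pure linear law
    m <- material_linear(E_linear)
    m$kind <- "tendon"
    m$E_linear <- E_linear
    m$eps_toe <- eps_toe
    return(m)
  }
  # Toe: sigma = a * (exp(b * eps) - 1) on [0, eps_toe], constrained so that
  # the slope at eps_toe equals E_linear (C1 continuity) and the toe-end
  # stress equals toe_stress_fraction * E_linear * eps_toe.  With x = b *
  # eps_toe those constraints reduce to (1 - exp(-x)) / x = fraction.
  f <- toe_stress_fraction
  x <- stats::uniroot(function(x) (1 - exp(-x)) / x - f,
                      interval = c(1e-8, 500), tol = 1e-12)$root
  b <- x / eps_toe
  a <- E_linear / (b * exp(x))
  sigma_toe <- a * (exp(x) - 1)
  stress <- function(eps) {
    eps <- pmax(eps, 0)
    ifelse(eps <= eps_toe,
           a * (exp(b * eps) - 1),
           sigma_toe + E_linear * (eps - eps_toe))
  }
  tangent <- function(eps) {
    ifelse(eps < 0, 0, ifelse(eps <= eps_toe, a * b * exp(b * eps), E_linear))
  }
  W_toe <- a * (exp(x) - 1) / b - a * eps_toe   # strain energy at toe end
  energy <- function(eps) {
    eps <- pmax(eps, 0)
    ifelse(eps <= eps_toe,
           a * (exp(b * eps) - 1) / b - a * eps,
           W_toe + sigma_toe * (eps - eps_toe) +
             0.5 * E_linear * (eps - eps_toe)^2)
  }
  structure(list(
    kind = "tendon", E_linear = E_linear, eps_toe = eps_toe,
    toe_stress_fraction = f, a = a, b = b,
    stress = stress, tangent = tangent, energy = energy
  ), class = "sn_material")
}

#' @export
print.sn_material <- function(x, ...) {
  if (x$kind == "linear") {
    cat(sprintf("<sn_material> linear, E = %g MPa\n", x$E))
  } else {
    cat(sprintf("<sn_material> tendon, E_linear = %g MPa, toe to eps = %g\n",
                x$E_linear, x$eps_toe))
  }
  invisible(x)
}

material_from_list <- function(lst) {
  kind <- lst$kind
  if (identical(kind, "linear")) {
    material_linear(E = as.numeric(lst$E_MPa))
  } else if (identical(kind, "tendon")) {
    material_tendon(
      E_linear = as.numeric(lst$E_linear_MPa %||% 1200),
      eps_toe = as.numeric(lst$eps_toe %||% 0.0127),
      toe_stress_fraction = as.numeric(lst$toe_stress_fraction %||% 0.5)
    )
  } else {
    stop("unknown material kind: ", kind, call. = FALSE)
  }
}

material_to_list <- function(m) {
  if (m$kind == "linear") {
    list(kind = "linear", E_MPa = m$E)
  } else {
    list(kind = "tendon", E_linear_MPa = m$E_linear, eps_toe = m$eps_toe,
         toe_stress_fraction = m$toe_stress_fraction)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
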