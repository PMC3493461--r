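#' Mutation specification
#'
#' Parameters of the bounded mutation law used by the random-mutation hill
#' climber.  A selected free parameter `c` with bounds `[c_L, c_U]` is
#' altered to `c_new = c +/- (c_U - c_L) * exp(R1 + r * R2)` with `r`
#' uniform on [0, 1] and the sign equiprobable, then clamped to the
#' bounds.  With the defaults R1 = -8, R2 = 9 the step magnitude lies
#' between `exp(-8) = 3.35e-4` and `exp(1) = 2.72` times the parameter
#' range, encouraging both fine and coarse moves.
#'
#' Each free parameter is selected for mutation with probability `p_rate`
#' (kept below 15% so the climber does not degenerate into random search).
#' Two auxiliary step regimes reuse the same law with `r` restricted:
#' `"fine"` allows only steps below 1% of the range at rate
#' `5 * p_rate`, `"coarse"` only steps above 20% at rate `0.2 * p_rate`.
#' `strategy_weights` gives the per-proposal probabilities of the
#' standard/fine/coarse regimes.
#'
#' @param R1,R2 exponents of the step-magnitude law.
#' @param p_rate per-parameter mutation probability of the standard regime.
#' @param fine_rate_multiplier,coarse_rate_multiplier rate multipliers of
#'   the fine (<1% steps) and coarse (>20% steps) regimes.
#' @param strategy_weights sampling weights of the three regimes.
#' @return list of class `sn_mutation_spec`.
#' @export
mutation_spec <- function(R1 = -8, R2 = 9, p_rate = 0.08,
                          fine_rate_multiplier = 5,
                          coarse_rate_multiplier = 0.2,
                          strategy_weights = c(standard = 0.6, fine = 0.3,
                                               coarse = 0.1)) {
  stopifnot(p_rate > 0, p_rate < 0.15, R2 > 0,
            length(strategy_weights) == 3)
  structure(list(R1 = R1, R2 = R2, p_rate = p_rate,
                 fine_rate_multiplier = fine_rate_multiplier,
                 coarse_rate_multiplier = coarse_rate_multiplier,
                 strategy_weights = strategy_weights / sum(strategy_weights)),
            class = "sn_mutation_spec")
}

# Admissible range of r and effective selection rate for a step regime.
# fine: (cU-cL)*exp(R1 + r R2) < 0.01 (cU-cL)  <=>  r < (log(0.01) - R1)/R2
# coarse: step fraction > 0.2                  <=>  r > (log(0.2)  - R1)/R2
strategy_params <- function(spec, strategy) {
  switch(strategy,
    standard = list(r_lo = 0, r_hi = 1, rate = spec$p_rate),
    fine = list(r_lo = 0,
                r_hi = min(1, (log(0.01) - spec$R1) / spec$R2),
                rate = min(1, spec$fine_rate_multiplier * spec$p_rate)),
    coarse = list(r_lo = max(0, (log(0.2) - spec$R1) / spec$R2),
                  r_hi = 1,
                  rate = spec$coarse_rate_multiplier * spec$p_rate),
    stop("unknown strategy: ", strategy, call. = FALSE))
}

#' Mutate one bounded parameter
#'
#' Applies the mutation law once (the parameter is assumed already
#' selected).  Values leaving `[c_L, c_U]` are set to the violated bound.
#'
#' @param c current value, inside `[c_L, c_U]`.
#' @param c_L,c_U bounds, `c_L < c_U`.
#' @param spec a [mutation_spec()].
#' @param r optional draw in [0, 1] (random if `NULL`).
#' @param sign optional +1/-1 (random if `NULL`).
#' @param strategy step regime restricting the range of `r`.
#' @return mutated value in `[c_L, c_U]`.
#' @export
mutate_parameter <- function(c, c_L, c_U, spec = mutation_spec(), r = NULL,
                             sign = NULL, strategy = "standard") {
  if (!(c_L < c_U)) stop("degenerate bounds: c_L must be < c_U",
                         call. = FALSE)
  sp <- strategy_params(spec, strategy)
  if (is.null(r)) r <- stats::runif(1, sp$r_lo, sp$r_hi)
  if (is.null(sign)) sign <- sample(c(-1, 1), 1)
  c_new <- c + sign * (c_U - c_L) * exp(spec$R1 + r * spec$R2)
  min(max(c_new, c_L), c_U)
}

# Vectorized mutation of a parameter vector with per-parameter selection.
mutate_vector <- function(vals, lo, hi, spec, strategy) {
  sp <- strategy_params(spec, strategy)
  sel <- stats::runif(length(vals)) < sp$rate
  k <- sum(sel)
  if (k == 0) return(vals)
  r <- stats::runif(k, sp$r_lo, sp$r_hi)
  sgn <- sample(c(-1, 1), k, replace = TRUE)
  step <- (hi[sel] - lo[sel]) * exp(spec$R1 + r * spec$R2)
  vals[sel] <- pmin(pmax(vals[sel] + sgn * step, lo[sel]), hi[sel])
  vals
}

#' Mutate a candidate model
#'
#' Independently mutates each string's rest length and cross-section with
#' the regime's selection probability and step law.  The node set and
#' string connectivity never change: topology evolves only implicitly,
#' through strings whose lengths keep them slack under every test.
#'
#' @param model an `sn_mesh` derived from a primordial mesh.
#' @param spec a [mutation_spec()].
#' @param strategy `"standard"`, `"fine"` or `"coarse"`.
#' @return mutated `sn_mesh`.
#' @export
mutate_model <- function(model, spec = mutation_spec(),
                         strategy = c("standard", "fine", "coarse")) {
  strategy <- match.arg(strategy)
  st <- model$strings
  st$l0 <- mutate_vector(st$l0, st$l_min, st$l_max, spec, strategy)
  st$A <- mutate_vector(st$A, st$A_min, st$A_max, spec, strategy)
  model$strings <- st
  model
}

#' Random-mutation hill climber on a bounded function
#'
#' The generic minimization kernel used throughout the package, exposed
#' directly: propose a mutation of the current point (each coordinate with
#' probability `p_rate`, at least one always), accept iff the objective
#' strictly decreases.  Capable of locating global optima of multimodal
#' smooth functions, e.g. `f(x) = (1 + x^2) * (1 - sin(4 * x) / 2)`, given
#' an adequate iteration budget.
#'
#' @param f objective, taking a numeric vector.
#' @param lower,upper bounds (recycled).
#' @param init starting point (default midpoint).
#' @param iterations proposal budget.
#' @param spec a [mutation_spec()].
#' @return list `par`, `value`, `accepted` (count), `trace` (accepted
#'   objective values, non-increasing).
#' @export
rmhc_minimize <- function(f, lower, upper, init = NULL, iterations = 5000,
                          spec = mutation_spec()) {
  n <- max(length(lower), length(upper))
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  x <- if (is.null(init)) (lower + upper) / 2 else rep_len(init, n)
  fx <- f(x)
  accepted <- 0L
  trace <- fx
  for (it in seq_len(iterations)) {
    sel <- stats::runif(n) < spec$p_rate
    if (!any(sel)) sel[sample.int(n, 1)] <- TRUE
    xn <- x
    k <- sum(sel)
    r <- stats::runif(k)
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    step <- (upper[sel] - lower[sel]) * exp(spec$R1 + r * spec$R2)
    xn[sel] <- pmin(pmax(x[sel] + sgn * step, lower[sel]), upper[sel])
    fn <- f(xn)
    if (is.finite(fn) && fn < fx) {
      x <- xn; fx <- fn; accepted <- accepted + 1L
      trace <- c(trace, fx)
    }
  }
  list(par = x, value = fx, accepted = accepted, trace = trace)
}
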