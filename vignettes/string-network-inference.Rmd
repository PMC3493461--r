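---
title: "Inferring elastic string networks from sparse tensile tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring elastic string networks from sparse tensile tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stringnet)
```

## The problem

Anatomical tendon networks -- the extensor mechanism on the back of a
finger is the classic example -- distribute muscle tensions to joints
through a web of collagen bands that has been approximated as a network of
strings since Winslow's 1732 description.  Imaging misses mechanically
critical interconnections, and dissection destroys them.  `stringnet`
implements a functional alternative: interrogate the specimen with a small
number of tensile tests and infer, in simulation, a population of string
models (topology *and* parameters) that explain the measured
force-deformation behaviour.

The measurement protocol mirrors a bench experiment: three input nodes are
pulled by tethers with commanded tensions along fixed lines of action; two
grounded output nodes report reaction-force magnitudes on swivelling
dynamometers; and six input-to-output inter-nodal distances are read with
a caliper once the network reaches static equilibrium.  One such record --
3 commanded tensions, 2 reactions, 6 distances -- is a *load set*.

## Mechanical model

Each string is a tension-only truss element with rest length $l_o$ (mm)
and cross-section $A$ (mm$^2$).  With displaced chord length $l$, the
engineering strain is $\varepsilon = (l - l_o)/l_o$; a string with
$l < l_o$ is *slack* and carries nothing, a taut string carries the axial
force $\sigma(\varepsilon)\,A$ along the displaced chord (units mm / N /
MPa, so no conversion factors appear).  Two material laws are provided:
linear $\sigma = E\varepsilon$ with $E = 1.62$ MPa for Latex rubber, and a
tendon law with an exponential toe blending $C^1$-smoothly into a linear
region ($E_{\text{lin}} = 1200$ MPa beyond a toe ending at 1.27% strain,
toe-end stress half the linear extrapolation; all four shape parameters
configurable).  A control material with constant $E = 1$ GPa is available
through `material_linear(1000)`.

Equilibrium solves $\mathbf g(\mathbf U) = \mathbf F(\mathbf U) -
\mathbf F_e = \mathbf 0$ by Newton-Raphson iteration from $\mathbf U =
\mathbf 0$, with the tangent stiffness assembled from taut elements only
(material part $A E_t/l_o\,\mathbf e\mathbf e^T$, geometric part
$N/l\,(\mathbf I - \mathbf e\mathbf e^T)$).  Large displacements are
exact through the current-chord kinematics; strains are engineering
strains (a large-displacement, small-strain formulation -- a
Green-Lagrange large-strain variant is deliberately out of scope).

Numerical choices, all configurable through `solver_config()`:

* convergence at $\|\mathbf g\|_\infty \le 10^{-8}$ N on free DOFs,
  at most 100 iterations;
* a stiffness floor of $10^{-9}$ N/mm on the diagonal keeps the tangent
  regular when nodes are held only by slack strings;
* Newton updates are capped at 100 mm and backtracked on the residual
  norm; slack/taut status is re-evaluated at every trial state;
* if the line search stalls (slack/taut switching can cycle), the solver
  minimizes the total potential energy by L-BFGS-B with the analytic
  gradient and polishes the result with a second Newton pass.  A solve
  that still fails is reported as non-convergent, never as a crash; the
  fitness layer assigns such models a large finite sentinel error
  ($10^6$%) so the hill climber discards them.

The Newton kernel is compiled (Rcpp/RcppArmadillo); an R reference
implementation of the same iteration backs custom material laws, and the
two are held to machine-precision agreement by the test suite.  A third,
fully independent equilibrium route -- direct minimization of the total
potential energy over node positions -- lives in the test helpers and
cross-checks the solver to $10^{-6}$ relative displacement error on
randomized networks.

## Fitness of a model

For a model simulated against the $N_{DS}$ exposed load sets, `obj_R`
averages the relative reaction discrepancies over all $N_R \times N_{DS}$
comparisons (in percent, denominators are the measured values guarded by
$10^{-3}$ N), `obj_D` does the same for the $N_D \times N_{DS}$ distances
($10^{-3}$ mm guard), and the training error is their arithmetic mean.
Cross-validation uses the *max*-based counterpart on the held-out grid:
the worst relative reaction discrepancy and the worst relative distance
discrepancy, averaged.  It bounds the maximal functional disagreement
between model and target and can never fall below the mean-based error on
the same sets; the mean-based form is kept for training because the
max-based landscape is too rough to descend efficiently.

The printed forms of these errors in the source material are images, so
the package fixes the algebra by their stated contracts (averages for
training, maximum for cross-validation) and documents the denominators and
guards above as implementation choices.

## Informativeness of a test

Given a population of models, a candidate test (three magnitudes, fixed
angles) is scored by simulating it on every model and measuring the
across-model dispersion of each output component -- its range, i.e. the
sum of the extreme deviations about the across-model mean.  The score

$$e_{test} = \frac{100}{2}\left(\frac{1}{N_R}\sum_j
\frac{\mathrm{range}_j(R)}{F_U} + \frac{1}{N_D}\sum_j
\frac{\mathrm{range}_j(d)}{\bar d}\right)$$

normalizes reaction ranges by the force bound $F_U = 5$ N (the
dynamometer full scale) and distance ranges by the pooled across-model
mean distance $\bar d$.  Two deliberate choices here:

* **Range, not variance.**  The range equals the dispersion about the
  mean at the extremes, is zero iff all models agree, and adding a
  duplicate model can never increase it -- a robustness property that
  sample or population variance lacks.
* **Pooled, scale-aware denominators.**  Normalizing each component by
  its own across-model mean (the obvious percent-style choice) makes the
  score maximal for tests whose outputs are nearly zero, since ratios of
  vanishing reactions blow up; Stage III then chases weak-force tests
  whose differences the instruments cannot even resolve.  The pooled
  normalization keeps $e_{test}$ dimensionless while tracking absolute,
  measurable disagreement.

## The estimation-exploration loop

`run_inference()` wires the three stages together:

1. **Stage I** -- the virtual laboratory measures the full design grid on
   a known in-silico target (4 force levels per input $\to 4^3 = 64$
   training sets; 2 levels $\to 2^3 = 8$ cross-validation sets;
   record order shuffled) and exposes one random training record.
2. **Stage II** -- a population of models evolves by random-mutation hill
   climbing.  A selected parameter mutates to $c_{new} = c \pm (c_U -
   c_L)\,e^{R_1 + r R_2}$ with $r \sim U[0,1]$, sign equiprobable,
   clamped to its bounds; with $R_1 = -8$, $R_2 = 9$ steps span
   $3.35\times10^{-4}$ to $2.72$ of the parameter range.  Each parameter
   is selected with probability $p_{rate} = 0.08$; auxiliary regimes make
   only sub-1% steps at $5\,p_{rate}$ or only >20% steps at
   $0.2\,p_{rate}$ (regimes drawn 0.6/0.3/0.1 per proposal).  A proposal
   replaces its model iff the training error strictly decreases.
   Termination: error below 0.5% (that model rests), or a no-improvement
   streak $G > 2 G_L$ with $G \ge G_{min}$, or a hard iteration cap.
   A stagnant worst model is crossed over with a random other model by
   uniform per-string parameter exchange, kept only if it improves
   (the crossover form and trigger are unspecified upstream; this is the
   package's interpretation).
3. **Stage III** -- the next test evolves by the same mutation law on the
   three magnitudes, maximizing $e_{test}$; the request is answered by
   the nearest precollected training record in least-squares magnitude
   space, by default without replacement (ties break to the
   lexicographically smallest magnitudes).  An oracle comparison mode
   that serves random records instead isolates the value of informative
   testing.

The loop repeats until a preset number of records (study scale: 20) has
been exposed.  Topology is read out at the end: a string participates iff
it became taut under at least one served test; strings slack throughout
are excluded from the reported topology but kept in the model, since a
later test may engage them.

## What the generator emulates, and what it does not

`build_target_network()` provides ground-truth networks on the
100 x 100 mm Latex footprint (4 mm$^2$ sections, i.e. 4 mm wide x 1 mm
thick) and a tendon-material rhombus on the smaller extensor footprint;
`build_primordial_mesh()` provides the over-complete starting fabrics
with the published string counts (36 for the AFH setup, 54 for the
adapted Winslow's rhombus, 71 for the extensor) and evolution bounds
(lengths up to 100 / 70 / 33 mm, sections within [0.01, 5] /
[0.01, 5] / [0.01, 11] mm$^2$).  Node coordinates of the published
fabrics and targets are available only as figures, so the builders place
nodes on regular layered layouts spanning the stated footprints; the
targets are therefore *synthetic stand-ins* that preserve footprint, node
counts, grounded-node spacing, materials and bounds, not replicas.
Published error tables against the physical specimens are consequently
not reproduction targets for this package.

The virtual laboratory reproduces the instrument model -- dynamometer
quantization of 2 g (0.0196 N), caliper quantization of 1 mm, optional
Gaussian noise ahead of quantization -- but none of the bench
pathologies: tether compliance, friction or stiction, manual-loading
cross-talk between inputs, or tissue degradation over a measurement
session.  Passing recovery tests on these targets therefore demonstrates
the correctness of the inference machinery, not the fidelity of any
specific anatomical reconstruction.

## Reproducibility and problem sizes

Every entry point draws all randomness from one `seed` argument through
R's generator, so runs are bit-reproducible at fixed population size (a
per-model stream split would additionally make them invariant to
population-size changes; base R offers no cheap stream splitting, and the
single-stream design is what the determinism tests assert).  The test
suite and the acceptance script run scaled-down configurations chosen as
sensible validation sizes: populations of 2-4 models, 6-8 exposed sets,
per-cycle hill-climb caps of a few thousand iterations on the 6-string
all-in-all recovery problem (12 free parameters), versus the study-scale
8 models, 20 sets and 100 000-iteration caps, which remain the defaults
of `mutation_spec()` / `evolution_counters()`.

## Known limitations

* 2D only; no wrapping over joint surfaces, no sheet/continuum
  parameterizations, no contact or friction between crossing strings
  (crossings without a shared node are mechanically independent).
* No dynamics, viscoelasticity or hysteresis; statics only.
* The tendon curve is a generic parameterization, not a fit to a
  specific specimen.
* Recovery of a unique topology is not guaranteed -- functionally
  equivalent, structurally diverse models are an expected outcome, and
  the string-ablation table (`ablate_strings()`) is the provided tool
  for probing which members of a recovered model are functionally
  relevant.

## A short worked example

```{r example, eval = FALSE}
cfg <- run_config(
  target = "all_in_all", primordial = "all_in_all_latex",
  proto = protocol("afh", quantize = TRUE),
  population_size = 3, max_informative_sets = 8,
  counters = evolution_counters(G_min = 1500, hard_iteration_limit = 6000,
                                stagnation_window = 1500),
  test_max_iter = 200, test_G_min = 50)
run <- run_inference(cfg, seed = 1)
run
min(run$final_errors)     # best training error, percent
run$topologies[[which.min(run$final_e_cross)]]
report(run, "stringnet_out")
```
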