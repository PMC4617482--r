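---
title: "Conditional robustness analysis: model, method and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional robustness analysis: model, method and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A biochemical network model rarely comes with one trustworthy
parameter vector: rate constants are known to an order of magnitude at
best. Robustness analysis embraces this by studying an *evaluation
function* — a scalar readout z of a simulated trajectory, such as the
area under an active-kinase curve — over a whole box of parameter
values. Under a uniform prior over that box, the readout becomes a
random variable Z with density f_Z(z), and the prior-weighted mean of
ζ over the box is the classical robustness measure of the capability
(implemented as `kitano_robustness()`, the Monte-Carlo sample mean).

`condrob` addresses the *inverse* question: which few parameters, set
to which values, move f_Z(z) into a desired regime? In oncology terms,
which nodes of a signalling cascade should a drug pin, and how hard,
to silence a proliferation readout; in synthetic biology, which
kinetic constants tune a circuit toward a faster or larger pulse. The
answer is a *conditioning set* K: a small set of parameters and fixed
values such that the conditional density f_{Z|K}(z) concentrates where
we want it.

## The procedure

1. **Sample** the parameter box with a Latin hypercube with linearly
   spaced strata (`sample_l2hs()`): each of the N samples occupies one
   of N equal-width strata per dimension, which makes the
   one-dimensional marginals very close to uniform at moderate N.
2. **Simulate** each draw and score it with the evaluation function
   (`evaluate_batch()`), giving the output sample set 𝒵.
3. **Partition** 𝒵 into the lower and upper tails L and U holding the
   `round(alpha*N)` smallest and largest outputs
   (`partition_output()`).
4. **Estimate conditional densities**: for every parameter, a Gaussian
   kernel density of its values among the samples that landed in U,
   and another for L (`estimate_density()`).
5. **Rank** parameters by the moment-independent robustness indicator
   (`miri()`), the L1 distance
   μ_i = ∫ |f_{P_i|U}(p) − f_{P_i|L}(p)| dp.
   μ_i ranges from 0 — the two tails place no constraint on p_i, its
   conditional marginals coincide — to 2 — the tails confine p_i to
   disjoint regions. Because it compares whole densities rather than
   moments, it is insensitive to how the output scale stretches
   either tail.
6. **Condition**: fix the top-k parameters at the mode of the tail
   density matching the goal — the U-conditioned mode to maximize the
   output, the L-conditioned mode to minimize it
   (`select_conditioning_set()`) — then re-sample the remaining
   parameters afresh and simulate the conditional output density
   (`conditional_analysis()`).

`run_cra()` chains the six steps and serializes samples, outputs,
MIRI tables, the conditioning set and summary statistics.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lower_factor`, `upper_factor` | 0.1, 10 | multiplicative bounds around each nominal value; the conventional two-orders-of-magnitude box |
| `N` | 10000 | Latin hypercube draws per realization |
| `alpha` | 0.1 | tail probability of L and U |
| `k` | 3 | conditioning-set size |
| `n_realizations` | study-dependent | independent sampling replicates for MIRI box statistics |

N and alpha are linked: each tail holds `alpha*N` samples and a
kernel density estimated from fewer than about 1000 points is not
trustworthy, so the package warns whenever `N < 1000/alpha`
(`check_n_alpha()`). The conditioning-set size k is a user choice —
inspect the MIRI spectrum for a gap; automated selection is out of
scope.

## Built-in models

**Pulse generator.** A two-state incoherent feedforward loop: the
input S1 (rectangular, 470 nM for 50 min) activates both the output Y
and a repressor R2 of Y, with Hill kinetics (exponents fixed at 3,
structural constants excluded from sampling). Six kinetic parameters
are sampled. Three readouts of Y are supported: area, maximum, and
time to first maximum. The simulation horizon defaults to 500 min:
at the nominal decay rate λ = 0.04/min the pulse is negligible long
before then, so the area readout is effectively horizon-independent,
while for the smallest sampled λ (0.004/min) a longer horizon would
still grow the area of slow-decaying samples; the horizon is
configurable, and tolerances on area-based conclusions should allow
for its effect at small λ.

**EGFR-IGF1R cascade.** Ten states: the receptor activities x1 (EGFR)
and x2 (IGF1R) decay from their initial values and drive
activation/deactivation cycles down the MAPK axis; states 3–10 obey
conservation laws (active + inactive = total), and the readout is the
area under active ERK (x7) over 30 min on a 1000-point grid. Two
quirks of the source equations are kept explicit rather than silently
repaired: the x3 balance removes flux through an unresolvable species
"x13" (exposed as the constant `x13_constant`, default 1), and the x5
balance removes flux at a rate driven by x7 instead of x5. The
verbatim x7-driven form is the default, with a switch to substitute
x5 for sensitivity checks. Canonical parameter values live in the
model's supplementary material and are user-supplied via
`load_parameter_table()`; the shipped placeholders (all ones) are
synthetic and support structural/directional analyses only.

Receptor abundance matters biologically, so the receptor initial
conditions x1(0), x2(0) can be appended to the sampling box
(`extend_with_initial_conditions()`), giving a 41-dimensional joint
space.

## Numerical choices

- **Integration**: `deSolve::lsoda` (stiff-capable, adaptive), rtol
  1e-6 / atol 1e-9, with the built-in models' right-hand sides
  compiled in C — a conditional robustness run costs one integration
  per draw, 10^4–10^5 in total, and the compiled path is ~15× faster
  than an R-level right-hand side. Piecewise-constant inputs are
  handled by restarting the integration at every switch time, so the
  solver never steps across a discontinuity.
- **Tail realization**: the probability-alpha tails are realized as
  empirical order statistics (the `round(alpha*N)` extreme samples),
  the consistent finite-sample estimator of the density-integral
  definition. Ties at a threshold resolve by ascending sample index —
  one deterministic, replayable rule that also keeps L and U disjoint
  for alpha ≤ 0.5.
- **KDE**: Gaussian kernels, Silverman's rule-of-thumb bandwidth on
  the conditioned subsample, floored at one grid cell so degenerate
  (zero-variance) inputs stay well-defined. Densities are evaluated
  on a 1024-point uniform grid spanning the parameter's *sampling
  bounds* (not the conditioned sample's range) so that U- and
  L-conditioned densities, and densities from different realizations,
  share a common grid; MIRI is then a plain trapezoidal quadrature.
  No boundary reflection is applied: kernel mass can leak past the
  box edges, so a conditioned density's grid integral may fall
  below 1 (it stays ≥ 0.95 in all tested non-pathological cases) and
  MIRI values near the theoretical maximum of 2 are reached only up
  to that leakage.
- **Positivity**: trajectory values within 1e-4 of zero *relative to
  the trajectory's state scale* are clamped to zero; anything more
  negative marks the sample as a failed integration. The clamp is
  relative, and far above atol = 1e-9, deliberately: lsoda controls
  local error, and near-zero sign overshoots of order rtol times the
  state scale are routine in switch-like cascades — flagging them as
  failures would discard healthy trajectories wholesale, while
  clipping them changes an area readout by a negligible fraction. In the EGFR model the
  verbatim x7-driven removal term in the x5 balance is gated by the
  smooth switch x5/(x5 + 1e-6·x5T): without it the term keeps draining
  x5 below zero and the resulting derivative discontinuity stalls the
  integrator; the gate only modifies the unphysical x5 ≤ 0 regime and
  keeps all states inside their conservation bounds.
- **Failure policy**: failed integrations are masked (the effective N
  is reported and used everywhere downstream); at 5% failures or more
  the batch aborts, since a box producing that many failures needs
  re-thinking, not silent pruning.
- **Tie-breaks**: `time_to_maximum` returns the first grid time
  achieving the maximum; density modes take the smallest grid argmax;
  MIRI ranking ties resolve by parameter declaration order.
- **Seeds**: every sampling call takes an explicit seed and restores
  the caller's RNG state; realization r of a replicated study uses
  `base_seed + r`, so any single realization can be replayed in
  isolation. Evaluation itself is deterministic, which is why results
  are bit-identical across worker counts.

## Design choices where the design was genuinely open

- Selection takes the *highest*-MIRI parameters: a large μ means the
  two output tails pull the parameter toward different regions, which
  is exactly the leverage a conditioning set needs. (Low-μ parameters
  are the robust directions — informative, but useless for
  conditioning.)
- Bound factors are constrained only by
  `0 < lower_factor < upper_factor`; the defaults (0.1, 10) give the
  conventional two-orders-of-magnitude box.
- For conditional re-analysis the free parameters are *re-sampled
  fresh* rather than filtered from the original sample set: filtering
  would leave only ~alpha·N rows and entangle the conditional density
  with the realization that selected K.
- Whether the MIRI integration grid should span the sampling bounds
  or the conditioned sample's range is not prescribed;
  bounds-spanning grids were chosen for cross-realization
  comparability.
- Multi-objective conditioning assigns each objective its top-MIRI
  parameter not already claimed by an earlier objective, visiting
  objectives in a user-controlled priority order (default:
  declaration order). The built-in examples have no conflicts; the
  rule matters only when two objectives elect the same parameter.
- Hill exponents of the pulse circuit are structural constants, not
  sampled: the sampled space is the six kinetic parameters.

## What the fixtures do and do not show

The closed-form fixtures (`make_identity_fixture()`,
`make_linear_fixture()`) drive every pipeline stage through maps with
known answers: for z = p1 on the unit box, the tail-conditioned
marginals of p1 are (asymptotically) disjoint uniforms — MIRI near 2 —
while inert parameters keep identical marginals — MIRI near 0; for
weighted sums, MIRI must order by |weight| and a negative weight must
swap the tails' modes. `gaussian_density_pair()` bypasses kernel
estimation entirely to test the MIRI quadrature against the
closed-form L1 distance of shifted normals,
2(2Φ(Δ/2σ) − 1). These fixtures validate the machinery, not the
biology: they are noise-free, monotone and low-dimensional, so
passing them says nothing about stiffness, multimodal conditional
densities, or parameter interactions in real cascades — that is what
the two ODE models probe.

## Problem sizes used in the shipped checks

The pulse-generator study conditions are N = 10000 draws at
alpha = 0.1 per realization; the package's replicated check uses
10 realizations and requires the expected top-parameter sets in at
least 8 of 10 — the ranking is stable enough that more replicates
only sharpen the box plots.
Fixture checks run at N = 2000–5000. The EGFR-IGF1R directional
checks run at N = 1500 with the synthetic placeholder kinetics, which
is ample for directional (mean/variance shrinkage) claims though the
package will warn that tail densities at that size are
rough.

## Known limitations

- Only scalar evaluation functions; multi-output readouts must be
  scalarized by the caller.
- The uniform prior is built in; other priors on the box would change
  both the robustness estimate and the conditional densities.
- Sobol/low-discrepancy sampling and optimized hypercubes are out of
  scope; so is the population-quartile alternative to the
  probability-tail partition, and Borgonovo's δ (which conditions on
  the parameter rather than the output tails).
- One-dimensional KDEs ignore dependence *between* parameters within
  a tail: a conditioning set built from marginal modes can be
  suboptimal when tail samples are strongly correlated across
  parameters.
- With `alpha = 0.5` and odd effective N, the two tails share the
  median sample count rule `round(0.5*N)`; they remain disjoint but
  not exhaustive.
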