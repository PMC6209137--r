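---
title: "Information-economic design of carbon labeling experiments"
author: "paretoMFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-economic design of carbon labeling experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretoMFA)
```

## The design problem

Steady-state ¹³C metabolic flux analysis (MFA) infers intracellular reaction
rates from the isotope labeling patterns that a ¹³C-enriched substrate
imprints on the metabolome. Before such a carbon labeling experiment (CLE)
is run, an investigator chooses a tracer mixture, an analytical platform, a
set of measurement groups and replicate counts. These choices drive both the
statistical quality of the flux estimates and the price of the experiment —
isotopically labeled substrates are expensive, and spectra need paid
analyst time. The two goals, *maximize flux information* and *minimize
cost*, are conflicting and not expressible in a common currency, so
`paretoMFA` treats experimental design as a multi-objective optimization
problem and approximates the set of Pareto-optimal designs: designs that
cannot be improved in any objective without losing in another.

The pipeline has five layers, each usable on its own:

1. **Network model** — atom-mapped stoichiometry, free-flux parametrization.
2. **Labeling simulator** — steady-state isotopomer fractions via the
   cumomer cascade, with flux sensitivities.
3. **Measurement and error model** — device observations η and their
   standard deviations σ.
4. **Information and cost criteria** — Fisher-information optimality
   scores after iterative freezing of non-identifiable fluxes, plus an
   itemized cost model.
5. **Pareto search and post-processing** — SMPSO with a bounded
   crowding-distance archive, exhaustive-grid oracle, clustering,
   robustness sampling and table exports.

## Flux model

A network is a set of metabolite pools (with carbon counts and roles:
balanced, input, or output) and reactions with per-carbon atom transitions
written as atom strings (`A#ab + B#c -> C#abc`). At metabolic steady state
the balanced pools satisfy `S v = b`; measured extracellular rates enter as
exact equality rows appended to `S` and inequality constraints and bounds
restrict the feasible flux space. Because networks contain parallel routes
and cycles, `v` is underdetermined: `stoichiometricAnalysis()` computes the
degrees of freedom `dim(v) − rank(S)` and a deterministic free-flux basis.
Dependent reactions are picked greedily in declaration order (a
caller-supplied preference list is tried last so that it stays free whenever
the algebra permits — the free-flux set is mathematically non-unique, and
naming it explicitly keeps results interpretable). Singular values below
1e−10 of the largest are treated as zero. Reversible reactions carry a
net/exchange pair; forward and backward rates derive as
`fwd = xch + max(net, 0)` and `bwd = xch + max(−net, 0)`, and every
exchange flux is an additional free coordinate.

Measured rates are treated as exact equalities; weighting them by their
uncertainty would require a joint estimation model that is outside this
package's scope.

## Labeling simulator

Given fluxes and a tracer mixture, the isotopomer distribution of every
balanced pool is the solution of a high-dimensional balance system that is
bilinear in the unknowns wherever two labeled educts condense. The package
uses the *cumomer* decomposition: the cumulative fraction of molecules
labeled at a carbon subset of weight w obeys a linear system whose
right-hand side involves only lower-weight cumomers and input patterns, so
the full solution is a cascade of small linear solves, one per weight
level. Cumomers were chosen over the (often faster) EMU decomposition
because measurement groups are expressed here as arbitrary nonnegative rows
over full isotopomer space — including joint precursor/fragment indicators
of tandem MS — which cumomer states support exactly; an EMU backend would
be an optimization, not a change in semantics.

Numerical conventions:

* Isotopomer vectors are indexed by bitmask + 1 (bit *i*−1 set ⇔ carbon *i*
  labeled); the Möbius transform converts between cumomer and isotopomer
  coordinates.
* A tracer of purity *q* contributes label probability *q* at its nominally
  labeled positions and 0 elsewhere; natural ¹³C abundance is not modelled.
  The built-in fixtures use purity 1 for labeled species so their
  hand-derived oracle values are exact; realistic purities (e.g. 0.99) are
  fully supported.
* A balanced pool with zero total outflux makes its level system singular;
  this is reported as a degeneracy error naming the pool.
* Reversible reactions with zero exchange simply contribute a zero backward
  rate — they behave as irreversible at that design point.

Sensitivities ∂η/∂v_free are computed by central finite differences of the
entire prediction pipeline with step `h = 1e−6·max(1, |v_i|)`; normalized
groups are therefore differentiated *after* normalization. At constraint
boundaries (e.g. an exchange flux at 0) differencing falls back to
one-sided with a warning. The test suite checks the finite differences
against step-halving (Richardson) and against closed forms, and checks the
whole simulator against an independent brute-force isotopomer solver on
every fixture.

## Measurements and errors

A measurement group is a nonnegative linear map over one pool's isotopomer
coordinates, acquired and (optionally) normalized jointly — mass isotopomer
distributions, tandem-MS precursor/fragment pairs, positional NMR
enrichments, or a single IRMS total-enrichment row
(`makeDeviceTemplates()`). Standard deviations follow the linear device
model `σ = a(n_rep)·(b1·η + b2)` with diagonal covariance `σ²`; `b2 > 0`
keeps every σ positive. The replicate scaling defaults to
`a(n) = sqrt(n/(n−1))` for n ≥ 2 with `a(1) = 2`: it is ≥ 1, non-increasing
and tends to 1 for many repetitions, reflecting that error estimates (not
the errors themselves) become trustworthy with replication. It is
configurable per device; the desk-scale fixtures use `a ≡ 1` so that their
closed-form flux standard deviations are exact.

## Information criteria and freezing

The Fisher information matrix is `FIM = Jᵀ Σ⁻¹ J` (sensitivities weighted
by inverse measurement variances) and the flux covariance is its inverse.
Inversion is only meaningful when the FIM's smallest eigenvalue exceeds
`τ1` — interpreted relative to the largest eigenvalue, default 1e−9 — and
its condition number stays below `τ2` (default 1e12). When a design fails
these conditions, fluxes are frozen one at a time starting from the worst
determined (largest diagonal of the FIM pseudo-inverse), until the retained
block passes; a column whose largest sensitivity falls below 1e−6 is
treated as unobserved outright, since central differences at step 1e−6
cannot distinguish it from zero. The retained dimension *p* is itself a
design objective.

The scalar criteria on the retained covariance are

* `Φ_D = det(Cov)^(1/(2p))` — the geometric mean of the flux standard
  deviations (a *p*-independent length scale of the confidence ellipsoid),
* `Φ_A = trace(Cov)/p` — the mean flux variance,
* `Φ_E = λ_max/λ_min` — the ellipsoid conditioning,
* `Φ_DoF = p`.

All three dispersion criteria are "smaller is better"; reported
*information values* are their reciprocals so that larger numbers mean more
informative designs, which is also the orientation the optimizer maximizes.
Criteria are only comparable across designs at equal *p*; archives carry
*p* explicitly and the analysis layer filters to a single *p* (by default
the maximum) before clustering.

## Cost model

Per experiment: substrate cost `mass·(x_inpᵀ·prices)` (default 5 g, from a
250 mL culture at 20 g/L) plus a fixed setup cost and wages for setup and
control; per device: acquisition (`n_samples·C_sample`, instrument
depreciation folded into the per-sample price) plus peak evaluation
(replicate-weighted peak count × time per peak × wage). Replicate counts
are bounded by the `n_samples` taken per experiment (default 10).
Unevaluated groups cost nothing. Costs are affine in mixture fractions and
non-decreasing in every replicate count and price — both are property
tests. The default price table spans the printed bounds for glucose
tracers (0.30 EUR/g unlabeled to 1293.00 EUR/g for the most expensive
singly labeled species); intermediate prices are plausible placeholders
and fully overridable, as real quotes vary by vendor and date.

## Design space and search

A design is, per parallel experiment, a tracer-fraction block and a
replicate count per measurement group; group inclusion is simply
`n_rep ≥ 1`. The search operates on a relaxed continuous vector and repairs
every candidate before evaluation: fractions are renormalized onto the
simplex (an all-zero block becomes the uniform mixture), replicates are
rounded to the nearest integer. Objectives are computed on the *rounded*
design, so every archive entry is an executable protocol. A degenerate
design (no evaluated measurements, or a labeling solver failure) is scored
with `Φ_DoF = 0`, zero information and its actual cost, so the swarm keeps
it and dominance removes it naturally.

The optimizer is a speed-constrained multi-objective particle swarm
(SMPSO): velocity constriction from acceleration coefficients drawn in
[1.5, 2.5], inertia 0.1, velocities clamped to half the variable range,
boundary handling by clipping with velocity reversal, polynomial mutation
(distribution index 20) on 15% of particles, leaders drawn by binary
crowding-distance tournament from a bounded external archive (defaults:
swarm 100, 250 iterations, archive 100). All randomness flows from one
seeded generator, so runs are bitwise reproducible. Crowding truncation
keeps boundary points (infinite distance) and drops the most crowded
interior point; because a *bounded* archive can shed a sliver of dominated
area when an interior point is truncated, the logged hypervolume is
monotone only up to that sliver — the test suite asserts exactly that.
`exhaustiveFront()` enumerates a discretized design space (guarded at 1e6
points) as an exact oracle; on grid-restricted problems the seeded swarm is
required to recover ≥ 90% of the exact front.

## Post-processing

* **Clustering**: designs (filtered to one *p*) are described by
  [composition fractions; D-information; total cost], each min-max scaled
  to [0, 1] — the features have incommensurable units, so equal scaling is
  the neutral choice — and clustered hierarchically with Euclidean
  distance and average linkage; compositions below 1% are suppressed in
  display summaries.
* **Robustness**: flux vectors are sampled uniformly in the axis-aligned
  bounding box of the confidence ellipsoid (half-widths `1.96·sqrt(diag
  Cov)` by default; the confidence level of the box is a user choice),
  infeasible draws are rejected, and the D-information of the design is
  recomputed at each sample with the retained free-flux set held fixed so
  the values stay comparable.
* **Exports**: front table with cost breakdown, chord-diagram link tables
  (objectives min-max scaled to 0–100%, species under 1% omitted),
  per-species mixture histograms (5% bins), per-group replicate histograms,
  and ternary coordinates when exactly three species are active. Chord and
  ternary diagrams themselves are drawn by external circular-plot tools;
  this package emits their input tables.

## Fixtures and what the tests show

Three deterministic desk-scale fixtures drive the test suite
(`makeFixture()`): a linear **chain** (labeling is flux-independent, so all
sensitivities vanish), a **branch** with an order-preserving and a
carbon-swapping route (the split ratio is read directly by positional NMR,
`η = r1`, but is invisible to mass isotopomer distributions), and a
**cycle** whose reversible back-exchange scrambles C1/C2 (the exchange flux
is identifiable from positional data under an informative tracer, and
frozen under uniform labeling). These reproduce, in miniature, the
qualitative positional-versus-mass information contrast between analytical
platforms. Every hand-derived fixture value ships in an expected-values
ledger that the suite re-verifies against the live implementation, and the
cumomer solver is checked against a brute-force isotopomer solver on all
fixtures (≤ 12 total carbons).

What passing tests do *not* show: fixture networks are orders of magnitude
smaller than genome-informed models (tens of pools, hundreds of reactions),
tracers are idealized at purity 1, natural abundance and measurement bias
are absent, and error-model coefficients are stylized constants. Results on
real models inherit none of these simplifications automatically; the input
schema supports full-scale atom-mapped models, tracers with realistic
purities, and literature-derived error coefficients as configuration.

Problem sizes in the shipped tests and acceptance script are chosen at desk
scale — swarms of 30–40 particles over 40–60 iterations, grids of a few
hundred designs, robustness samples of 10³–10⁴ — which keeps the full suite
in the low tens of seconds while still exercising every code path; the
defaults (`swarmParams()`) are sized for real studies.

## Known limitations

* Isotopically non-stationary (time-resolved) labeling is out of scope.
* Carbon-carrying metabolites must appear once per reaction side with unit
  coefficient (per-copy atom maps for stoichiometric duplicates are not
  supported); carbon-free cofactors are unrestricted.
* Measurement groups address a single pool; cross-pool linear combinations
  are not supported.
* The analytic implicit-differentiation Jacobian is not implemented; the
  finite-difference path is the reference implementation.
* Natural ¹³C abundance and spectral corrections are deliberately absent:
  simulated observations mimic corrected, percentage-scale measurements.
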