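---
title: "A stochastic individual-based model of tumour-immune coevolution under T-cell therapy"
author: "immunoSSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic individual-based model of tumour-immune coevolution under T-cell therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(immunoSSA)
```

## The model

immunoSSA simulates a continuous-time Markov jump process on a finite trait
space with three actor classes: cancer cells carrying a (genotype,
phenotype) pair, T-cells, and cytokine molecules. A population of size
order `K` (the carrying capacity) is represented by raw individual counts;
the scaled measure assigns each individual weight `1/K`, so interaction
terms are read off densities `n/K`.

Per-capita transition rates for a cancer cell of phenotype `p`:

* birth at `max(0, b(p) - sum_q c_b(p,q) nu(q))`: competition acts first by
  *reducing the birth rate* (kernel `c_b`); once the birth rate is floored
  at zero, the excess acts as an additional death rate;
* death at `d(p) + sum_q c(p,q) nu(q)` plus the therapy pressure
  `sum_z t_kill(p,z) nu(z)`; a therapy kill releases a deterministic burst
  of cytokines;
* phenotype switch to `q` (same genotype, no division required) at
  `s_nat(p,q) + sum_w s_cyt(w,p,q) nu(w)` — the cytokine-induced part
  models TNF-driven dedifferentiation;
* with probability `mu(g)` a birth is a mutation drawn from the mutation
  law `m_law` (zero diagonal, rows summing to one).

T-cells reproduce at `b_T(z) + sum_p t_prod(z,p) nu(p)` (each reproduction
also releases cytokines) and die at an *effective* rate `d_T(z)` that
absorbs exhaustion; cytokines decay at `d_W(w)`. Interaction sums exclude
the focal individual's own `1/K` contribution — a convention that matters
only at order `1/K` but must be fixed for small-population tests to be
exact.

Simulation is an exact Gillespie algorithm: every jump is generated, with
exponential waiting times and rate-proportional channel choice. The
compiled engine and a pure-R reference engine consume the RNG stream
identically, and the test suite checks they produce bit-identical
trajectories under a shared seed. Rates are rebuilt after every event;
with at most a dozen traits this costs microseconds and avoids any
approximation.

## The deterministic limit

As `K` grows the scaled process converges to a quadratic ODE system
(`vectorField()`, `integrateODE()`): logistic self-limitation, a
predator–prey coupling between T-cells and their target phenotype, switch
flows, and bilinear cytokine production. It is not a generalised
Lotka–Volterra system: the birth-rate floor makes the field only piecewise
quadratic, and the suite verifies exact degree-2 polynomial structure away
from the floor. Mutations with probabilities that vanish as `K` grows are
invisible in this limit, so the mutation terms are off by default.

`findFixedPoints()` enumerates support patterns (each trait forced to zero
or left free), seeds a damped Newton iteration from fixed density levels
and from endpoints of the support-clamped flow, keeps solutions whose full
field (including influx into the zeroed coordinates) vanishes below
`1e-9`, and classifies them by the spectrum of a central-difference
Jacobian. Stability can be assessed in the full space or restricted to the
support's invariant subspace — the distinction the therapy analysis turns
on: the tumour-only state is attracting inside the no-T-cell hyperplane
yet unstable in the full space. Points sitting exactly on the birth-rate
floor are flagged and reported as marginal rather than silently
classified; the field is non-smooth there.

## Invasion fitness of a switching mutant

A rare mutant genotype with `k` phenotypes against a resident equilibrium
is approximated, until it dies out or reaches size `eps K`, by a
multi-type branching process with mean dynamics `dn/dt = A n`
(`meanMatrix()`). Diagonal entries are per-phenotype net growth rates in
the resident background; off-diagonal entries are switch rates (column
feeds row). The largest eigenvalue `lambda1` generalises scalar invasion
fitness: an outgoing switch is a loss for a phenotype but not for the
genotype, so the clone can grow even when every phenotype declines in
isolation. When the switch graph is irreducible the normalized leading
right eigenvector `v` is strictly positive and gives the phenotype
composition of a surviving clone; `invasionMCOracle()` checks both claims
by exact simulation with the resident frozen at its equilibrium counts
(the object the branching approximation describes — mutant offspring that
mutate out of the genotype are lost to the clone).

## Birth-reducing competition and mutation timing

With pure birth-reducing competition the total mutation rate at size `n`
is `mu n max(0, b - c_b n/K)`: a quadratic with maximum at
`n* = bK/(2 c_b)`, while the equilibrium sits at
`n_bar = (b-d)K/(c + c_b)`. For `c = 0` the equilibrium rate is submaximal
exactly when `d < b/2`: a large tumour at equilibrium sees fewer births —
hence fewer mutation opportunities — than a smaller one regrowing through
`n*`. The package verifies the closed forms on a parameter grid and
demonstrates the stochastic counterpart by comparing cumulative mutation
events between a regrowing and an equilibrated population of matched
duration (`brcMutationStudy()`).

## Built-in scenarios and what the calibration means

All fixture parameter sets are synthetic: they are this package's own
calibration, not measured rates. Two groups exist.

The *qualitative* scenarios (`one_tcell_qualitative`,
`two_tcell_qualitative`, `K = 200`) use fast, order-one rates chosen so the
deterministic phase portrait has the structure the therapy analysis needs —
extinction state, tumour-only state (stable only inside its hyperplane),
and an interior state that is the unique fully stable point; adding a
second T-cell specificity adds an interior point for the enlarged system
and a point without the first T-cell type, and destabilizes the old
interior. At `K = 200` the T-cell trough after the initial tumour crash is
a handful of individuals, so ensembles split between T-cell survival and
fluctuation-driven T-cell extinction — the two characteristic stochastic
behaviours — with the split frequency set by `K` (the
fluctuation-amplitude parameter).

The *calibrated* ACT scenario (`act_calibrated`, nominal `K = 1e5`)
reproduces three printed timings of the melanoma adoptive-transfer
experiments it emulates: differentiated relapses regrow to the
pre-treatment size about 90 days after tumour initiation, dedifferentiated
relapses about 190 days, and the tumour stays microscopic (below 1% of its
pre-treatment count, roughly the sub-millimetre detection scale on the
diameter read-out) for about 50 days. The calibration was done against
the deterministic limit and then tuned at `K = 1e3` — the size used by the
timing studies, where a replicate costs a couple of seconds — exploiting
that both relapse clocks are governed by near-deterministic growth phases
and are insensitive to `K`. Structurally: differentiated cells divide
every 1–2 days with net growth 0.5/day; dedifferentiated cells are
near-quiescent escape variants (net growth 0.056/day, very low turnover,
so that the few founder cells seeded during the kill phase survive);
T-cells are homeostatic (`b_T = d_T = 1`), so after clearing their target
they form a critical birth-death population whose stochastic extinction
time — median around day 75 — decides the relapse mode, mirroring the
role exhaustion plays in the experiments. The tumour-size read-out maps
counts to the diameter of an equivalent sphere
(`diameterFromCount()`, `cells_per_mm3 = 4300` so the pre-treatment tumour
is about 7 mm at the nominal `K`).

What passing the timing checks shows — and what it does not: the model
reproduces the remission/relapse kinetics and their stochastic dichotomy
under the stated conditions; it says nothing about spatial structure,
explicit re-stimulation, or other immune actors, all deliberately outside
the model (exhaustion is folded into the effective T-cell death rate).

The `mutant_invasion` scenario provides a resident at equilibrium plus a
two-phenotype mutant whose phenotypes both decline in isolation while the
genotype's `lambda1` is positive; `brc_mutation` provides the pure
birth-reducing regime with `d < b/2`.

## Numerical choices

* SSA: full channel rebuild per event; channel ties at cumulative-sum
  boundaries resolved in canonical trait order; replicate `i` of an
  ensemble uses seed `base_seed + i`.
* ODE: `lsoda` with `rtol 1e-8`, `atol 1e-10`, densities clipped at zero.
* Fixed points: residual tolerance `1e-9`, deduplication distance `1e-6`,
  Newton damping by step halving (at most 40 halvings, 60 iterations).
* Eigenproblems are dense (`k <= ~6`); the leading eigenvalue must be real
  to `1e-10` or the computation aborts rather than silently proceeding.
* Study sizes: timing study 50 replicates at `K = 1e3`; extinction oracle
  `1e4` runs; law-of-large-numbers ladder `K = 1e2, 1e3, 1e4` with 40, 16
  and 6 replicates; invasion Monte-Carlo 300 runs per instance; closure
  ensembles 200 seeds. These give comfortable margins for the 3-standard-
  error checks while keeping a full run in minutes on one CPU.

## Known limitations

* No spatial structure or microenvironment; rates are effective,
  well-mixed quantities.
* The finite-`K` basin-of-attraction probabilities after a mutant reaches
  `eps K` are not computed analytically; the package only offers
  deterministic continuation from user-chosen initial conditions, because
  with multiple attractors the outcome is genuinely random at finite `K`.
* A fixed point lying exactly on the birth-rate floor boundary is reported
  marginal; no centre-manifold analysis is attempted there.
* The remission/relapse thresholds (1% microscopic, 90% regrowth) are
  config keys with defaults chosen on the diameter scale of the emulated
  experiments; classification is state-based and invariant under
  trajectory thinning, but the absolute remission duration depends on the
  microscopic threshold chosen.
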