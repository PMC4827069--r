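# immunoSSA

Stochastic individual-based modelling of tumour–immune coevolution under
adoptive T-cell transfer (ACT) therapy.

## The problem

Melanomas under ACT therapy escape treatment not only by genetic mutation
but by reversible, TNF-α-driven *phenotype switching*: T-cells kill
differentiated melanoma cells, the inflammation they cause pushes surviving
cells into a dedifferentiated state the T-cells no longer recognise, and the
tumour relapses. Deterministic models miss the essential part of this story:
during remission both the tumour and the T-cell population consist of a
handful of cells, and pure chance — does the T-cell population survive its
trough? — decides between qualitatively different outcomes.

immunoSSA implements an exact stochastic individual-based model for this
system, for modellers and quantitative biologists studying therapy
resistance. Cancer cells carry a genotype and a switchable phenotype;
T-cells kill their target phenotype and release cytokine bursts; cytokines
enhance switching; competition can reduce birth rates as well as increase
death rates (birth-reducing competition, `c_b`); rare mutations move cells
between genotypes. The population is a continuous-time Markov jump process
with carrying-capacity scaling `K`; each individual carries weight `1/K` in
the scaled measure.

Around the simulation core the package provides:

* **Exact Gillespie simulation** (`simulateSSA()`): compiled engine plus a
  pure-R reference engine that consumes the RNG stream identically
  (bit-identical trajectories under a shared seed), injection schedules,
  frozen-trait mode, threshold stop rules.
* **The deterministic large-K limit** (`vectorField()`, `integrateODE()`,
  `findFixedPoints()`, `classifyStability()`): a quadratic ODE system with
  fixed-point location by support-pattern enumeration and linear stability
  in the full space or restricted to invariant subspaces.
* **Invasion fitness of switching mutants** (`meanMatrix()`,
  `invasionFitness()`, `invasionMCOracle()`): the mean matrix `A` of the
  multi-type branching process that approximates a rare mutant clone;
  its largest eigenvalue `lambda1` generalises invasion fitness, its
  leading eigenvector `v` gives the phenotype composition of surviving
  clones — a genotype can invade even when every phenotype declines in
  isolation, because an outgoing switch is a loss for a phenotype but not
  for the genotype.
* **Mutation timing under birth-reducing competition**
  (`brcMutationCurve()`): the total mutation rate
  `mu·n·max(0, b − c_b n/K)` is quadratic in `n` and maximal at
  `n* = bK/(2c_b)`; when `d < b/2` a tumour *shrunk by therapy and
  regrowing* mutates faster than one sitting at its equilibrium.
* **A therapy laboratory** (`Scenario()`, `runEnsemble()`,
  `classifyOutcome()`, `diameterFromCount()`, `builtinScenarios()`):
  replicated ensembles with per-run outcome classification (cure,
  differentiated/dedifferentiated relapse, coexistence, T-cell
  extinctions), Wilson confidence intervals, and a mm-diameter read-out.

## Worked example

One-specificity therapy, qualitative regime (`K = 200`): three deterministic
fixed points, and a stochastic dichotomy between T-cell survival and
fluctuation-driven T-cell extinction.

```r
library(immunoSSA)

sc <- builtinScenario("one_tcell_qualitative")
fps <- findFixedPoints(sc@params)
for (fp in fps) print(fp)
#> P_0.0.0.0 ( unstable )  residual 0
#>  x  y zx  w
#>  0  0  0  0
#> max Re(eigenvalue): 2
#> P_x.y.0.0 ( unstable )  residual 1.28e-12
#>        x        y       zx        w
#> 1.538462 1.538462 0.000000 0.000000
#> max Re(eigenvalue): 6.69231
#> P_x.y.zx.w ( stable )  residual 2.5e-16
#>        x        y       zx        w
#> 0.200000 1.915761 0.072873 0.065585
#> max Re(eigenvalue): -0.434011
```

The origin and the tumour-only state are unstable in the full space (the
tumour-only state is stable *inside* the no-T-cell hyperplane — exactly
where stochastic runs land when the T-cells die out); the interior state,
with the differentiated tumour held low by the T-cells, is the only stable
point. A 50-replicate ensemble splits between the two behaviours:

```r
sc@replicates <- 50
runEnsemble(sc)
#> OutcomeTable (one_tcell_qualitative) : 50 replicate(s)
#>             label count frequency  ci_lower  ci_upper
#>       coexistence    33      0.66 0.5215383 0.7756305
#>  tcell_zx_extinct    17      0.34 0.2243695 0.4784617
```

Runs in which the T-cells die out (`tcell_zx_extinct`) regrow a
differentiated tumour towards the tumour-only state; runs in which they
survive sit near the interior point (`coexistence`, with the
dedifferentiated phenotype dominating the tumour). The calibrated scenario
(`act_calibrated`, `K = 1e5` nominal)
reproduces the timing of the emulated experiments — differentiated relapses
regain the pre-treatment size about 90 days after tumour initiation,
dedifferentiated ones about 190 days, with a roughly 50-day microscopic
remission — and `relapseTimingStudy()` recomputes those numbers at `K = 1e3`
in a couple of minutes.

Invasion fitness of a switching mutant against a resident at equilibrium:

```r
pars <- builtinScenario("mutant_invasion")@params
resident <- c(p = 2)          # resident equilibrium density
inv <- invasionFitness(meanMatrix(resident, "gm", pars))
inv
#> InvasionResult for genotype gm
#>   lambda1 = 0.1106736 (supercritical)
#>   proportions v: p1=0.5846, p2=0.4154
```

Both mutant phenotypes have negative growth rates on their own (the
diagonal of `A` is negative), yet `lambda1 > 0`: the clone invades through
the switch cycle, and surviving clones arrive at size `εK` in roughly these
proportions.

## Command line

A thin CLI wraps the same functions (installed under `exec/`):

```sh
immunossa simulate    --config model.yaml --seed 1 --out-dir out/
immunossa ode         --config model.yaml --out-dir out/
immunossa fixedpoints --config model.yaml --out-dir out/
immunossa fitness     --config model.yaml --out-dir out/   # run.mutant_genotype
immunossa ensemble    --config model.yaml --replicates 200 --out-dir out/
immunossa brc         --config model.yaml --out-dir out/   # run.brc block
```

Configs are YAML with sections `space`, `cancer`, `tcells`, `cytokines`,
`K`, `init`, `run`; `writeConfig(builtinScenario("one_tcell_qualitative"),
"model.yaml")` writes a complete example of the dialect.
Identical config + seed gives byte-identical outputs; every run writes a
`manifest.json` listing its outputs and the config hash.

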