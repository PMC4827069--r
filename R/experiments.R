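# Reusable study functions: each runs one of the package's standard
# computational experiments end-to-end and returns plain summaries. The
# acceptance script and the test suite are thin wrappers around these.

#' Relapse-timing study on the calibrated ACT scenario
#'
#' Runs the calibrated single-specificity therapy ensemble, classifies every
#' replicate, and summarises the two relapse classes: runs in which the
#' T-cells die out regrow as differentiated tumours (fast), runs in which
#' they survive relapse later as dedifferentiated tumours. Relapse times are
#' days after tumour initiation; remission is the longest contiguous period
#' with the total tumour below the scenario's microscopic threshold.
#'
#' @param K carrying capacity (the timing is governed by the
#'   near-deterministic growth phases and is insensitive to K; smaller K
#'   runs faster but fluctuates more).
#' @param replicates ensemble size.
#' @param baseSeed RNG base seed.
#' @return list with `t_diff` (median differentiated relapse time, days),
#'   `t_dediff` (median dedifferentiated relapse time), `t_remission`
#'   (median remission duration over relapse runs), `table` (the
#'   [OutcomeTable-class]), and class counts.
#' @export
relapseTimingStudy <- function(K = 1000, replicates = 50, baseSeed = 1) {
  sc <- builtinScenario("act_calibrated", K = K)
  sc@replicates <- replicates
  sc@baseSeed <- baseSeed
  tab <- runEnsemble(sc)
  per <- perReplicate(tab)
  dd <- per[per$label == "relapse_differentiated", ]
  ud <- per[per$label == "relapse_dedifferentiated", ]
  rel <- per[per$label %in% c("relapse_differentiated", "relapse_dedifferentiated"), ]
  list(
    t_diff = stats::median(dd$relapse_time),
    t_dediff = stats::median(ud$relapse_time),
    t_remission = stats::median(rel$remission_duration, na.rm = TRUE),
    n_diff = nrow(dd), n_dediff = nrow(ud),
    n_cure = sum(per$label == "cure"),
    table = tab
  )
}

#' Extinction-probability oracle for the single-type branching process
#'
#' A single type with constant birth and death rates and no competition is a
#' linear birth-death process: starting from n0 individuals the extinction
#' probability is (d/b)^n0. The study estimates it by direct simulation
#' (extinction before reaching a large escape threshold) and returns the
#' closed-form value alongside.
#'
#' @param b,d per-capita birth and death rates (b > d).
#' @param n0 initial individuals.
#' @param nRuns Monte-Carlo replicates.
#' @param seed base seed.
#' @param escape count at which a run is deemed to have escaped extinction.
#' @return list with `estimate`, `expected` = (d/b)^n0, `se` (binomial).
#' @export
extinctionProbabilityStudy <- function(b = 2, d = 1, n0 = 3, nRuns = 1e4,
                                       seed = 1, escape = 500) {
  pars <- ModelParams(TraitSpace("g", list(g = "p")), K = 1,
                      cancer = list(b = c(p = b), d = c(p = d)))
  sp <- pars@space
  ext <- logical(nRuns)
  for (i in seq_len(nRuns)) {
    tr <- simulateSSA(populationState(sp, c(p = n0)), pars, tMax = 1e6,
                      seed = seed + i, recordDt = 1e6,
                      thresholdTraits = "p", thresholdCount = escape)
    ext[i] <- stopReason(tr) %in% c("all_extinct", "group_extinct")
  }
  p <- mean(ext)
  list(estimate = p, expected = (d / b)^n0,
       se = sqrt(p * (1 - p) / nRuns), nRuns = nRuns)
}

#' Law-of-large-numbers convergence study
#'
#' For the qualitative one-specificity scenario, measures the supremum over
#' a fixed time grid of the distance between the scaled stochastic
#' trajectory and the deterministic limit, averaged over runs in which the
#' T-cells do not die out, for a ladder of carrying capacities. The mean
#' deviation decreases as K grows (fluctuations scale like 1/sqrt(K)).
#'
#' @param Ks increasing carrying capacities.
#' @param tMax,dt time grid.
#' @param repsPerK replicates per K (recycled to length of Ks).
#' @param baseSeed RNG base seed.
#' @return data.frame with K, meanSupDev, nUsed (non-extinct runs).
#' @export
llnConvergenceStudy <- function(Ks = c(100, 1000, 10000), tMax = 15,
                                dt = 0.5, repsPerK = c(40, 16, 6),
                                baseSeed = 1) {
  repsPerK <- rep(repsPerK, length.out = length(Ks))
  tGrid <- seq(0, tMax, by = dt)
  out <- data.frame(K = Ks, meanSupDev = NA_real_, nUsed = 0L)
  for (j in seq_along(Ks)) {
    K <- Ks[j]
    sc <- builtinScenario("one_tcell_qualitative", K = K)
    pars <- sc@params
    x0 <- sc@initialCounts / K
    ode <- integrateODE(x0, pars, tGrid)
    odeM <- as.matrix(ode[match(tGrid, ode$time), traitNames(pars@space)])
    devs <- c()
    for (i in seq_len(repsPerK[j])) {
      tr <- simulateSSA(populationState(pars@space, sc@initialCounts), pars,
                        tMax = tMax, seed = baseSeed + 1000 * j + i,
                        recordDt = dt)
      if (finalCounts(tr)["zx"] == 0) next   # fluctuation-driven extinction
      X <- scaledCounts(tr)
      rows <- match(tGrid, trajTimes(tr))
      if (any(is.na(rows))) next
      devs <- c(devs, max(abs(X[rows, ] - odeM)))
    }
    out$meanSupDev[j] <- mean(devs)
    out$nUsed[j] <- length(devs)
  }
  out
}

#' T-cell extinction frequency as a function of K
#'
#' The amplitude of stochastic fluctuations is set by K: with a small
#' carrying capacity the T-cell population passes through a low minimum and
#' dies out far more often than with a large one.
#'
#' @param Ks carrying capacities to compare.
#' @param reps replicates per K.
#' @param tMax horizon (days).
#' @param baseSeed base seed.
#' @return data.frame with K, extinctionFreq.
#' @export
tcellExtinctionStudy <- function(Ks = c(100, 10000), reps = c(40, 10),
                                 tMax = 40, baseSeed = 1) {
  reps <- rep(reps, length.out = length(Ks))
  out <- data.frame(K = Ks, extinctionFreq = NA_real_)
  for (j in seq_along(Ks)) {
    sc <- builtinScenario("one_tcell_qualitative", K = Ks[j])
    ext <- 0
    for (i in seq_len(reps[j])) {
      tr <- simulateSSA(populationState(sc@params@space, sc@initialCounts),
                        sc@params, tMax = tMax,
                        seed = baseSeed + 131 * j + i, recordDt = tMax)
      ext <- ext + (finalCounts(tr)["zx"] == 0)
    }
    out$extinctionFreq[j] <- ext / reps[j]
  }
  out
}

#' Invasion sign-law study
#'
#' Over a set of mutant parameterizations (one to three phenotypes) against
#' a single-type resident at equilibrium, compares the branching-process
#' invasion fitness lambda1 with the Monte-Carlo survival frequency of the
#' resident-frozen clone: clearly supercritical clones (lambda1 > 0.1)
#' invade with frequency above 5%, clearly subcritical ones
#' (lambda1 < -0.1) below 1%. For surviving supercritical clones the
#' phenotype composition at the threshold is compared with the normalized
#' leading eigenvector.
#'
#' @param K carrying capacity for the Monte-Carlo companion.
#' @param epsilon threshold fraction.
#' @param nRuns Monte-Carlo replicates per instance.
#' @param seed base seed.
#' @return list: `instances` data.frame (k, lambda1, survival, se) and
#'   `composition` data.frame (phenotype, v, empirical, se) for the
#'   supercritical multi-phenotype instance.
#' @export
invasionSignLawStudy <- function(K = 1e4, epsilon = 0.05, nRuns = 300,
                                 seed = 1) {
  mk <- function(bMut, dMut, cMutRes, sw = NULL) {
    k <- length(bMut)
    phen <- paste0("q", seq_len(k))
    sp <- TraitSpace(c("g", "gm"), list(g = "p", gm = phen))
    cmat <- matrix(0, k + 1, k + 1, dimnames = list(c("p", phen), c("p", phen)))
    cmat["p", "p"] <- 1
    for (i in seq_len(k)) cmat[phen[i], "p"] <- cMutRes[i]
    snat <- matrix(0, k + 1, k + 1, dimnames = dimnames(cmat))
    if (k > 1 && !is.null(sw)) {
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i != j) snat[phen[i], phen[j]] <- sw[i, j]
      }
    }
    ModelParams(sp, K = K, cancer = list(
      b = stats::setNames(c(3, bMut), c("p", phen)),
      d = stats::setNames(c(1, dMut), c("p", phen)),
      c = cmat, s_nat = snat
    ))
  }
  # resident equilibrium density (b - d) / c = 2
  instances <- list(
    list(tag = "k1_super", pars = mk(4, 1, 1.2)),            # 4-1-2.4 = +0.6
    list(tag = "k1_sub", pars = mk(2.2, 1, 0.75)),           # 2.2-1-1.5 = -0.3
    list(tag = "k2_super", pars = mk(c(4.2, 1.6), c(1, 1), c(1.2, 0.2),
                                     matrix(c(0, 1, 0.5, 0), 2, 2, byrow = TRUE))),
    list(tag = "k2_sub", pars = mk(c(2.4, 1.4), c(1, 1), c(0.8, 0.5),
                                   matrix(c(0, 0.6, 0.6, 0), 2, 2, byrow = TRUE))),
    list(tag = "k3_rescue", pars = mk(c(3.4, 1.2, 1.1), c(1, 1, 1),
                                      c(0.95, 0.2, 0.2),
                                      matrix(c(0, 1.2, 0.3,
                                               0.8, 0, 0.2,
                                               0.3, 0.2, 0), 3, 3, byrow = TRUE)))
  )
  rows <- list()
  compo <- NULL
  for (ii in seq_along(instances)) {
    inst <- instances[[ii]]
    pars <- inst$pars
    nms <- traitNames(pars@space)
    resident <- stats::setNames(c(2, rep(0, length(nms) - 1)), nms)
    inv <- invasionFitness(meanMatrix(resident, "gm", pars))
    mc <- invasionMCOracle(resident, "gm", pars, epsilon = epsilon,
                           nRuns = nRuns, seed = seed + 977 * ii)
    rows[[ii]] <- data.frame(
      tag = inst$tag, k = length(inv@v), lambda1 = inv@lambda1,
      survival = mc$survival, se = mc$se, nSurvived = mc$nSurvived,
      stringsAsFactors = FALSE
    )
    if (inst$tag == "k2_super") {
      compo <- data.frame(
        phenotype = names(inv@v), v = as.numeric(inv@v),
        empirical = as.numeric(mc$proportions),
        se = as.numeric(mc$propSE), stringsAsFactors = FALSE
      )
    }
  }
  # the scalar reduction is exact for k = 1
  k1 <- instances[[1]]$pars
  nms <- traitNames(k1@space)
  inv1 <- invasionFitness(meanMatrix(
    stats::setNames(c(2, 0), nms), "gm", k1))
  exact1 <- 4 - 1 - 1.2 * 2
  list(instances = do.call(rbind, rows), composition = compo,
       k1_lambda1 = inv1@lambda1, k1_exact = exact1)
}

#' Birth-reducing-competition mutation study
#'
#' Verifies the closed forms n* = bK/(2 c_b), n-bar = (b-d)K/(c+c_b) and
#' the submaximality criterion d < b/2 over a parameter grid, and measures
#' by simulation that a population regrowing through n* accumulates more
#' mutation events than an equilibrium population over the same duration.
#'
#' @param K carrying capacity of the simulated comparison.
#' @param nrep replicate pairs for the simulated comparison.
#' @param seed base seed.
#' @return list: `grid` (data.frame of analytic checks), `growth_mutations`,
#'   `equilibrium_mutations` (mean cumulative mutation events).
#' @export
brcMutationStudy <- function(K = 1000, nrep = 30, seed = 1) {
  grid <- expand.grid(b = c(1, 2, 3), d = c(0.2, 0.5, 1.2), c_b = c(0.5, 1, 2))
  grid <- grid[grid$b > grid$d, ]
  grid$n_star <- NA_real_
  grid$n_bar <- NA_real_
  grid$submax <- NA
  for (i in seq_len(nrow(grid))) {
    cv <- brcMutationCurve(b = grid$b[i], d = grid$d[i], c = 0,
                           c_b = grid$c_b[i], mu = 1e-3, K = K)
    grid$n_star[i] <- cv$n_star
    grid$n_bar[i] <- cv$n_bar
    grid$submax[i] <- cv$submaximal_at_equilibrium
  }
  grid$n_star_ok <- abs(grid$n_star - grid$b * K / (2 * grid$c_b)) < 1e-9
  grid$n_bar_ok <- abs(grid$n_bar - (grid$b - grid$d) * K / grid$c_b) < 1e-9
  grid$criterion_ok <- grid$submax == (grid$d < grid$b / 2)

  sp <- TraitSpace(c("g0", "gmut"), list(g0 = "p", gmut = "pm"))
  pars <- ModelParams(sp, K = K, cancer = list(
    b = c(p = 2, pm = 3), d = c(p = 0.5, pm = 0.5),
    c_b = list(p = list(p = 1, pm = 1), pm = list(p = 1, pm = 1)),
    mu = c(g0 = 0.02, gmut = 0), m_law = list(p = list(pm = 1))
  ))
  nbar <- (2 - 0.5) * K
  growM <- eqM <- numeric(nrep)
  for (i in seq_len(nrep)) {
    g <- simulateSSA(populationState(sp, c(p = round(0.8 * K))), pars,
                     tMax = 3, seed = seed + i, recordDt = 3, frozen = "pm")
    e <- simulateSSA(populationState(sp, c(p = nbar)), pars, tMax = 3,
                     seed = seed + 5000 + i, recordDt = 3, frozen = "pm")
    growM[i] <- unname(eventCounts(g)["mutant_birth"])
    eqM[i] <- unname(eventCounts(e)["mutant_birth"])
  }
  list(grid = grid, growth_mutations = mean(growM),
       equilibrium_mutations = mean(eqM))
}

#' Outcome-set closure study
#'
#' Runs large ensembles of the qualitative one- and two-specificity
#' scenarios and tabulates the outcome labels; every run falls in the
#' closed scenario set (cure, the two relapse subtypes, coexistence, and
#' T-cell-extinction states).
#'
#' @param replicates seeds per scenario.
#' @param tMax horizon (days).
#' @param baseSeed base seed.
#' @return list of named label-count tables, one per scenario.
#' @export
outcomeClosureStudy <- function(replicates = 200, tMax = 100, baseSeed = 1) {
  out <- list()
  for (nm in c("one_tcell_qualitative", "two_tcell_qualitative")) {
    sc <- builtinScenario(nm)
    sc@replicates <- replicates
    sc@tMax <- tMax
    sc@baseSeed <- baseSeed
    tab <- runEnsemble(sc)
    out[[nm]] <- table(perReplicate(tab)$label)
  }
  out
}
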