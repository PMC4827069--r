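# Built-in fixture scenarios. All parameter values are synthetic: they were
# calibrated within this package (see the methods vignette) to reproduce the
# qualitative regimes of melanoma ACT therapy -- phenotype switching under
# TNF-alpha, T-cell predation with cytokine bursts, remission/relapse
# kinetics -- and, for the calibrated ACT scenario, the reported timing of
# differentiated (~90 d) and dedifferentiated (~190 d) relapses and a 50-60
# day remission.

oneTcellSpace <- function(twoTcells = FALSE) {
  TraitSpace(
    genotypes = "mel",
    phenotypesOf = list(mel = c("x", "y")),   # x differentiated, y dedifferentiated
    tcellTypes = if (twoTcells) c("zx", "zy") else "zx",
    cytokineTypes = "w"                        # TNF-alpha
  )
}

qualitativeParams <- function(twoTcells = FALSE, K = 200) {
  sp <- oneTcellSpace(twoTcells)
  tk <- list(x = list(zx = 20))
  kb <- list(x = list(zx = list(w = 2)))
  tp <- list(zx = list(x = 5))
  bT <- list(zx = 0); dT <- list(zx = 1); rb <- list(zx = list(w = 1))
  if (twoTcells) {
    tk$y <- list(zy = 20)
    kb$y <- list(zy = list(w = 2))
    tp$zy <- list(y = 5)
    bT$zy <- 0; dT$zy <- 1; rb$zy <- list(w = 1)
  }
  ModelParams(
    space = sp, K = K,
    cancer = list(
      b = c(x = 3, y = 3), d = c(x = 1, y = 1),
      c = matrix(c(1, 0.3, 0.3, 1), 2, 2, byrow = TRUE,
                 dimnames = list(c("x", "y"), c("x", "y"))),
      t_kill = tk, kill_burst = kb,
      s_nat = list(x = list(y = 0.05), y = list(x = 0.05)),
      s_cyt = list(w = list(x = list(y = 3))),
      mu = c(mel = 0)
    ),
    tcells = list(b_T = bT, d_T = dT, t_prod = tp, rep_burst = rb),
    cytokines = list(d_W = 10)
  )
}

# Calibrated ACT regime. Differentiated cells (x) divide fast and are the
# T-cell target; dedifferentiated cells (y) are slow-cycling, near-quiescent
# escape variants, strongly suppressed by the bulk tumour before therapy and
# seeded during the kill phase by TNF-driven switching. T-cells are
# homeostatic (b_T = d_T): after clearing their target they persist as a
# critical population whose stochastic extinction time decides between the
# two relapse modes. Densities are in units of K; the pre-treatment tumour
# sits near 7.8 K cells.
actCalibratedParams <- function(twoTcells = FALSE, K = 1e5) {
  sp <- oneTcellSpace(twoTcells)
  r_y <- 0.056
  tk <- list(x = list(zx = 100))
  kb <- list(x = list(zx = list(w = 2)))
  tp <- list(zx = list(x = 0.025))
  bT <- list(zx = 1); dT <- list(zx = 1); rb <- list(zx = list(w = 1))
  if (twoTcells) {
    tk$y <- list(zy = 100)
    kb$y <- list(zy = list(w = 2))
    tp$zy <- list(y = 0.025)
    bT$zy <- 1; dT$zy <- 1; rb$zy <- list(w = 1)
  }
  ModelParams(
    space = sp, K = K,
    cancer = list(
      b = c(x = 0.75, y = 0.01 + r_y + 0.03), d = c(x = 0.25, y = 0.01),
      c = matrix(c(0.0625, 0.04375, 0.125, r_y / 8), 2, 2, byrow = TRUE,
                 dimnames = list(c("x", "y"), c("x", "y"))),
      t_kill = tk, kill_burst = kb,
      s_nat = list(x = list(y = 1.5e-4), y = list(x = 0.03)),
      s_cyt = list(w = list(x = list(y = 8e-4))),
      mu = c(mel = 0)
    ),
    tcells = list(b_T = bT, d_T = dT, t_prod = tp, rep_burst = rb),
    cytokines = list(d_W = 10)
  )
}

#' Built-in fixture scenarios
#'
#' Named, validated parameter sets covering the regimes the model is built
#' to explore. All numbers are this package's own calibration (synthetic),
#' chosen to reproduce the qualitative phenomenology and, for the calibrated
#' ACT scenarios, the timing targets documented in the methods vignette.
#'
#' \describe{
#'   \item{one_tcell_qualitative}{ACT with one T-cell specificity (kills the
#'     differentiated phenotype x only), K = 200. Three deterministic fixed
#'     points: extinction, tumour-only, and an interior point; the T-cell
#'     minimum during remission is low, so stochastic runs split between
#'     T-cell survival and T-cell extinction followed by differentiated
#'     regrowth.}
#'   \item{two_tcell_qualitative}{adds a second specificity zy attacking the
#'     dedifferentiated phenotype; five stochastic scenarios including cure.}
#'   \item{act_calibrated}{quantitatively calibrated single-specificity
#'     regime, K = 1e5 by default: tumour initiated at day 0, T-cell dose at
#'     day 16; differentiated relapses regain the pre-treatment size about
#'     90 days after initiation, dedifferentiated ones about 190 days, with
#'     remission at microscopic size for 50-60 days.}
#'   \item{act_two_calibrated}{the calibrated regime with both
#'     specificities; cure is the modal outcome.}
#'   \item{mutant_invasion}{a resident single-phenotype tumour at
#'     equilibrium plus a two-phenotype mutant genotype whose phenotypes
#'     both have negative per-phenotype growth but positive genotype-level
#'     invasion fitness through asymmetric switching.}
#'   \item{brc_mutation}{a single tumour type under pure birth-reducing
#'     competition (c = 0) able to mutate to a fitter genotype; the total
#'     mutation rate is quadratic in the population size and submaximal at
#'     equilibrium since d < b/2.}
#' }
#'
#' @param K optional carrying-capacity override applied to every returned
#'   scenario (initial counts and doses scale with K).
#' @return named list of [Scenario-class] objects, all passing
#'   [validateParameters()].
#' @export
builtinScenarios <- function(K = NULL) {
  out <- list()

  mkQual <- function(two) {
    KK <- if (is.null(K)) 200 else K
    pars <- qualitativeParams(two, K = KK)
    init <- c(x = round(1.5 * KK), zx = round(0.1 * KK))
    if (two) init <- c(init, zy = round(0.1 * KK))
    Scenario(
      params = pars, initialCounts = init, tMax = 100,
      replicates = 50, baseSeed = 1,
      meta = list(
        name = if (two) "two_tcell_qualitative" else "one_tcell_qualitative",
        diffPhenotypes = "x", recordDt = 0.25,
        description = paste0("qualitative ACT, ", if (two) "two" else "one",
                             " T-cell specificit", if (two) "ies" else "y")
      )
    )
  }
  out$one_tcell_qualitative <- mkQual(FALSE)
  out$two_tcell_qualitative <- mkQual(TRUE)

  mkCal <- function(two) {
    KK <- if (is.null(K)) 1e5 else K
    pars <- actCalibratedParams(two, K = KK)
    sched <- data.frame(time = 16, trait = "zx", count = round(0.052 * KK),
                        stringsAsFactors = FALSE)
    if (two) {
      sched <- rbind(sched,
                     data.frame(time = 16, trait = "zy", count = round(0.052 * KK),
                                stringsAsFactors = FALSE))
    }
    Scenario(
      params = pars,
      initialCounts = c(x = round(0.6 * KK)),
      schedule = sched, tMax = 300, replicates = 50, baseSeed = 1,
      meta = list(
        name = if (two) "act_two_calibrated" else "act_calibrated",
        diffPhenotypes = "x", recordDt = 0.5,
        cellsPerMm3 = 4300,
        description = paste0("calibrated ACT therapy, ",
                             if (two) "two specificities" else "one specificity")
      )
    )
  }
  out$act_calibrated <- mkCal(FALSE)
  out$act_two_calibrated <- mkCal(TRUE)

  # resident tumour at equilibrium + two-phenotype mutant genotype
  KK <- if (is.null(K)) 1e4 else K
  spInv <- TraitSpace(
    genotypes = c("g", "gm"),
    phenotypesOf = list(g = "p", gm = c("p1", "p2"))
  )
  parsInv <- ModelParams(
    space = spInv, K = KK,
    cancer = list(
      b = c(p = 3, p1 = 4, p2 = 1),
      d = c(p = 1, p1 = 1, p2 = 1),
      c = list(p = list(p = 1, p1 = 1, p2 = 1),
               p1 = list(p = 1.05, p1 = 1, p2 = 1),
               p2 = list(p = 0.5, p1 = 1, p2 = 1)),
      s_nat = list(p1 = list(p2 = 1.5), p2 = list(p1 = 1)),
      mu = c(g = 1e-3, gm = 0),
      m_law = list(p = list(p1 = 0.5, p2 = 0.5))
    )
  )
  out$mutant_invasion <- Scenario(
    params = parsInv, initialCounts = c(p = 2 * KK), tMax = 100,
    replicates = 50, baseSeed = 1,
    meta = list(name = "mutant_invasion", mutantGenotype = "gm",
                description = "rare mutant with switching phenotypes vs resident at equilibrium")
  )

  # pure birth-reducing competition with a fitter mutant target
  KB <- if (is.null(K)) 1000 else K
  spBrc <- TraitSpace(
    genotypes = c("g0", "gmut"),
    phenotypesOf = list(g0 = "p", gmut = "pm")
  )
  parsBrc <- ModelParams(
    space = spBrc, K = KB,
    cancer = list(
      b = c(p = 2, pm = 3),
      d = c(p = 0.5, pm = 0.5),
      c_b = list(p = list(p = 1, pm = 1), pm = list(p = 1, pm = 1)),
      mu = c(g0 = 1e-3, gmut = 0),
      m_law = list(p = list(pm = 1))
    )
  )
  out$brc_mutation <- Scenario(
    params = parsBrc, initialCounts = c(p = round(0.05 * KB)), tMax = 40,
    replicates = 50, baseSeed = 1,
    meta = list(name = "brc_mutation", mutantGenotype = "gmut",
                brc = list(b = 2, d = 0.5, c = 0, c_b = 1, mu = 1e-3),
                description = "quadratic total mutation rate under pure birth-reducing competition")
  )
  out
}

#' Fetch a single built-in scenario by name
#' @param name scenario name (see [builtinScenarios()]).
#' @param K optional carrying-capacity override.
#' @return a [Scenario-class].
#' @export
builtinScenario <- function(name, K = NULL) {
  sc <- builtinScenarios(K = K)
  if (!name %in% names(sc)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(sc), collapse = ", "))
  }
  sc[[name]]
}
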