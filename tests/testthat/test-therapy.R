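# Build a Trajectory by hand: counts rows on a time grid.
mkTraj <- function(times, counts, K = 100, stopReason = "t_max") {
  new("Trajectory", times = times, counts = counts,
      cumMutations = numeric(length(times)), K = K, seed = 1,
      stopReason = stopReason, paramsHash = "deadbeef",
      eventCounts = stats::setNames(numeric(10), immunoSSA:::kindNames))
}

qualPars <- builtinScenario("one_tcell_qualitative")@params

test_that("cure, relapse subtypes and degenerate runs are classified", {
  nms <- traitNames(qualPars@space)  # x y zx w
  tt <- seq(0, 100, 5)
  n <- length(tt)

  # cure: tumour hits zero, T-cells and cytokines decay afterwards
  X <- matrix(0, n, 4, dimnames = list(NULL, nms))
  X[, "x"] <- round(pmax(0, 1000 - 120 * tt))
  X[, "zx"] <- round(c(rep(50, 10), 50 * exp(-0.5 * (tt[11:n] - tt[10]))))
  oc <- classifyOutcome(mkTraj(tt, X), qualPars, diffPhenotypes = "x")
  expect_equal(oc$label, "cure")
  expect_false(is.na(oc$cureTime))

  # differentiated relapse: zx dies, x regrows past 90% of its start
  X2 <- matrix(0, n, 4, dimnames = list(NULL, nms))
  X2[, "x"] <- round(pmin(1000, c(1000 * exp(-0.8 * tt[1:8]),
                                  3 * exp(0.25 * (tt[9:n] - tt[8])))))
  X2[, "y"] <- round(2 * exp(0.02 * tt))
  X2[, "zx"] <- round(c(50, 80, 40, 20, 8, 3, 1, rep(0, n - 7)))
  oc2 <- classifyOutcome(mkTraj(tt, X2), qualPars, diffPhenotypes = "x")
  expect_equal(oc2$label, "relapse_differentiated")
  expect_gt(oc2$diffFracAtRelapse, 0.5)
  expect_false(is.na(oc2$tcellExtinctions["zx"]))
  expect_false(is.na(oc2$remissionDuration))

  # dedifferentiated relapse: zx survives, y regrows
  X3 <- X2
  X3[, "zx"] <- 30
  X3[, "x"] <- round(1000 * exp(-0.8 * tt))
  X3[, "y"] <- round(pmin(1100, 2 * exp(0.12 * tt)))
  oc3 <- classifyOutcome(mkTraj(tt, X3), qualPars, diffPhenotypes = "x")
  expect_equal(oc3$label, "relapse_dedifferentiated")
  expect_lt(oc3$diffFracAtRelapse, 0.5)

  # flat all-zero trajectory is a (degenerate) cure
  X0 <- matrix(0, n, 4, dimnames = list(NULL, nms))
  oc0 <- classifyOutcome(mkTraj(tt, X0), qualPars, diffPhenotypes = "x")
  expect_equal(oc0$label, "cure")

  # everything alive at horizon, tumour controlled: coexistence
  X4 <- matrix(5, n, 4, dimnames = list(NULL, nms))
  X4[, "x"] <- 100
  X4[1, "x"] <- 1000
  oc4 <- classifyOutcome(mkTraj(tt, X4), qualPars, diffPhenotypes = "x")
  expect_equal(oc4$label, "coexistence")
})

test_that("classification is invariant under uniform time-thinning", {
  sc <- builtinScenario("one_tcell_qualitative")
  tr <- simulateSSA(populationState(sc@params@space, sc@initialCounts),
                    sc@params, tMax = 80, seed = 11, recordDt = 0.25)
  thin <- function(traj, k) {
    keep <- seq(1, length(traj@times), by = k)
    if (!length(traj@times) %in% keep) keep <- c(keep, length(traj@times))
    new("Trajectory", times = traj@times[keep],
        counts = traj@counts[keep, , drop = FALSE],
        cumMutations = traj@cumMutations[keep], K = traj@K, seed = traj@seed,
        stopReason = traj@stopReason, paramsHash = traj@paramsHash,
        eventCounts = traj@eventCounts)
  }
  oc1 <- classifyOutcome(tr, sc@params, diffPhenotypes = "x")
  oc4 <- classifyOutcome(thin(tr, 4), sc@params, diffPhenotypes = "x")
  expect_equal(oc1$label, oc4$label)
  if (!is.na(oc1$relapseTime)) {
    expect_lt(abs(oc1$relapseTime - oc4$relapseTime), 1.01)
  }
})

test_that("ensembles are deterministic given the base seed", {
  sc <- builtinScenario("one_tcell_qualitative")
  sc@replicates <- 6
  sc@tMax <- 30
  t1 <- runEnsemble(sc)
  t2 <- runEnsemble(sc)
  expect_identical(perReplicate(t1), perReplicate(t2))
  expect_identical(outcomeFrequencies(t1), outcomeFrequencies(t2))
  expect_equal(sum(outcomeFrequencies(t1)$frequency), 1)

  sc@replicates <- 0
  empty <- runEnsemble(sc)
  expect_equal(nrow(perReplicate(empty)), 0)
})

test_that("outcome frequencies carry Wilson intervals containing the estimate", {
  sc <- builtinScenario("one_tcell_qualitative")
  sc@replicates <- 8
  sc@tMax <- 40
  agg <- outcomeFrequencies(runEnsemble(sc))
  expect_true(all(agg$ci_lower <= agg$frequency + 1e-12))
  expect_true(all(agg$ci_upper >= agg$frequency - 1e-12))
  expect_true(all(agg$ci_lower >= 0 & agg$ci_upper <= 1))
})

test_that("tumour diameter read-out is a calibrated sphere", {
  expect_equal(diameterFromCount(0), 0)
  N0 <- 12345
  expect_equal(diameterFromCount(8 * N0), 2 * diameterFromCount(N0))
  expect_error(diameterFromCount(-1), "non-negative")
  # monotone
  N <- seq(0, 1e6, length.out = 50)
  expect_true(all(diff(diameterFromCount(N)) > 0))
  # inverse round-trip
  expect_equal(countFromDiameter(diameterFromCount(5e5, 1114), 1114), 5e5)
  # the calibrated scenario maps its pre-treatment count near the
  # experimentally reported pre-treatment diameter scale (a few mm), and a
  # tumour regrown to the same count maps back to the same diameter
  sc <- builtinScenario("act_calibrated")
  pre <- sum(sc@initialCounts)
  calib <- sc@meta$cellsPerMm3
  d1 <- diameterFromCount(pre, calib)
  expect_equal(diameterFromCount(pre, calib), d1)
})

test_that("larger initial T-cell doses deepen the tumour minimum", {
  # deterministic dose-response: more injected T-cells push the
  # differentiated tumour through a strictly lower minimum
  pars <- builtinScenario("one_tcell_qualitative")@params
  xmin <- vapply(c(0.05, 0.1, 0.3, 1.0), function(dose) {
    min(integrateODE(c(x = 1.5, zx = dose), pars, seq(0, 60, 0.1))$x)
  }, numeric(1))
  expect_true(all(diff(xmin) < 0))
})

test_that("fluctuation amplitude: small K makes T-cell extinction more likely", {
  # K sets the fluctuation amplitude, hence the probability that the T-cell
  # population dies out during its trough
  ext <- tcellExtinctionStudy(Ks = c(100, 10000), reps = c(30, 8), tMax = 40,
                              baseSeed = 1)
  expect_gt(ext$extinctionFreq[ext$K == 100],
            ext$extinctionFreq[ext$K == 10000])
})
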