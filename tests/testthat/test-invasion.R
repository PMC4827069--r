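test_that("mean matrix reduces to scalar net growth for one phenotype", {
  # empty resident
  pars <- residentMutantModel(bMut = 2, dMut = 1, cMutRes = 0, sw = NULL,
                              mu = 0.1)
  empty <- stats::setNames(rep(0, nTraits(pars@space)), traitNames(pars@space))
  M <- meanMatrix(empty, "gm", pars)
  expect_equal(dim(M@A), c(1L, 1L))
  muEff <- 0.1 * 0   # mu belongs to genotype g, not gm
  expect_equal(M@A[1, 1], 2 * (1 - 0) - 1)

  # against a resident at density 2: standard invasion fitness recovered
  pars2 <- residentMutantModel(bMut = 4, dMut = 1, cMutRes = 1.2, sw = NULL)
  res <- c(p = (3 - 1) / 1)
  M2 <- meanMatrix(res, "gm", pars2)
  expect_equal(M2@A[1, 1], 4 - 1 - 1.2 * 2)
  inv2 <- invasionFitness(M2)
  expect_identical(inv2@lambda1, M2@A[1, 1])
  expect_equal(unname(inv2@v), 1)

  # resident containing the mutant is rejected
  expect_error(meanMatrix(c(p = 2, q1 = 0.1), "gm", pars2), "mutant")
})

test_that("symmetric two-phenotype clone has lambda1 = r and v = (1/2, 1/2)", {
  r <- 0.7; sig <- 1.3
  # diagonals r - sig after subtracting outgoing switch, off-diagonals sig
  pars <- residentMutantModel(bMut = c(1 + r, 1 + r), dMut = c(1, 1),
                              cMutRes = c(0, 0),
                              sw = matrix(c(0, sig, sig, 0), 2, 2))
  M <- meanMatrix(stats::setNames(rep(0, 3), traitNames(pars@space)), "gm", pars)
  expect_equal(M@A, matrix(c(r - sig, sig, sig, r - sig), 2, 2,
                           dimnames = dimnames(M@A)))
  inv <- invasionFitness(M)
  expect_equal(inv@lambda1, r, tolerance = 1e-12)
  expect_equal(unname(inv@v), c(0.5, 0.5), tolerance = 1e-12)
  expect_true(inv@irreducible)
  expect_true(inv@supercritical)
})

test_that("asymmetric switching can rescue phenotypes that decline alone", {
  # closed-form 2x2: A = [[-a, s],[s', -a']] with lambda1 =
  # -(a+a')/2 + sqrt(((a-a')/2)^2 + s s'); positive iff s s' > a a'
  a <- 0.6; ap <- 2; s12 <- 1.5; s21 <- 1
  # build via rates: diag = r_i - outgoing switch
  pars <- residentMutantModel(
    bMut = c(1 + (s12 - a), 1 + (s21 - ap)), dMut = c(1, 1), cMutRes = c(0, 0),
    sw = matrix(c(0, s12, s21, 0), 2, 2, byrow = TRUE)
  )
  M <- meanMatrix(stats::setNames(rep(0, 3), traitNames(pars@space)), "gm", pars)
  expect_equal(unname(diag(M@A)), c(-a, -ap))
  expect_true(all(diag(M@A) < 0))
  inv <- invasionFitness(M)
  lamExact <- -(a + ap) / 2 + sqrt(((a - ap) / 2)^2 + s12 * s21)
  expect_equal(inv@lambda1, lamExact, tolerance = 1e-12)
  expect_gt(inv@lambda1, 0)    # s12 * s21 = 1.5 > a * a' = 1.2
  expect_true(all(inv@v > 0))  # Perron vector strictly positive
})

test_that("reducible switch graphs are flagged", {
  pars <- residentMutantModel(bMut = c(2, 1.5), dMut = c(1, 1),
                              cMutRes = c(0, 0),
                              sw = matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE))
  M <- meanMatrix(stats::setNames(rep(0, 3), traitNames(pars@space)), "gm", pars)
  inv <- invasionFitness(M)
  expect_false(inv@irreducible)
})

test_that("Monte-Carlo invasion survival matches the birth-death oracle", {
  # k = 1 supercritical: survival from one individual = 1 - d_eff/b_eff
  pars <- residentMutantModel(bMut = 2, dMut = 1, cMutRes = 0.25, K = 2000)
  res <- c(p = 2)
  M <- meanMatrix(res, "gm", pars)
  bEff <- 2
  dEff <- 1 + 0.25 * 2
  expect_equal(M@A[1, 1], bEff - dEff)
  mc <- invasionMCOracle(res, "gm", pars, epsilon = 0.05, nRuns = 800,
                         seed = 100)
  pSurv <- 1 - dEff / bEff
  expect_lt(abs(mc$survival - pSurv), 3 * sqrt(pSurv * (1 - pSurv) / 800) + 0.01)

  # subcritical: survival to epsilon*K is (nearly) impossible
  parsSub <- residentMutantModel(bMut = 1, dMut = 1.3, cMutRes = 0, K = 2000)
  mcSub <- invasionMCOracle(stats::setNames(c(2, 0), c("p", "q1")), "gm",
                            parsSub, epsilon = 0.05, nRuns = 400, seed = 50)
  expect_lt(mcSub$survival, 0.01)
})

test_that("surviving clones reach epsilon*K with proportions v", {
  sig <- 1.2
  pars <- residentMutantModel(bMut = c(2.2, 1.4), dMut = c(1, 1),
                              cMutRes = c(0, 0), K = 4000,
                              sw = matrix(c(0, sig, 0.4, 0), 2, 2, byrow = TRUE))
  empty <- stats::setNames(rep(0, 3), traitNames(pars@space))
  inv <- invasionFitness(meanMatrix(empty, "gm", pars))
  expect_gt(inv@lambda1, 0)
  mc <- invasionMCOracle(empty, "gm", pars, epsilon = 0.05, nRuns = 300,
                         seed = 77)
  expect_gt(mc$nSurvived, 30)
  for (ph in names(inv@v)) {
    tol <- 3 * mc$propSE[ph] + 0.02
    expect_lt(abs(mc$proportions[ph] - inv@v[ph]), tol)
  }
})

test_that("BRC mutation-rate curve: maximum, equilibrium and criterion", {
  cv <- brcMutationCurve(b = 2, d = 0.5, c = 0, c_b = 1, mu = 1e-3, K = 1000)
  expect_equal(cv$n_bar, 1500)
  expect_equal(cv$n_star, 1000)
  expect_true(cv$submaximal_at_equilibrium)   # d = 0.5 < b/2 = 1
  expect_equal(cv$rate_at(0), 0)
  # quadratic: rate(n) = mu n (b - c_b n / K) below the floor
  n <- c(100, 700, 1500)
  expect_equal(cv$rate_at(n), 1e-3 * n * (2 - n / 1000))
  # argmax by direct numerical maximization
  opt <- optimize(cv$rate_at, c(0, 2000), maximum = TRUE)
  expect_equal(opt$maximum, cv$n_star, tolerance = 1e-4)
  expect_gt(cv$rate_at(cv$n_star), cv$rate_at(cv$n_bar))

  # boundary d = b/2: equilibrium sits exactly at the maximum
  cv2 <- brcMutationCurve(b = 2, d = 1, c = 0, c_b = 1, mu = 1e-3, K = 1000)
  expect_equal(cv2$n_bar, cv2$n_star)
  expect_false(cv2$submaximal_at_equilibrium)

  # d > b/2: equilibrium below the argmax, flag false
  cv3 <- brcMutationCurve(b = 2, d = 1.4, c = 0, c_b = 1, mu = 1e-3, K = 1000)
  expect_lt(cv3$n_bar, cv3$n_star)
  expect_false(cv3$submaximal_at_equilibrium)
  expect_lt(cv3$rate_at(cv3$n_bar), cv3$rate_at(cv3$n_star))

  expect_error(brcMutationCurve(b = 1, d = 1.5, c = 0, c_b = 1, mu = 0, K = 10),
               "b > d")
})

test_that("a tumour regrowing after therapy mutates faster than at equilibrium", {
  # pure BRC with d < b/2: the total mutation rate mu n (b - c_b n/K) peaks
  # at n* = bK/2 below the equilibrium n_bar, so a population regrowing
  # through n* accumulates more mutation events than one sitting at n_bar
  # for the same duration. Mutant offspring are frozen out so the resident
  # dynamics stay pure.
  sp <- TraitSpace(c("g0", "gmut"), list(g0 = "p", gmut = "pm"))
  K <- 1000
  pars <- ModelParams(sp, K = K, cancer = list(
    b = c(p = 2, pm = 3), d = c(p = 0.5, pm = 0.5),
    c_b = list(p = list(p = 1, pm = 1), pm = list(p = 1, pm = 1)),
    mu = c(g0 = 0.02, gmut = 0),
    m_law = list(p = list(pm = 1))
  ))
  nbar <- (2 - 0.5) * K   # / (c + c_b) with c = 0, c_b = 1
  dur <- 3
  nrep <- 30
  growM <- eqM <- numeric(nrep)
  for (i in seq_len(nrep)) {
    g <- simulateSSA(populationState(sp, c(p = 800)), pars, tMax = dur,
                     seed = 400 + i, recordDt = dur, frozen = "pm")
    e <- simulateSSA(populationState(sp, c(p = nbar)), pars, tMax = dur,
                     seed = 800 + i, recordDt = dur, frozen = "pm")
    growM[i] <- unname(eventCounts(g)["mutant_birth"])
    eqM[i] <- unname(eventCounts(e)["mutant_birth"])
  }
  expect_gt(mean(growM), mean(eqM))
})
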