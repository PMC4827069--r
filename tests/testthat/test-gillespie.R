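test_that("effective cancer rates implement the birth-rate floor", {
  sp <- TraitSpace("g", list(g = c("p", "q")))
  mk <- function(cb_pq) {
    ModelParams(sp, K = 100, cancer = list(
      b = c(p = 3, q = 1), d = c(p = 1, q = 1),
      c_b = list(p = list(q = cb_pq))
    ))
  }
  # S_b = c_b(p,q) * nu(q) = cb_pq * 100/100
  st <- populationState(sp, c(p = 1, q = 100))
  r1 <- effectiveCancerRates(st, mk(1), "p")
  expect_equal(r1$B_eff, 2)
  expect_equal(r1$D_extra_brc, 0)
  # floor: excess birth reduction becomes additional death
  r2 <- effectiveCancerRates(st, mk(4), "p")
  expect_equal(r2$B_eff, 0)
  expect_equal(r2$D_extra_brc, 1)
  expect_equal(r2$B_eff * r2$D_extra_brc, 0)

  # lone cell: all interaction sums empty (self excluded)
  lone <- populationState(sp, c(p = 1))
  r3 <- effectiveCancerRates(lone, mk(4), "p")
  expect_equal(r3$B_eff, 3)
  expect_equal(r3$D_comp, 0)
  expect_equal(r3$D_therapy, 0)
})

test_that("self-interaction is excluded from competition sums", {
  sp <- TraitSpace("g", list(g = "p"))
  p <- ModelParams(sp, K = 10, cancer = list(
    b = c(p = 2), d = c(p = 1),
    c = matrix(5, 1, 1, dimnames = list("p", "p"))
  ))
  st1 <- populationState(sp, c(p = 1))
  expect_equal(effectiveCancerRates(st1, p, "p")$D_comp, 0)
  st2 <- populationState(sp, c(p = 2))
  expect_equal(effectiveCancerRates(st2, p, "p")$D_comp, 5 * 1 / 10)
})

test_that("switch rate combines natural and cytokine-induced parts", {
  sp <- TraitSpace("g", list(g = c("p", "q")), cytokineTypes = "w")
  p <- ModelParams(sp, K = 100, cancer = list(
    b = c(p = 1, q = 1),
    s_nat = list(p = list(q = 0.3)),
    s_cyt = list(w = list(p = list(q = 2)))
  ), cytokines = list(d_W = 1))
  expect_equal(switchRate(populationState(sp, c(p = 1)), p, "p", "q"), 0.3)
  expect_equal(switchRate(populationState(sp, c(p = 1, w = 100)), p, "p", "q"),
               0.3 + 2)
  # no natural switching and no cytokines: rate is zero (switching
  # requires the cytokine signal)
  p0 <- ModelParams(sp, K = 100, cancer = list(
    b = c(p = 1, q = 1), s_cyt = list(w = list(p = list(q = 2)))
  ), cytokines = list(d_W = 1))
  expect_equal(switchRate(populationState(sp, c(p = 5)), p0, "p", "q"), 0)

  sp2 <- TraitSpace(c("g1", "g2"), list(g1 = "p", g2 = "q"))
  p2 <- ModelParams(sp2, K = 10, cancer = list(b = c(p = 1, q = 1)))
  expect_error(switchRate(populationState(sp2, c(p = 1)), p2, "p", "q"),
               "genotype")
})

test_that("channel enumeration covers exactly the possible events", {
  sp <- TraitSpace("g", list(g = "p"))
  p <- singleTypeModel(b = 2, d = 1, K = 100)
  empty <- buildChannels(populationState(sp), p)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "total"), 0)

  one <- buildChannels(populationState(sp, c(p = 1)), p)
  expect_equal(nrow(one), 2)
  expect_setequal(one$kind, c("cancer_birth", "cancer_death_natural"))
  expect_equal(attr(one, "total"), 2 + 1)

  # T-cell birth channel grows in presence of prey
  spz <- TraitSpace("g", list(g = "p"), tcellTypes = "z")
  pz <- ModelParams(spz, K = 100, cancer = list(b = c(p = 1), d = c(p = 1)),
                    tcells = list(b_T = c(z = 0.5), d_T = c(z = 1),
                                  t_prod = list(z = list(p = 4))))
  ch <- buildChannels(populationState(spz, c(p = 50, z = 10)), pz)
  tb <- ch[ch$kind == "tcell_birth", ]
  expect_equal(tb$rate, 10 * (0.5 + 4 * 50 / 100))
})

test_that("event application follows the documented increments", {
  sp <- TraitSpace("g", list(g = c("p", "q")), tcellTypes = "z",
                   cytokineTypes = "w")
  p <- ModelParams(sp, K = 100, cancer = list(
    b = c(p = 2, q = 1), d = c(p = 1, q = 1),
    t_kill = list(p = list(z = 3)),
    kill_burst = list(p = list(z = list(w = 2))),
    s_nat = list(p = list(q = 0.5), q = list(p = 0.5))
  ), tcells = list(d_T = c(z = 1)), cytokines = list(d_W = 5))
  st <- populationState(sp, c(p = 10, q = 2, z = 4, w = 1))

  kill <- data.frame(kind = "cancer_death_therapy", actor = "p", target = "z")
  out <- applyEvent(st, kill, p)
  expect_equal(unname(stateCounts(out)[c("p", "w")]), c(9, 3))

  set.seed(1)
  birth <- data.frame(kind = "cancer_birth", actor = "p", target = NA)
  out2 <- applyEvent(st, birth, p)   # mu = 0: clonal copy
  expect_equal(unname(stateCounts(out2)["p"]), 11)

  sw <- data.frame(kind = "cancer_switch", actor = "p", target = "q")
  out3 <- applyEvent(st, sw, p)
  expect_equal(unname(stateCounts(out3)[c("p", "q")]), c(9, 3))
  expect_equal(sum(stateCounts(out3)[c("p", "q")]),
               sum(stateCounts(st)[c("p", "q")]))

  bad <- data.frame(kind = "tcell_death", actor = "z", target = NA)
  st0 <- populationState(sp, c(p = 1))
  expect_error(applyEvent(st0, bad, p), "count 0")
})

test_that("drawEvent samples channels in proportion to their rates", {
  ch <- data.frame(kind = c("a", "b"), actor = c("1", "2"),
                   target = NA, rate = c(1, 3), stringsAsFactors = FALSE)
  attr(ch, "total") <- 4
  set.seed(7)
  picks <- replicate(10000, drawEvent(ch)$channel$kind)
  f <- mean(picks == "b")
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(f - 0.75), 3 * se)

  one <- ch[2, , drop = FALSE]
  attr(one, "total") <- 5
  set.seed(7)
  ds <- replicate(2000, drawEvent(one)$dt)
  expect_lt(abs(mean(ds) - 1 / 5), 3 * (1 / 5) / sqrt(2000))

  set.seed(11)
  a <- replicate(5, drawEvent(ch)$channel$kind)
  set.seed(11)
  b <- replicate(5, drawEvent(ch)$channel$kind)
  expect_identical(a, b)

  none <- ch[0, ]
  attr(none, "total") <- 0
  expect_error(drawEvent(none), "absorbing")
})

test_that("compiled and reference engines produce identical trajectories", {
  # model exercising every channel type: competition, BRC floor, therapy
  # with bursts, cytokine-induced switching, mutation
  sp <- TraitSpace(c("g", "h"), list(g = c("p", "q"), h = "r"),
                   tcellTypes = "z", cytokineTypes = "w")
  pars <- ModelParams(sp, K = 60, cancer = list(
    b = c(p = 2, q = 2, r = 2.5), d = c(p = 0.5, q = 0.5, r = 0.5),
    c = matrix(0.5, 3, 3, dimnames = list(c("p", "q", "r"), c("p", "q", "r"))),
    c_b = matrix(0.3, 3, 3, dimnames = list(c("p", "q", "r"), c("p", "q", "r"))),
    t_kill = list(p = list(z = 2)),
    kill_burst = list(p = list(z = list(w = 2))),
    s_nat = list(p = list(q = 0.2), q = list(p = 0.1)),
    s_cyt = list(w = list(p = list(q = 1))),
    mu = c(g = 0.1, h = 0),
    m_law = list(p = list(r = 1), q = list(r = 1))
  ), tcells = list(b_T = c(z = 0.1), d_T = c(z = 0.8),
                   t_prod = list(z = list(p = 1))),
  cytokines = list(d_W = 4))
  init <- populationState(sp, c(p = 30, q = 5, z = 10, w = 2))
  sched <- data.frame(time = 1.5, trait = "z", count = 5)
  t1 <- simulateSSA(init, pars, tMax = 4, seed = 99, recordDt = 0.25,
                    schedule = sched, engine = "cpp")
  t2 <- simulateSSA(init, pars, tMax = 4, seed = 99, recordDt = 0.25,
                    schedule = sched, engine = "R")
  expect_identical(trajTimes(t1), trajTimes(t2))
  expect_identical(trajCounts(t1), trajCounts(t2))
  expect_identical(cumMutations(t1), cumMutations(t2))
  expect_identical(stopReason(t1), stopReason(t2))
  expect_identical(eventCounts(t1), eventCounts(t2))
})

test_that("degenerate and absorbing initial states stop immediately", {
  sp <- TraitSpace("g", list(g = "p"))
  p <- singleTypeModel()
  tr <- simulateSSA(populationState(sp), p, tMax = 10, seed = 1)
  expect_equal(length(trajTimes(tr)), 1L)
  expect_equal(stopReason(tr), "all_extinct")
})

test_that("pure-death extinction time matches the order-statistic oracle", {
  # n0 independent unit-rate exponential lifetimes: E[max] = H_{n0}
  n0 <- 100
  p <- singleTypeModel(b = 0, d = 1, K = 1)
  sp <- p@space
  nrep <- 400
  times <- numeric(nrep)
  for (i in seq_len(nrep)) {
    tr <- simulateSSA(populationState(sp, c(p = n0)), p, tMax = 100,
                      seed = 1000 + i, recordDt = 100)
    expect_equal(stopReason(tr), "all_extinct")
    times[i] <- trajTimes(tr)[length(trajTimes(tr))]
  }
  H <- sum(1 / seq_len(n0))
  sdMax <- sqrt(sum(1 / seq_len(n0)^2))
  expect_lt(abs(mean(times) - H), 3 * sdMax / sqrt(nrep))
})

test_that("branching-process extinction probability matches (d/b)^n0", {
  p <- singleTypeModel(b = 2, d = 1, K = 1)
  sp <- p@space
  nrep <- 2000
  ext <- logical(nrep)
  for (i in seq_len(nrep)) {
    tr <- simulateSSA(populationState(sp, c(p = 3)), p, tMax = 1e4,
                      seed = 5000 + i, recordDt = 1e4,
                      thresholdTraits = "p", thresholdCount = 500)
    ext[i] <- stopReason(tr) %in% c("all_extinct", "group_extinct")
  }
  pTrue <- (1 / 2)^3
  se <- sqrt(pTrue * (1 - pTrue) / nrep)
  expect_lt(abs(mean(ext) - pTrue), 3 * se)
})

test_that("without mutation no new genotype ever appears", {
  pars <- twoPhenotypeModel(K = 50)
  sp <- TraitSpace(c("g", "h"), list(g = c("p1", "p2"), h = "p3"))
  pars2 <- ModelParams(sp, K = 50, cancer = list(
    b = c(p1 = 2, p2 = 2, p3 = 3), d = c(p1 = 1, p2 = 1, p3 = 1),
    c = matrix(1, 3, 3, dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3"))),
    s_nat = list(p1 = list(p2 = 0.5), p2 = list(p1 = 0.5)),
    mu = c(g = 0, h = 0)
  ))
  tr <- simulateSSA(populationState(sp, c(p1 = 30)), pars2, tMax = 20, seed = 3)
  expect_true(all(trajCounts(tr)[, "p3"] == 0))
  expect_equal(unname(eventCounts(tr)["mutant_birth"]), 0)
})

test_that("counts stay non-negative and integral along trajectories", {
  sc <- builtinScenario("one_tcell_qualitative")
  tr <- simulateSSA(populationState(sc@params@space, sc@initialCounts),
                    sc@params, tMax = 20, seed = 5, recordDt = 0.5)
  X <- trajCounts(tr)
  expect_true(all(X >= 0))
  expect_true(all(X == round(X)))
  expect_true(all(diff(trajTimes(tr)) > 0))
})
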