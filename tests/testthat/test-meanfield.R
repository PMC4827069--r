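test_that("single-type equilibrium solves b - c_b x = d + c x", {
  p <- singleTypeModel(b = 3, d = 1, c = 0.5, c_b = 0.3)
  xeq <- (3 - 1) / (0.5 + 0.3)
  f <- vectorField(c(p = xeq), p)
  expect_equal(unname(f), 0, tolerance = 1e-12)
  # floor inactive there
  expect_lt(0.3 * xeq, 3)
})

test_that("the origin is always a fixed point and sign structure holds", {
  sc <- builtinScenario("one_tcell_qualitative")
  f0 <- vectorField(rep(0, 4), sc@params)
  expect_equal(unname(f0), rep(0, 4))

  # a predator alone declines without prey
  spz <- TraitSpace("g", list(g = "p"), tcellTypes = "z")
  pz <- ModelParams(spz, K = 10, cancer = list(b = c(p = 1), d = c(p = 1)),
                    tcells = list(b_T = c(z = 0.2), d_T = c(z = 1),
                                  t_prod = list(z = list(p = 5))))
  f <- vectorField(c(z = 0.4), pz)
  expect_lt(f["z"], 0)
})

test_that("logistic integration approaches the closed-form equilibrium", {
  p <- singleTypeModel(b = 2, d = 1, c = 1, c_b = 0)
  df <- integrateODE(c(p = 0.01), p, seq(0, 60, 0.5))
  xeq <- (2 - 1) / 1
  expect_equal(df$p[nrow(df)], xeq, tolerance = 1e-3)
  # monotone approach from below
  expect_true(all(diff(df$p) > -1e-10))
  expect_lt(attr(df, "finalDerivNorm"), 1e-6)

  # exact logistic solution at interior times
  r <- 1; x0 <- 0.01
  tt <- c(2, 5, 10)
  exact <- xeq / (1 + (xeq / x0 - 1) * exp(-r * tt))
  expect_equal(df$p[match(tt, df$time)], exact, tolerance = 1e-6)
})

test_that("the field is quadratic where the birth-rate floor is inactive", {
  pars <- twoPhenotypeModel(b = c(2, 3), d = c(1, 0.5), s12 = 0.4, s21 = 0.2,
                            c = 0.5, K = 10)
  # degree-2 polynomial interpolation in (x1, x2) must reproduce the field
  set.seed(1)
  X <- matrix(runif(60, 0, 2), ncol = 2)
  mono <- function(x) c(1, x[1], x[2], x[1]^2, x[1] * x[2], x[2]^2)
  B <- t(apply(X, 1, mono))
  for (comp in 1:2) {
    y <- apply(X, 1, function(x) vectorField(c(p1 = x[1], p2 = x[2]), pars)[comp])
    fit <- lm.fit(B, y)
    expect_lt(max(abs(fit$residuals)), 1e-10)
    # and it predicts new points exactly
    xn <- c(1.234, 0.567)
    pred <- sum(fit$coefficients * mono(xn))
    expect_equal(pred, unname(vectorField(c(p1 = xn[1], p2 = xn[2]), pars)[comp]),
                 tolerance = 1e-9)
  }
})

test_that("invariant subspaces are closed: zeros without influx stay zero", {
  pars <- twoPhenotypeModel(s12 = 0, s21 = 0.5, c = 1, K = 10)
  # p2 has no influx (switch p1 -> p2 is zero): starting at p2 = 0 it stays 0
  df <- integrateODE(c(p1 = 0.5), pars, seq(0, 30, 0.5))
  expect_true(all(df$p2 == 0))
  # p1 receives influx from p2, so from p1 = 0 it becomes positive
  f <- vectorField(c(p2 = 0.5), pars)
  expect_gt(f["p1"], 0)
  expect_equal(unname(f["p1"]), 0.5 * 0.5)   # s21 * x2
})

test_that("rare mutations are invisible in the deterministic limit", {
  sp <- TraitSpace(c("g", "h"), list(g = "p", h = "q"))
  pars <- ModelParams(sp, K = 100, cancer = list(
    b = c(p = 2, q = 3), d = c(p = 1, q = 1),
    c = matrix(1, 2, 2, dimnames = list(c("p", "q"), c("p", "q"))),
    mu = c(g = 0.05, h = 0), m_law = list(p = list(q = 1))
  ))
  fOff <- vectorField(c(p = 0.5), pars, mutationOn = FALSE)
  expect_equal(unname(fOff["q"]), 0)
  fOn <- vectorField(c(p = 0.5), pars, mutationOn = TRUE)
  # influx = mu * B_eff * x, clonal part reduced by (1 - mu)
  expect_equal(unname(fOn["q"]), 0.05 * 2 * 0.5)
  # clonal part reduced by (1 - mu); self-competition c * x
  expect_equal(unname(fOn["p"]), 0.5 * ((1 - 0.05) * 2 - 1 - 1 * 0.5))
})

test_that("fixed-point inventory of the one-specificity regime", {
  pars <- builtinScenario("one_tcell_qualitative")@params
  fps <- findFixedPoints(pars)
  labs <- vapply(fps, function(fp) fp$label, character(1))
  expect_gte(length(fps), 3)
  expect_true("P_0.0.0.0" %in% labs)
  origin <- fps[[which(labs == "P_0.0.0.0")]]
  expect_equal(origin$classification, "unstable")

  tumourOnly <- Filter(function(fp) setequal(fp$support, c("x", "y")), fps)
  expect_length(tumourOnly, 1)
  expect_equal(tumourOnly[[1]]$classification, "unstable")
  restricted <- classifyStability(tumourOnly[[1]], pars, restrictToSupport = TRUE)
  expect_equal(restricted$classification, "stable")

  interior <- Filter(function(fp) length(fp$support) == 4, fps)
  expect_length(interior, 1)
  expect_equal(interior[[1]]$classification, "stable")
  # the interior point is the only fully stable one
  stable <- Filter(function(fp) fp$classification == "stable", fps)
  expect_length(stable, 1)
})

test_that("second T-cell specificity adds two fixed points and destabilizes the old interior", {
  pars2 <- builtinScenario("two_tcell_qualitative")@params
  fps2 <- findFixedPoints(pars2)
  sup <- lapply(fps2, function(fp) fp$support)
  has <- function(s) any(vapply(sup, function(x) setequal(x, s), logical(1)))
  expect_true(has(character()))                      # origin
  expect_true(has(c("x", "y")))                      # tumour only
  expect_true(has(c("x", "y", "zx", "w")))           # old interior
  expect_true(has(c("x", "y", "zy", "w")))           # zx absent
  expect_true(has(c("x", "y", "zx", "zy", "w")))     # new interior

  oldInt <- Filter(function(fp) setequal(fp$support, c("x", "y", "zx", "w")), fps2)[[1]]
  expect_equal(oldInt$classification, "unstable")
  restr <- classifyStability(oldInt, pars2, restrictToSupport = TRUE)
  expect_equal(restr$classification, "stable")

  newInt <- Filter(function(fp) length(fp$support) == 5, fps2)[[1]]
  expect_equal(newInt$classification, "stable")
})

test_that("pure-death system has the origin as unique fixed point", {
  p <- singleTypeModel(b = 0, d = 1, c = 1)
  fps <- findFixedPoints(p)
  expect_length(fps, 1)
  expect_equal(unname(fps[[1]]$x), 0)
  expect_equal(fps[[1]]$classification, "stable")
})

test_that("stability classification matches analytic signs", {
  p <- singleTypeModel(b = 2, d = 1, c = 1, c_b = 0.5)
  xeq <- (2 - 1) / 1.5
  fp <- classifyStability(c(p = xeq), p)
  expect_equal(fp$classification, "stable")
  # 1-D: eigenvalue = d/dx [x(b - c_b x) - x d - c x^2] at xeq = -(b-d)
  expect_equal(Re(fp$eigenvalues), -(2 - 1), tolerance = 1e-5)

  origin <- classifyStability(c(p = 0), p)
  expect_equal(origin$classification, "unstable")
  expect_equal(Re(origin$eigenvalues), 2 - 1, tolerance = 1e-6)
})
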