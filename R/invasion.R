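# Invasion fitness of a rare mutant genotype with phenotype structure.
# Until the mutant clone dies out or reaches size epsilon*K it is
# approximated by a multi-type branching process whose mean count vector
# n(t) obeys dn/dt = A n; the largest eigenvalue of A generalises the
# scalar invasion fitness, and its right eigenvector gives the phenotype
# composition of a surviving clone.

residentDensities <- function(residentEq, params) {
  nms <- traitNames(params@space)
  if (inherits(residentEq, "FixedPoint")) {
    if (residentEq$residual > 1e-6) {
      stop("resident equilibrium residual too large: ", residentEq$residual)
    }
    residentEq <- residentEq$x
  }
  denseVec(residentEq, nms, "resident densities")
}

#' Mean matrix of the branching-process approximation for a rare mutant
#'
#' Builds the generator A of the mean dynamics dn/dt = A n of a clone of the
#' mutant genotype's phenotypes against a fixed resident background. The
#' diagonal entry of phenotype p_i is its net per-capita growth rate in that
#' background (clonal birth net of the birth-reduction floor, natural and
#' competitive death, therapy kill, and all outgoing switch rates); the
#' off-diagonal entry A\[i, j\] is the switch rate from p_j to p_i (column j
#' feeds row i). An outgoing switch is a loss for a phenotype but not for
#' the genotype, which is why the genotype's growth rate can be positive
#' even when every phenotype's diagonal entry is negative.
#'
#' @param residentEq a fixed point from [findFixedPoints()] or a named
#'   density vector; the mutant genotype's phenotypes must have zero density
#'   in it.
#' @param mutantGenotype genotype identifier whose phenotypes form the clone.
#' @param params a [ModelParams-class].
#' @return a [MeanMatrix-class].
#' @export
meanMatrix <- function(residentEq, mutantGenotype, params) {
  sp <- params@space
  if (!mutantGenotype %in% sp@genotypes) {
    stop("unknown genotype: ", mutantGenotype)
  }
  xbar <- residentDensities(residentEq, params)
  phen <- sp@phenotypesOf[[mutantGenotype]]
  if (any(xbar[phen] > 0)) {
    stop("resident equilibrium contains the mutant genotype (",
         paste(phen[xbar[phen] > 0], collapse = ", "), " > 0)")
  }
  P <- phenotypes(sp)
  Z <- tcellTypes(sp)
  W <- cytokineTypes(sp)
  muEff <- effectiveMu(params)
  k <- length(phen)
  A <- matrix(0, k, k, dimnames = list(phen, phen))
  sEff <- params@cancer$s_nat
  for (w in W) sEff <- sEff + xbar[w] * params@cancer$s_cyt[w, , ]
  for (i in seq_len(k)) {
    p <- phen[i]
    Sb <- sum(params@cancer$c_b[p, ] * xbar[P])
    Sd <- sum(params@cancer$c[p, ] * xbar[P])
    kill <- if (length(Z)) sum(params@cancer$t_kill[p, ] * xbar[Z]) else 0
    out <- sum(sEff[p, phen[-i]])
    A[i, i] <- (1 - muEff[p]) * max(0, params@cancer$b[p] - Sb) -
      params@cancer$d[p] - Sd - kill - max(0, Sb - params@cancer$b[p]) - out
    for (j in seq_len(k)) {
      if (j != i) A[i, j] <- sEff[phen[j], p]
    }
  }
  new("MeanMatrix", A = A, phenotypes = phen, genotype = mutantGenotype,
      resident = xbar)
}

stronglyConnected <- function(B) {
  k <- nrow(B)
  if (k == 1L) return(TRUE)
  adj <- B > 0
  diag(adj) <- TRUE
  reach <- adj
  for (s in seq_len(k)) reach <- (reach %*% adj) > 0   # k-step closure
  all(reach) && all(t(reach))
}

#' Invasion fitness and phenotype proportions of a mutant clone
#'
#' The clone grows with positive probability (uniformly in K) if and only
#' if the largest eigenvalue lambda1 of the mean matrix is strictly
#' positive; otherwise it dies out with probability tending to one. For a
#' single mutant phenotype lambda1 reduces to the standard scalar invasion
#' fitness. When the switch graph is irreducible, the normalized right
#' eigenvector v is strictly positive and gives the asymptotic phenotype
#' proportions of a surviving clone at size epsilon*K.
#'
#' @param M a [MeanMatrix-class] from [meanMatrix()].
#' @return an [InvasionResult-class].
#' @export
invasionFitness <- function(M) {
  stopifnot(is(M, "MeanMatrix"))
  A <- M@A
  e <- eigen(A)
  idx <- which.max(Re(e$values))
  lam <- e$values[idx]
  if (abs(Im(lam)) > 1e-10) {
    stop("leading eigenvalue has non-negligible imaginary part (",
         format(Im(lam)), "); defective eigenproblem")
  }
  v <- Re(e$vectors[, idx])
  s <- sum(v)
  if (s != 0) v <- v / s
  v[abs(v) < 1e-12] <- 0
  irr <- stronglyConnected(A - diag(diag(A), nrow = nrow(A)))
  if (irr && any(v < 0)) {
    warning("leading eigenvector not non-negative despite irreducibility")
  }
  names(v) <- M@phenotypes
  new("InvasionResult",
    lambda1 = Re(lam), v = v, supercritical = Re(lam) > 0,
    irreducible = irr, A = M
  )
}

setMethod("show", "InvasionResult", function(object) {
  cat("InvasionResult for genotype", object@A@genotype, "\n")
  cat("  lambda1 =", format(object@lambda1, digits = 8),
      if (object@supercritical) "(supercritical)" else "(subcritical)", "\n")
  cat("  proportions v:", paste(sprintf("%s=%.4f", names(object@v), object@v),
                                collapse = ", "), "\n")
  if (!object@irreducible) cat("  WARNING: switch graph not irreducible\n")
})

setMethod("show", "MeanMatrix", function(object) {
  cat("MeanMatrix (dn/dt = A n) for genotype", object@genotype, "\n")
  print(object@A)
})

#' Monte-Carlo companion of the branching-process invasion calculus
#'
#' Simulates the mutant clone by the exact stochastic algorithm with the
#' resident populations frozen at their equilibrium counts (the object the
#' branching-process theory classifies), starting from a single mutant
#' individual, until the clone reaches size epsilon*K or dies out. Mutant
#' offspring that mutate out of the clone's genotype are lost to the clone.
#'
#' @param residentEq fixed point or named density vector of the resident.
#' @param mutantGenotype genotype of the invading clone.
#' @param params a [ModelParams-class].
#' @param epsilon threshold size as a fraction of K (epsilon*K must be at
#'   least 10 for the threshold to be meaningful).
#' @param nRuns number of replicates.
#' @param seed base seed; replicate i uses seed + i.
#' @param initPhenotype phenotype of the founding individual (default: the
#'   mutant genotype's first phenotype).
#' @param tMax guard horizon in days.
#' @return list with `survival` (fraction of runs reaching epsilon*K),
#'   `se` (binomial standard error), `proportions` (mean phenotype
#'   composition at the hitting time over surviving runs), `nRuns`,
#'   `threshold`.
#' @export
invasionMCOracle <- function(residentEq, mutantGenotype, params,
                             epsilon = 0.05, nRuns = 1000, seed = 1,
                             initPhenotype = NULL, tMax = 1e5) {
  sp <- params@space
  xbar <- residentDensities(residentEq, params)
  phen <- sp@phenotypesOf[[mutantGenotype]]
  if (is.null(initPhenotype)) initPhenotype <- phen[1]
  stopifnot(initPhenotype %in% phen)
  K <- params@K
  threshold <- ceiling(epsilon * K)
  if (threshold < 10) stop("epsilon*K must be >= 10 (got ", threshold, ")")
  nms <- traitNames(sp)
  init <- round(xbar * K)
  init[phen] <- 0
  init[initPhenotype] <- 1
  frozen <- setdiff(nms, phen)
  surv <- logical(nRuns)
  comp <- matrix(0, nRuns, length(phen), dimnames = list(NULL, phen))
  for (i in seq_len(nRuns)) {
    tr <- simulateSSA(populationState(sp, init), params, tMax = tMax,
                      seed = seed + i, recordDt = tMax,
                      frozen = frozen, thresholdTraits = phen,
                      thresholdCount = threshold)
    surv[i] <- stopReason(tr) == "threshold"
    if (surv[i]) {
      fc <- finalCounts(tr)[phen]
      comp[i, ] <- fc / sum(fc)
    }
  }
  p <- mean(surv)
  list(
    survival = p,
    se = sqrt(p * (1 - p) / nRuns),
    proportions = if (any(surv)) colMeans(comp[surv, , drop = FALSE]) else
      stats::setNames(rep(NA_real_, length(phen)), phen),
    propSE = if (sum(surv) > 1) apply(comp[surv, , drop = FALSE], 2, stats::sd) / sqrt(sum(surv)) else
      stats::setNames(rep(NA_real_, length(phen)), phen),
    nSurvived = sum(surv),
    nRuns = nRuns,
    threshold = threshold
  )
}

#' Total mutation rate under birth-reducing competition
#'
#' For a single-type population whose competition lowers the birth rate,
#' the total mutation rate at population size n is mu * n * max(0, b - c_b
#' n / K): a quadratic in n, maximal at n* = bK/(2 c_b). The equilibrium
#' size solves b - c_b n/K = d + c n/K, i.e. n-bar = (b-d)K/(c+c_b). In the
#' pure birth-reducing case (c = 0) the equilibrium mutation rate is not
#' maximal precisely when d < b/2: a large population at equilibrium then
#' encounters fewer births, hence fewer mutations, than a smaller population
#' growing towards its equilibrium -- so therapy that pushes the tumour
#' below n* can raise the total mutation rate.
#'
#' @param b,d birth and death rate (per day), b > d >= 0.
#' @param c death-increasing competition coefficient (0 for pure
#'   birth-reducing competition).
#' @param c_b birth-reducing competition coefficient (> 0).
#' @param mu mutation probability per birth.
#' @param K carrying capacity.
#' @return object of class `BrcMutationCurve`: list with `rate_at`
#'   (function of n), `n_star`, `n_bar`, `submaximal_at_equilibrium`, and
#'   the parameters.
#' @examples
#' cv <- brcMutationCurve(b = 2, d = 0.5, c = 0, c_b = 1, mu = 1e-3, K = 1000)
#' cv$n_bar; cv$n_star; cv$submaximal_at_equilibrium
#' @export
brcMutationCurve <- function(b, d, c = 0, c_b, mu, K) {
  if (!(b > d)) stop("no positive equilibrium: requires b > d")
  if (d < 0 || c < 0) stop("rates must be non-negative")
  if (!(c_b > 0)) stop("birth-reducing coefficient c_b must be positive")
  nStar <- b * K / (2 * c_b)
  nBar <- (b - d) * K / (c + c_b)
  out <- list(
    b = b, d = d, c = c, c_b = c_b, mu = mu, K = K,
    rate_at = function(n) mu * n * pmax(0, b - c_b * n / K),
    n_star = nStar,
    n_bar = nBar,
    submaximal_at_equilibrium = nBar > nStar
  )
  class(out) <- "BrcMutationCurve"
  out
}

#' @export
print.BrcMutationCurve <- function(x, ...) {
  cat("BRC mutation-rate curve: rate(n) = mu n max(0, b - c_b n/K)\n")
  cat(sprintf("  n* (argmax) = %.6g, equilibrium n-bar = %.6g\n", x$n_star, x$n_bar))
  cat("  equilibrium rate submaximal:", x$submaximal_at_equilibrium, "\n")
  invisible(x)
}
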