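# Dense normalization helpers ------------------------------------------------

denseVec <- function(x, nms, what) {
  out <- stats::setNames(numeric(length(nms)), nms)
  if (is.null(x)) return(out)
  x <- unlist(x)
  if (length(x) == 0L) return(out)
  if (is.null(names(x)) && length(x) == length(nms)) {
    names(x) <- nms
  }
  bad <- setdiff(names(x), nms)
  if (length(bad)) {
    stop("unknown name(s) in ", what, ": ", paste(bad, collapse = ", "))
  }
  out[names(x)] <- as.numeric(x)
  out
}

denseMat <- function(x, rn, cn, what) {
  out <- matrix(0, length(rn), length(cn), dimnames = list(rn, cn))
  if (is.null(x)) return(out)
  if (is.matrix(x)) {
    if (is.null(dimnames(x))) {
      stopifnot(all(dim(x) == dim(out)))
      dimnames(x) <- list(rn, cn)
    }
    bad <- c(setdiff(rownames(x), rn), setdiff(colnames(x), cn))
    if (length(bad)) stop("unknown name(s) in ", what, ": ", paste(bad, collapse = ", "))
    out[rownames(x), colnames(x)] <- x
    return(out)
  }
  # nested named list {row: {col: value}}
  for (r in names(x)) {
    if (!r %in% rn) stop("unknown row '", r, "' in ", what)
    row <- unlist(x[[r]])
    bad <- setdiff(names(row), cn)
    if (length(bad)) stop("unknown column(s) in ", what, "[", r, "]: ", paste(bad, collapse = ", "))
    out[r, names(row)] <- as.numeric(row)
  }
  out
}

dense3 <- function(x, d1, d2, d3, what) {
  out <- array(0, dim = c(length(d1), length(d2), length(d3)),
               dimnames = list(d1, d2, d3))
  if (is.null(x)) return(out)
  if (is.array(x) && length(dim(x)) == 3L) {
    stopifnot(all(dim(x) == dim(out)))
    if (is.null(dimnames(x))) dimnames(x) <- dimnames(out)
    out[dimnames(x)[[1]], dimnames(x)[[2]], dimnames(x)[[3]]] <- x
    return(out)
  }
  # nested list {a: {b: {c: value}}}
  for (a in names(x)) {
    if (!a %in% d1) stop("unknown name '", a, "' in ", what)
    for (b in names(x[[a]])) {
      if (!b %in% d2) stop("unknown name '", b, "' in ", what, "[", a, "]")
      v <- unlist(x[[a]][[b]])
      bad <- setdiff(names(v), d3)
      if (length(bad)) stop("unknown name(s) in ", what, "[", a, "][", b, "]")
      out[a, b, names(v)] <- as.numeric(v)
    }
  }
  out
}

# Constructor ------------------------------------------------------------------

#' Construct a full model parameter set
#'
#' All kernels are stored dense over the declared trait space; entries not
#' supplied default to zero. Rate maps may be given as named vectors, named
#' matrices, or nested named lists (the natural shape of a parsed YAML
#' config).
#'
#' @param space a [TraitSpace-class].
#' @param K carrying capacity (positive scalar). Sets the weight 1/K of an
#'   individual in the scaled population measure and thereby the amplitude
#'   of stochastic fluctuations.
#' @param cancer list with any of: `b`, `d` (per-phenotype rates, per day),
#'   `c`, `c_b` (phenotype x phenotype competition kernels: `c` raises the
#'   death rate, `c_b` lowers the birth rate and, once the birth rate is
#'   floored at zero, acts as additional death), `t_kill`
#'   (phenotype x T-cell kill kernel), `kill_burst`
#'   (phenotype x T-cell x cytokine integer bursts released at each kill),
#'   `s_nat`, `s_cyt` (natural / cytokine-induced switch kernels; `s_cyt` is
#'   cytokine x from x to), `mu` (per-genotype mutation probability),
#'   `m_law` (phenotype x phenotype mutation law, rows sum to 1, zero
#'   diagonal).
#' @param tcells list with any of: `b_T`, `d_T` (per-type rates; `d_T` is an
#'   effective death rate that also absorbs exhaustion), `t_prod`
#'   (T-cell x phenotype reproduction kernel in presence of prey),
#'   `rep_burst` (T-cell x cytokine integer bursts at reproduction).
#' @param cytokines list with `d_W` (per-cytokine decay rate).
#' @param muScaling list(rule = "constant") or
#'   list(rule = "K_logK", mu_bar = <per-genotype>); under "K_logK" the
#'   effective mutation probability is mu_bar / (K log K).
#'
#' @return a [ModelParams-class]; use [validateParameters()] to obtain a
#'   report of violated constraints (construction itself only enforces
#'   structural shape).
#' @export
ModelParams <- function(space, K, cancer = list(), tcells = list(),
                        cytokines = list(),
                        muScaling = list(rule = "constant")) {
  P <- phenotypes(space)
  Z <- tcellTypes(space)
  W <- cytokineTypes(space)
  G <- space@genotypes
  # exact [[-indexing throughout: $ would partially match (e.g. $c -> c_b)
  can <- list(
    b = denseVec(cancer[["b"]], P, "b"),
    d = denseVec(cancer[["d"]], P, "d"),
    c = denseMat(cancer[["c"]], P, P, "c"),
    c_b = denseMat(cancer[["c_b"]], P, P, "c_b"),
    t_kill = denseMat(cancer[["t_kill"]], P, Z, "t_kill"),
    kill_burst = dense3(cancer[["kill_burst"]], P, Z, W, "kill_burst"),
    s_nat = denseMat(cancer[["s_nat"]], P, P, "s_nat"),
    s_cyt = dense3(cancer[["s_cyt"]], W, P, P, "s_cyt"),
    mu = denseVec(cancer[["mu"]], G, "mu"),
    m_law = denseMat(cancer[["m_law"]], P, P, "m_law")
  )
  unknown <- setdiff(names(cancer), names(can))
  if (length(unknown)) stop("unknown cancer parameter(s): ", paste(unknown, collapse = ", "))
  tc <- list(
    b_T = denseVec(tcells[["b_T"]], Z, "b_T"),
    d_T = denseVec(tcells[["d_T"]], Z, "d_T"),
    t_prod = denseMat(tcells[["t_prod"]], Z, P, "t_prod"),
    rep_burst = denseMat(tcells[["rep_burst"]], Z, W, "rep_burst")
  )
  unknown <- setdiff(names(tcells), names(tc))
  if (length(unknown)) stop("unknown tcells parameter(s): ", paste(unknown, collapse = ", "))
  cy <- list(d_W = denseVec(cytokines[["d_W"]], W, "d_W"))
  unknown <- setdiff(names(cytokines), "d_W")
  if (length(unknown)) stop("unknown cytokines parameter(s): ", paste(unknown, collapse = ", "))
  new("ModelParams",
    space = space, cancer = can, tcells = tc, cytokines = cy,
    K = as.numeric(K), muScaling = muScaling
  )
}

setValidity("ModelParams", function(object) {
  P <- phenotypes(object@space)
  Z <- tcellTypes(object@space)
  W <- cytokineTypes(object@space)
  msg <- character()
  chk <- function(ok, m) if (!ok) msg <<- c(msg, m)
  chk(identical(names(object@cancer$b), P), "cancer$b misshapen")
  chk(identical(dim(object@cancer$c), c(length(P), length(P))), "cancer$c misshapen")
  chk(identical(dim(object@cancer$t_kill), c(length(P), length(Z))), "cancer$t_kill misshapen")
  chk(identical(dim(object@cancer$kill_burst), c(length(P), length(Z), length(W))),
      "cancer$kill_burst misshapen")
  chk(identical(dim(object@cancer$s_cyt), c(length(W), length(P), length(P))),
      "cancer$s_cyt misshapen")
  chk(identical(names(object@cytokines$d_W), W), "cytokines$d_W misshapen")
  chk(length(object@K) == 1L, "K must be a scalar")
  if (length(msg)) msg else TRUE
})

#' Validate every structural constraint of a parameter set
#'
#' Checks all model invariants: non-negativity of all rates and kernels,
#' mutation probabilities in \[0, 1\], row-stochastic mutation law with zero
#' diagonal, switch kernels connecting only phenotypes of the same genotype
#' with zero diagonal, integer burst counts, and K >= 1. Violations are
#' returned as data, not raised.
#'
#' @param params a [ModelParams-class].
#' @return character vector of human-readable violations; empty if valid.
#' @examples
#' sp <- TraitSpace("g", list(g = c("p", "q")))
#' p <- ModelParams(sp, K = 100, cancer = list(b = c(p = 1, q = 1), mu = c(g = 1.3)))
#' validateParameters(p)
#' @export
validateParameters <- function(params) {
  stopifnot(is(params, "ModelParams"))
  sp <- params@space
  P <- phenotypes(sp)
  gof <- genotypeOf(sp)
  v <- character()
  bad <- function(x) any(!is.finite(x)) || any(x < 0)
  if (length(params@K) != 1L || !is.finite(params@K) || params@K < 1) {
    v <- c(v, "K: must be a finite scalar >= 1")
  }
  for (nm in c("b", "d")) {
    if (bad(params@cancer[[nm]])) v <- c(v, paste0("cancer$", nm, ": negative or non-finite rate"))
  }
  for (nm in c("c", "c_b", "t_kill", "s_nat", "m_law")) {
    if (bad(params@cancer[[nm]])) v <- c(v, paste0("cancer$", nm, ": negative or non-finite entry"))
  }
  if (bad(params@cancer$kill_burst)) v <- c(v, "cancer$kill_burst: negative entry")
  if (any(params@cancer$kill_burst != round(params@cancer$kill_burst))) {
    v <- c(v, "cancer$kill_burst: non-integer burst count")
  }
  if (bad(params@cancer$s_cyt)) v <- c(v, "cancer$s_cyt: negative or non-finite entry")
  mu <- params@cancer$mu
  for (g in names(mu)) {
    if (!is.finite(mu[g]) || mu[g] < 0 || mu[g] > 1) {
      v <- c(v, paste0("cancer$mu[", g, "]: must lie in [0, 1], got ", mu[g]))
    }
  }
  # switch kernels connect only phenotypes of the same genotype; zero diagonal
  for (i in P) {
    for (j in P) {
      cross <- gof[i] != gof[j]
      if (params@cancer$s_nat[i, j] != 0 && (cross || i == j)) {
        v <- c(v, paste0("cancer$s_nat[", i, ",", j, "]: ",
                         if (i == j) "diagonal entry must be zero" else "links phenotypes of different genotypes"))
      }
      if (any(params@cancer$s_cyt[, i, j] != 0) && (cross || i == j)) {
        v <- c(v, paste0("cancer$s_cyt[.,", i, ",", j, "]: ",
                         if (i == j) "diagonal entry must be zero" else "links phenotypes of different genotypes"))
      }
    }
  }
  # mutation law: zero diagonal, rows sum to 1 wherever mutation is possible
  ml <- params@cancer$m_law
  if (length(P)) {
    dg <- diag(ml)
    if (any(dg != 0)) {
      v <- c(v, paste0("cancer$m_law[", P[which(dg != 0)[1]], "]: self-mutation probability must be zero"))
    }
    for (i in P) {
      rs <- sum(ml[i, ])
      muOK <- is.finite(mu[gof[i]]) && mu[gof[i]] >= 0 && mu[gof[i]] <= 1
      if (muOK && mu[gof[i]] > 0 && abs(rs - 1) > 1e-9) {
        v <- c(v, paste0("cancer$m_law[", i, ",]: row must sum to 1 (got ", rs,
                         ") since mu[", gof[i], "] > 0"))
      }
      if (mu[gof[i]] == 0 && rs != 0 && abs(rs - 1) > 1e-9) {
        v <- c(v, paste0("cancer$m_law[", i, ",]: row must sum to 0 or 1"))
      }
    }
  }
  for (nm in c("b_T", "d_T", "t_prod", "rep_burst")) {
    if (bad(params@tcells[[nm]])) v <- c(v, paste0("tcells$", nm, ": negative or non-finite entry"))
  }
  if (any(params@tcells$rep_burst != round(params@tcells$rep_burst))) {
    v <- c(v, "tcells$rep_burst: non-integer burst count")
  }
  if (bad(params@cytokines$d_W)) v <- c(v, "cytokines$d_W: negative or non-finite rate")
  rule <- params@muScaling$rule
  if (!identical(rule, "constant") && !identical(rule, "K_logK")) {
    v <- c(v, "muScaling$rule: must be 'constant' or 'K_logK'")
  }
  v
}

#' Effective per-phenotype mutation probability
#'
#' Applies the configured mutation-rate scaling rule. Under "constant" the
#' per-genotype mu is used as given; under "K_logK" the effective value is
#' mu_bar / (K log K), the regime in which an order-one number of mutations
#' occurs while the population grows by order K individuals.
#'
#' @param params a [ModelParams-class].
#' @return named numeric vector over phenotypes (each phenotype inherits the
#'   mu of its genotype).
#' @export
effectiveMu <- function(params) {
  gof <- genotypeOf(params@space)
  rule <- params@muScaling$rule
  if (identical(rule, "K_logK")) {
    muBar <- denseVec(params@muScaling$mu_bar, params@space@genotypes, "mu_bar")
    mug <- muBar / (params@K * log(params@K))
    mug <- pmin(mug, 1)
  } else {
    mug <- params@cancer$mu
  }
  stats::setNames(as.numeric(mug[gof]), names(gof))
}

#' Carrying capacity accessor
#' @param params a [ModelParams-class].
#' @return numeric scalar K.
#' @export
carryingCapacity <- function(params) params@K

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams: K =", format(object@K), "\n")
  show(object@space)
  viol <- validateParameters(object)
  if (length(viol)) {
    cat("INVALID:", length(viol), "violation(s); see validateParameters()\n")
  } else {
    cat("all structural constraints satisfied\n")
  }
})

# Population states -------------------------------------------------------------

#' Construct an integer population state
#'
#' @param space a [TraitSpace-class] or [ModelParams-class].
#' @param counts named vector of individual counts; traits not named start
#'   at zero.
#' @param time time point in days.
#' @return a [PopulationState-class].
#' @export
populationState <- function(space, counts = numeric(), time = 0) {
  nms <- traitNames(space)
  x <- denseVec(counts, nms, "counts")
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  new("PopulationState", time = as.numeric(time), counts = x)
}

#' Counts accessor
#' @param state a [PopulationState-class].
#' @return named numeric vector of raw individual counts.
#' @export
stateCounts <- function(state) state@counts

#' Scaled population measure
#'
#' Each individual carries weight 1/K; the scaled measure of a trait is its
#' count divided by K.
#'
#' @param state a [PopulationState-class].
#' @param K carrying capacity (>= 1).
#' @return named numeric vector counts/K.
#' @examples
#' sp <- TraitSpace("g", list(g = "p"))
#' scaledMeasure(populationState(sp, c(p = 200)), K = 200)
#' @export
scaledMeasure <- function(state, K) {
  if (!is.numeric(K) || length(K) != 1L || K <= 0) {
    stop("invalid carrying capacity: K must be a positive scalar")
  }
  state@counts / K
}

setMethod("show", "PopulationState", function(object) {
  cat("PopulationState at t =", format(object@time), "days\n")
  print(object@counts)
})

# Fingerprint -------------------------------------------------------------------

# djb2 string hash, rendered in hex; a stable cross-platform fingerprint for
# run manifests (not cryptographic).
djb2 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 2^31
  }
  sprintf("%08x", h)
}

#' Stable fingerprint of a parameter set
#' @param params a [ModelParams-class].
#' @return 8-hex-digit character fingerprint of the canonical JSON
#'   serialization.
#' @export
paramsHash <- function(params) {
  djb2(paramsToJSON(params))
}
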