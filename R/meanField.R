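# Deterministic large-population (K -> infinity) limit: a system of
# quadratic ODEs with a logistic part, predator-prey coupling between
# T-cells and cancer cells, switch and (optional) mutation parts. It is not
# a generalised Lotka-Volterra system: the birth-rate floor and the
# cytokine production terms break that form.

#' Right-hand side of the deterministic limit system
#'
#' For a cancer phenotype p of genotype g:
#' dx_p = x_p\[(1-mu) max(0, b - sum c_b x) - d - sum c x - sum t_kill x_z
#'        - max(0, sum c_b x - b) - outgoing switch rates\] + switch influx
#'        (+ mutation influx when `mutationOn`).
#' For a T-cell type z: dx_z = x_z(b_T - d_T + sum_p t_prod x_p).
#' For a cytokine w: dx_w = -d_W x_w + bursts from therapy kills and T-cell
#' reproduction. With mutation probabilities vanishing as K grows, rare
#' mutations are invisible in this limit, so `mutationOn = FALSE` is the
#' default.
#'
#' @param x named numeric vector of scaled densities (units of K) over all
#'   traits, or a [PopulationState-class] (whose counts are divided by K).
#' @param params a [ModelParams-class].
#' @param mutationOn include the mutation terms.
#' @return named numeric vector of time derivatives.
#' @export
vectorField <- function(x, params, mutationOn = FALSE) {
  sp <- params@space
  nms <- traitNames(sp)
  if (is(x, "PopulationState")) x <- x@counts / params@K
  x <- denseVec(x, nms, "densities")
  if (any(x < -1e-8)) stop("negative density input")
  f <- makeField(params, mutationOn)
  stats::setNames(f(unname(x)), nms)
}

# Build the field once (engine matrices precomputed); returns a function on
# unnamed density vectors. The hot path for Newton iterations and Jacobians.
makeField <- function(params, mutationOn = FALSE) {
  em <- engineModel(params)
  nP <- em$nP; nZ <- em$nZ; nW <- em$nW
  mu <- if (mutationOn) em$muP else numeric(nP)
  tmlaw <- t(em$mlaw)
  function(x) {
    xP <- x[seq_len(nP)]
    xZ <- if (nZ) x[nP + seq_len(nZ)] else numeric()
    xW <- if (nW) x[nP + nZ + seq_len(nW)] else numeric()
    Sb <- as.numeric(em$Cb %*% xP)
    Sd <- as.numeric(em$C %*% xP)
    kill <- if (nZ) as.numeric(em$Tkill %*% xZ) else numeric(nP)
    Beff <- pmax(0, em$b - Sb)
    Dbrc <- pmax(0, Sb - em$b)
    sEff <- em$Snat
    for (w in seq_len(nW)) sEff <- sEff + xW[w] * em$Scyt[w, , ]
    dxP <- xP * ((1 - mu) * Beff - em$d - Sd - kill - Dbrc - rowSums(sEff)) +
      as.numeric(t(sEff) %*% xP)
    if (mutationOn) {
      dxP <- dxP + as.numeric(tmlaw %*% (xP * mu * Beff))
    }
    dxZ <- if (nZ) xZ * (em$bT - em$dT + as.numeric(em$Tprod %*% xP)) else numeric()
    dxW <- numeric(nW)
    if (nW) {
      killM <- em$Tkill * outer(xP, xZ)        # nP x nZ interaction mass
      preyZ <- em$bT + as.numeric(em$Tprod %*% xP)
      for (w in seq_len(nW)) {
        dxW[w] <- -em$dW[w] * xW[w] +
          sum(em$killBurst[, , w] * killM) +
          sum(em$repBurst[, w] * xZ * preyZ)
      }
    }
    c(dxP, dxZ, dxW)
  }
}

#' Integrate the deterministic limit system
#'
#' Stiff-capable integration (lsoda) of [vectorField()]; densities are
#' clipped at zero within solver tolerance. Scheduled injections are applied
#' as instantaneous density additions (count / K).
#'
#' @param x0 named numeric vector of initial densities (or a
#'   [PopulationState-class], converted via counts/K).
#' @param params a [ModelParams-class].
#' @param times output time grid (days).
#' @param mutationOn include mutation terms.
#' @param schedule optional data.frame(time, trait, count) of injections
#'   (counts are divided by K).
#' @param rtol,atol solver tolerances.
#' @return data.frame with column `time` and one column per trait (scaled
#'   densities); attribute `"finalDerivNorm"` holds the max-norm of the
#'   vector field at the terminal state.
#' @export
integrateODE <- function(x0, params, times, mutationOn = FALSE,
                         schedule = NULL, rtol = 1e-8, atol = 1e-10) {
  sp <- params@space
  nms <- traitNames(sp)
  if (is(x0, "PopulationState")) x0 <- x0@counts / params@K
  x0 <- denseVec(x0, nms, "x0")
  f <- makeField(params, mutationOn)
  rhs <- function(t, y, p) {
    list(f(pmax(y, 0)))
  }
  events <- NULL
  if (!is.null(schedule) && nrow(schedule) > 0L) {
    ev <- data.frame(
      var = schedule$trait,
      time = schedule$time,
      value = schedule$count / params@K,
      method = "add", stringsAsFactors = FALSE
    )
    # deSolve requires event times to be in the output times
    times <- sort(unique(c(times, schedule$time)))
    events <- list(data = ev)
  }
  names(x0) <- nms
  out <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      events = events)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed; istate = ", attr(out, "istate")[1])
  }
  df <- as.data.frame(out)
  df[nms] <- lapply(df[nms], function(col) pmax(col, 0))
  fin <- unlist(df[nrow(df), nms])
  attr(df, "finalDerivNorm") <- max(abs(vectorField(fin, params, mutationOn)))
  df
}

# Fixed points -----------------------------------------------------------------

numJacobian <- function(f, x, relStep = 1e-6, minStep = 1e-8) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    h <- max(minStep, relStep * abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

supportLabel <- function(nms, present) {
  comp <- ifelse(present, nms, "0")
  sep <- if (all(nchar(nms) == 1L)) "" else "."
  paste0("P_", paste(comp, collapse = sep))
}

#' Locate fixed points of the deterministic system
#'
#' Enumerates support patterns (each trait forced to zero or free) and runs
#' a damped Newton iteration on the support-restricted field from several
#' deterministic seed levels; solutions are kept when the full vector field
#' (including influx into the zeroed coordinates) vanishes to tolerance,
#' deduplicated, and classified by linear stability.
#'
#' @param params a [ModelParams-class].
#' @param seeds numeric vector of density levels used as Newton starting
#'   points on each support.
#' @param extraSeeds optional list of full named density vectors to use as
#'   additional starting points (support taken from their positive pattern).
#' @param tol residual tolerance for acceptance.
#' @param dedupTol minimum max-norm distance between distinct points.
#' @param mutationOn analyse the field with mutation terms included.
#' @return list of fixed points; each is a list with elements `x` (named
#'   densities), `residual`, `support` (trait names with positive density),
#'   `label` (subscript-style name, 0 for absent populations),
#'   `eigenvalues`, `classification` ("stable", "unstable" or "marginal"),
#'   and `floorActive` (TRUE if some phenotype sits on the birth-rate floor
#'   boundary, where the field is non-smooth).
#' @export
findFixedPoints <- function(params, seeds = c(0.05, 0.3, 1, 3),
                            extraSeeds = list(), tol = 1e-9,
                            dedupTol = 1e-6, mutationOn = FALSE) {
  nms <- traitNames(params@space)
  nT <- length(nms)
  if (nT > 12) stop("support enumeration limited to <= 12 traits")
  field <- makeField(params, mutationOn)
  found <- list()
  addPoint <- function(x) {
    res <- max(abs(field(x)))
    if (res > tol) return(invisible(NULL))
    for (fp in found) {
      if (max(abs(fp$x - x)) < dedupTol) return(invisible(NULL))
    }
    found[[length(found) + 1L]] <<- list(x = stats::setNames(x, nms), residual = res)
    invisible(NULL)
  }
  newtonOnSupport <- function(sup, x0) {
    x <- x0
    fr <- function(u) {
      full <- numeric(nT)
      full[sup] <- u
      field(full)[sup]
    }
    for (it in 1:60) {
      Fv <- fr(x)
      if (max(abs(Fv)) < tol / 2) break
      J <- numJacobian(fr, x)
      step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      ok <- FALSE
      n0 <- max(abs(Fv))
      for (h in 1:40) {
        xn <- x + lam * step
        if (all(is.finite(xn)) && max(abs(fr(xn))) < n0) { ok <- TRUE; break }
        lam <- lam / 2
      }
      if (!ok) return(NULL)
      x <- x + lam * step
      if (max(abs(x)) > 1e6) return(NULL)
    }
    if (max(abs(fr(x))) >= tol) return(NULL)
    if (any(x < dedupTol)) return(NULL)   # belongs to a smaller support
    full <- numeric(nT)
    full[sup] <- x
    full
  }
  # flow the support-clamped field for a while: endpoints of the invariant
  # subspace dynamics are good Newton seeds for attracting points
  flowSeed <- function(sup, level) {
    x0 <- numeric(nT)
    x0[sup] <- level
    rhs <- function(t, y, p) {
      y[!sup] <- 0
      dy <- field(pmax(y, 0))
      dy[!sup] <- 0
      list(dy)
    }
    out <- tryCatch(
      suppressWarnings(
        deSolve::ode(y = x0, times = c(0, 150, 300), func = rhs, parms = NULL,
                     method = "lsoda", rtol = 1e-7, atol = 1e-9)
      ),
      error = function(e) NULL
    )
    if (is.null(out) || nrow(out) < 3) return(NULL)
    y <- pmax(as.numeric(out[nrow(out), -1]), 0)
    y[sup]
  }
  addPoint(numeric(nT))  # the origin: always a candidate
  for (mask in 1:(2^nT - 1)) {
    sup <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(nT - 1L))))
    for (s in seeds) {
      sol <- newtonOnSupport(sup, rep(s, sum(sup)))
      if (!is.null(sol)) addPoint(sol)
    }
    for (s in seeds[c(1, length(seeds))]) {
      fs <- flowSeed(sup, s)
      if (!is.null(fs) && all(is.finite(fs))) {
        sol <- newtonOnSupport(sup, fs)
        if (!is.null(sol)) addPoint(sol)
      }
    }
  }
  for (xs in extraSeeds) {
    xv <- denseVec(xs, nms, "extraSeeds")
    sup <- xv > 0
    if (!any(sup)) next
    sol <- newtonOnSupport(sup, xv[sup])
    if (!is.null(sol)) addPoint(sol)
  }
  lapply(found, function(fp) {
    classifyStability(fp, params, mutationOn = mutationOn)
  })
}

#' Linear stability of a fixed point
#'
#' Evaluates the Jacobian of [vectorField()] by central differences (step
#' scaled to each density's magnitude) and classifies the point by the
#' maximal real part of its spectrum: strictly negative is stable, any
#' strictly positive is unstable, within tolerance of zero is marginal. A
#' point sitting exactly on the birth-rate floor boundary (where the field
#' is non-smooth) is flagged and classified marginal.
#'
#' @param fp a fixed point (list with `x`, `residual`) as produced by
#'   [findFixedPoints()], or a named density vector.
#' @param params a [ModelParams-class].
#' @param restrictToSupport assess stability within the invariant subspace
#'   spanned by the point's support only (the Jacobian restricted to the
#'   support coordinates).
#' @param tol spectral tolerance for the marginal classification.
#' @param mutationOn include mutation terms in the field.
#' @return the fixed point list augmented with `eigenvalues`,
#'   `classification`, `support`, `label`, `floorActive` (and
#'   `restrictedTo` when `restrictToSupport`).
#' @export
classifyStability <- function(fp, params, restrictToSupport = FALSE,
                              tol = 1e-8, mutationOn = FALSE) {
  nms <- traitNames(params@space)
  if (is.numeric(fp)) fp <- list(x = denseVec(fp, nms, "fp"), residual = NA_real_)
  x <- unname(fp$x[nms])
  field <- makeField(params, mutationOn)
  if (is.na(fp$residual)) fp$residual <- max(abs(field(x)))
  present <- fp$x > 1e-8
  fp$support <- nms[present]
  fp$label <- supportLabel(nms, present)
  # floor boundary: some phenotype's birth-reduction sum equals its birth rate
  em <- engineModel(params)
  nP <- em$nP
  Sb <- as.numeric(em$Cb %*% x[seq_len(nP)])
  fp$floorActive <- any(present[seq_len(nP)] & abs(em$b - Sb) < 1e-7 &
                          (em$b > 0 | Sb > 0))
  J <- numJacobian(field, x)
  if (restrictToSupport) {
    J <- J[present, present, drop = FALSE]
    fp$restrictedTo <- fp$support
  }
  ev <- eigen(J, only.values = TRUE)$values
  fp$eigenvalues <- ev
  mx <- if (length(ev)) max(Re(ev)) else -Inf
  fp$classification <- if (fp$floorActive) {
    "marginal"
  } else if (mx < -tol) {
    "stable"
  } else if (mx > tol) {
    "unstable"
  } else {
    "marginal"
  }
  class(fp) <- "FixedPoint"
  fp
}

#' @export
print.FixedPoint <- function(x, ...) {
  cat(x$label, "(", x$classification, ")  residual", format(x$residual, digits = 3), "\n")
  print(round(x$x, 6))
  cat("max Re(eigenvalue):", format(max(Re(x$eigenvalues)), digits = 6), "\n")
  invisible(x)
}
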