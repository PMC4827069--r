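#' @useDynLib immunoSSA, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

kindNames <- c(
  "cancer_birth", "cancer_death_natural", "cancer_death_competition",
  "cancer_death_excess_brc", "cancer_death_therapy", "cancer_switch",
  "tcell_birth", "tcell_death", "cytokine_decay", "mutant_birth"
)

# Flatten a ModelParams into the plain-array form the engines consume.
engineModel <- function(params) {
  sp <- params@space
  P <- phenotypes(sp)
  Z <- tcellTypes(sp)
  W <- cytokineTypes(sp)
  list(
    nP = length(P), nZ = length(Z), nW = length(W),
    b = unname(params@cancer$b), d = unname(params@cancer$d),
    C = unname(params@cancer$c), Cb = unname(params@cancer$c_b),
    Tkill = unname(params@cancer$t_kill),
    killBurst = unname(params@cancer$kill_burst),
    Snat = unname(params@cancer$s_nat),
    Scyt = unname(params@cancer$s_cyt),
    muP = unname(effectiveMu(params)),
    mlaw = unname(params@cancer$m_law),
    bT = unname(params@tcells$b_T), dT = unname(params@tcells$d_T),
    Tprod = unname(params@tcells$t_prod),
    repBurst = unname(params@tcells$rep_burst),
    dW = unname(params@cytokines$d_W),
    K = params@K
  )
}

traitIdx <- function(space, trait) {
  i <- match(trait, traitNames(space))
  if (any(is.na(i))) stop("trait(s) not in space: ", paste(trait[is.na(i)], collapse = ", "))
  i
}

# Per-individual rate components -------------------------------------------------

#' Effective per-individual birth and death rate components of a cancer cell
#'
#' Competition acts on the birth rate through the birth-reducing kernel
#' `c_b` until the birth rate is floored at zero; any excess then acts as an
#' additional death rate. The usual competition kernel `c` and the therapy
#' kernel `t_kill` contribute death components. Interaction sums are taken
#' over the scaled measure excluding the focal individual's own 1/K
#' contribution.
#'
#' @param state a [PopulationState-class].
#' @param params a [ModelParams-class].
#' @param trait a phenotype identifier.
#' @return list with components `B_eff` (per-individual birth rate),
#'   `D_extra_brc` (excess birth reduction acting as death), `D_comp`,
#'   `D_therapy`. At most one of `B_eff`, `D_extra_brc` is positive.
#' @export
effectiveCancerRates <- function(state, params, trait) {
  sp <- params@space
  P <- phenotypes(sp)
  if (!trait %in% P) stop("trait not in space: ", trait)
  K <- params@K
  n <- state@counts
  Sb <- 0; Sd <- 0
  for (j in P) {
    nuj <- (n[j] - (j == trait) * min(n[trait], 1)) / K
    Sb <- Sb + params@cancer$c_b[trait, j] * nuj
    Sd <- Sd + params@cancer$c[trait, j] * nuj
  }
  Beff <- params@cancer$b[trait] - Sb
  Dbrc <- 0
  if (Beff < 0) { Dbrc <- -Beff; Beff <- 0 }
  Dther <- 0
  for (z in tcellTypes(sp)) {
    Dther <- Dther + params@cancer$t_kill[trait, z] * (n[z] / K)
  }
  list(B_eff = unname(Beff), D_extra_brc = unname(Dbrc),
       D_comp = unname(Sd), D_therapy = unname(Dther))
}

#' Per-individual phenotypic switch rate
#'
#' Natural rate plus the cytokine-induced rate, the latter proportional to
#' the scaled cytokine density.
#'
#' @param state a [PopulationState-class].
#' @param params a [ModelParams-class].
#' @param from,to phenotype identifiers of the same genotype.
#' @return numeric per-individual rate (per day).
#' @export
switchRate <- function(state, params, from, to) {
  sp <- params@space
  gof <- genotypeOf(sp)
  if (!from %in% names(gof) || !to %in% names(gof)) stop("unknown phenotype")
  if (gof[from] != gof[to]) {
    stop("cross-genotype switch requested: ", from, " -> ", to,
         " (switching never changes the genotype)")
  }
  if (from == to) stop("switch source and destination coincide")
  r <- params@cancer$s_nat[from, to]
  for (w in cytokineTypes(sp)) {
    r <- r + params@cancer$s_cyt[w, from, to] * (state@counts[w] / params@K)
  }
  unname(r)
}

#' Enumerate all event channels of a population state
#'
#' Channels are listed in the canonical order used by the simulation engine:
#' for each phenotype with positive count, birth (clonal/mutant resolved at
#' draw time), natural death, competition death, excess birth-reduction
#' death, therapy death per T-cell type, then switches per destination; then
#' per T-cell type birth and death; then cytokine decays.
#'
#' @param state a [PopulationState-class].
#' @param params a [ModelParams-class].
#' @param frozen optional character vector of traits held fixed (they
#'   contribute to interaction sums but generate no events).
#' @return data.frame with columns kind, actor, target, rate, and attribute
#'   `"total"` = sum of rates (0 iff no event is possible).
#' @export
buildChannels <- function(state, params, frozen = character()) {
  sp <- params@space
  P <- phenotypes(sp)
  Z <- tcellTypes(sp)
  W <- cytokineTypes(sp)
  K <- params@K
  n <- state@counts
  muP <- effectiveMu(params)
  kind <- character(); actor <- character(); target <- character(); rate <- numeric()
  total <- 0
  push <- function(k, a, tg, r) {
    r <- unname(r)
    kind[length(kind) + 1L] <<- k
    actor[length(actor) + 1L] <<- a
    target[length(target) + 1L] <<- tg
    total <<- total + r
    rate[length(rate) + 1L] <<- r
  }
  for (i in P) {
    if (n[i] <= 0 || i %in% frozen) next
    Sb <- 0; Sd <- 0
    for (j in P) {
      nuj <- (n[j] - (j == i)) / K
      Sb <- Sb + params@cancer$c_b[i, j] * nuj
      Sd <- Sd + params@cancer$c[i, j] * nuj
    }
    Beff <- params@cancer$b[i] - Sb
    Dbrc <- 0
    if (Beff < 0) { Dbrc <- -Beff; Beff <- 0 }
    push("cancer_birth", i, NA_character_, n[i] * Beff)
    push("cancer_death_natural", i, NA_character_, n[i] * params@cancer$d[i])
    push("cancer_death_competition", i, NA_character_, n[i] * Sd)
    push("cancer_death_excess_brc", i, NA_character_, n[i] * Dbrc)
    for (z in Z) {
      push("cancer_death_therapy", i, z, n[i] * params@cancer$t_kill[i, z] * (n[z] / K))
    }
    for (j in P) {
      if (j == i) next
      sr <- params@cancer$s_nat[i, j]
      for (w in W) sr <- sr + params@cancer$s_cyt[w, i, j] * (n[w] / K)
      if (sr > 0) push("cancer_switch", i, j, n[i] * sr)
    }
  }
  for (z in Z) {
    if (n[z] <= 0 || z %in% frozen) next
    prey <- params@tcells$b_T[z]
    for (p in P) prey <- prey + params@tcells$t_prod[z, p] * (n[p] / K)
    push("tcell_birth", z, NA_character_, n[z] * prey)
    push("tcell_death", z, NA_character_, n[z] * params@tcells$d_T[z])
  }
  for (w in W) {
    if (n[w] <= 0 || w %in% frozen) next
    push("cytokine_decay", w, NA_character_, n[w] * params@cytokines$d_W[w])
  }
  out <- data.frame(kind = kind, actor = actor, target = target, rate = rate,
                    stringsAsFactors = FALSE)
  out <- out[out$rate > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}

#' Draw the next event (waiting time and channel)
#'
#' Waiting time is exponential with the total rate; the channel is chosen
#' with probability proportional to its rate, ties at cumulative-sum
#' boundaries resolved by canonical channel order.
#'
#' @param channels output of [buildChannels()] with positive total rate.
#' @return list with `dt` (days) and `channel` (one-row data.frame).
#' @export
drawEvent <- function(channels) {
  total <- attr(channels, "total")
  if (is.null(total) || total <= 0) {
    stop("absorbing state: total event rate is zero")
  }
  u1 <- stats::runif(1)
  dt <- -log(u1) / total
  u2 <- stats::runif(1)
  cumr <- 0
  k <- nrow(channels)
  targetVal <- u2 * total
  for (q in seq_len(nrow(channels))) {
    cumr <- cumr + channels$rate[q]
    if (cumr >= targetVal) { k <- q; break }
  }
  list(dt = dt, channel = channels[k, , drop = FALSE])
}

#' Apply one event to a population state
#'
#' Cancer births resolve mutation at application time: with the genotype's
#' mutation probability the newborn is drawn from the mutation law instead
#' of copying the parent. Therapy deaths and T-cell reproductions add their
#' deterministic cytokine bursts.
#'
#' @param state a [PopulationState-class].
#' @param channel one-row data.frame as returned in [drawEvent()].
#' @param params a [ModelParams-class].
#' @param dt time increment to add to the state's clock (default 0).
#' @return a new [PopulationState-class].
#' @export
applyEvent <- function(state, channel, params, dt = 0) {
  sp <- params@space
  n <- state@counts
  kind <- channel$kind
  a <- channel$actor
  tg <- channel$target
  if (n[a] <= 0) stop("cannot apply event: actor '", a, "' has count 0")
  muP <- effectiveMu(params)
  W <- cytokineTypes(sp)
  mutated <- FALSE
  switch(kind,
    cancer_birth = {
      mutant <- FALSE
      if (muP[a] > 0) mutant <- stats::runif(1) < muP[a]
      if (mutant) {
        u4 <- stats::runif(1)
        acc <- 0
        dest <- a
        for (j in phenotypes(sp)) {
          acc <- acc + params@cancer$m_law[a, j]
          if (u4 < acc) { dest <- j; break }
        }
        n[dest] <- n[dest] + 1
        mutated <- TRUE
      } else {
        n[a] <- n[a] + 1
      }
    },
    cancer_death_natural = { n[a] <- n[a] - 1 },
    cancer_death_competition = { n[a] <- n[a] - 1 },
    cancer_death_excess_brc = { n[a] <- n[a] - 1 },
    cancer_death_therapy = {
      n[a] <- n[a] - 1
      for (w in W) n[w] <- n[w] + params@cancer$kill_burst[a, tg, w]
    },
    cancer_switch = {
      n[a] <- n[a] - 1
      n[tg] <- n[tg] + 1
    },
    tcell_birth = {
      n[a] <- n[a] + 1
      for (w in W) n[w] <- n[w] + params@tcells$rep_burst[a, w]
    },
    tcell_death = { n[a] <- n[a] - 1 },
    cytokine_decay = { n[a] <- n[a] - 1 },
    stop("unknown event kind: ", kind)
  )
  out <- new("PopulationState", time = state@time + dt, counts = n)
  attr(out, "mutated") <- mutated
  out
}

# Full simulation ----------------------------------------------------------------

#' Exact stochastic simulation of the tumour-immune jump process
#'
#' Gillespie algorithm: every event of the continuous-time Markov process is
#' simulated. States are recorded on a regular time grid plus the stop time.
#' The compiled engine (`engine = "cpp"`) and the pure-R reference engine
#' consume the RNG stream identically, so both produce the same trajectory
#' under the same seed.
#'
#' @param initial a [PopulationState-class] (or named count vector).
#' @param params a [ModelParams-class].
#' @param tMax horizon in days.
#' @param seed RNG seed for this run (NULL = use current RNG state).
#' @param recordDt recording grid spacing in days.
#' @param schedule optional data.frame(time, trait, count) of scheduled
#'   injections (e.g. T-cell doses).
#' @param engine "cpp" (compiled) or "R" (reference implementation).
#' @param frozen character vector of traits held fixed at their initial
#'   counts: they interact but generate no events (used for the
#'   resident-frozen branching-process approximation).
#' @param stopTumourExtinct stop as soon as all cancer counts are zero.
#' @param thresholdTraits,thresholdCount optional stop rule: stop with
#'   reason "threshold" when the summed count over `thresholdTraits`
#'   reaches `thresholdCount`, or "group_extinct" when it hits zero.
#' @param maxEvents hard event-count guard.
#' @return a [Trajectory-class].
#' @examples
#' sp <- TraitSpace("g", list(g = "p"))
#' pars <- ModelParams(sp, K = 100, cancer = list(b = c(p = 0), d = c(p = 1)))
#' tr <- simulateSSA(populationState(sp, c(p = 100)), pars, tMax = 50, seed = 1)
#' stopReason(tr)
#' @export
simulateSSA <- function(initial, params, tMax, seed = NULL, recordDt = 0.5,
                        schedule = NULL, engine = c("cpp", "R"),
                        frozen = character(), stopTumourExtinct = FALSE,
                        thresholdTraits = character(), thresholdCount = Inf,
                        maxEvents = 2e9) {
  engine <- match.arg(engine)
  sp <- params@space
  nms <- traitNames(sp)
  if (!is(initial, "PopulationState")) {
    initial <- populationState(sp, initial)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule) || nrow(schedule) == 0L) {
    schedule <- data.frame(time = numeric(), trait = character(),
                           count = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(schedule) > 0L) {
    if (is.unsorted(schedule$time)) stop("schedule times must be sorted")
    if (any(schedule$time < 0)) stop("injection times must be >= 0")
  }
  frozenMask <- nms %in% frozen
  thrIdx <- if (length(thresholdTraits)) traitIdx(sp, thresholdTraits) - 1L else integer()

  if (engine == "cpp") {
    res <- ssa_run_cpp(
      engineModel(params), unname(initial@counts), initial@time, tMax,
      recordDt, schedule$time, traitIdx(sp, schedule$trait) - 1L,
      as.numeric(schedule$count), frozenMask, stopTumourExtinct,
      thrIdx, thresholdCount, maxEvents
    )
  } else {
    res <- ssaRunR(params, unname(initial@counts), initial@time, tMax,
                   recordDt, schedule, frozenMask, stopTumourExtinct,
                   thrIdx + 1L, thresholdCount, maxEvents)
  }
  counts <- res$counts
  colnames(counts) <- nms
  names(res$eventCounts) <- kindNames
  new("Trajectory",
    times = res$times, counts = counts, cumMutations = res$cumMutations,
    K = params@K, seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
    stopReason = res$stopReason, paramsHash = paramsHash(params),
    eventCounts = res$eventCounts
  )
}

# Pure-R reference engine: mirrors the compiled engine's channel order and
# RNG consumption exactly (two uniforms per iteration, plus the mutation
# draws inside a cancer birth). Intended for small instances and for
# cross-checking the compiled engine.
ssaRunR <- function(params, init, t0, tMax, recordDt, schedule, frozenMask,
                    stopTumourExtinct, thrIdx, thresholdCount, maxEvents) {
  em <- engineModel(params)
  nP <- em$nP; nZ <- em$nZ; nW <- em$nW
  nT <- nP + nZ + nW
  n <- as.numeric(init)
  K <- em$K
  schedTimes <- schedule$time
  schedTrait <- if (nrow(schedule)) traitIdx(params@space, schedule$trait) else integer()
  schedCount <- schedule$count
  recT <- numeric(); recX <- NULL; recMut <- numeric()
  rows <- list()
  cumMut <- 0
  evCount <- numeric(10)
  t <- t0
  gridNext <- t0 + recordDt
  schedIdx <- 1L
  nSched <- length(schedTimes)
  stopReason <- "t_max"
  nEvents <- 0
  useThr <- length(thrIdx) > 0

  rec <- function(tt) {
    rows[[length(rows) + 1L]] <<- c(tt, n, cumMut)
  }
  recUpTo <- function(tNew) {
    while (gridNext <= tNew + 1e-12 && gridNext <= tMax + 1e-12) {
      rec(gridNext)
      gridNext <<- gridNext + recordDt
    }
  }
  rec(t0)
  while (schedIdx <= nSched && schedTimes[schedIdx] <= t0) {
    n[schedTrait[schedIdx]] <- n[schedTrait[schedIdx]] + schedCount[schedIdx]
    schedIdx <- schedIdx + 1L
  }

  repeat {
    if (nEvents >= maxEvents) { stopReason <- "max_events"; break }
    # build channels (order mirrors the compiled engine)
    ck <- integer(); ca <- integer(); ct <- integer(); cr <- numeric()
    total <- 0
    for (i in seq_len(nP)) {
      if (n[i] <= 0 || frozenMask[i]) next
      Sb <- 0; Sd <- 0
      for (j in seq_len(nP)) {
        nuj <- (n[j] - (j == i)) / K
        Sb <- Sb + em$Cb[i, j] * nuj
        Sd <- Sd + em$C[i, j] * nuj
      }
      Beff <- em$b[i] - Sb; Dbrc <- 0
      if (Beff < 0) { Dbrc <- -Beff; Beff <- 0 }
      for (piece in 1:4) {
        r <- switch(piece, n[i] * Beff, n[i] * em$d[i], n[i] * Sd, n[i] * Dbrc)
        total <- total + r
        ck <- c(ck, piece - 1L); ca <- c(ca, i); ct <- c(ct, -1L); cr <- c(cr, total)
      }
      for (z in seq_len(nZ)) {
        r <- n[i] * em$Tkill[i, z] * (n[nP + z] / K)
        total <- total + r
        ck <- c(ck, 4L); ca <- c(ca, i); ct <- c(ct, z); cr <- c(cr, total)
      }
      for (j in seq_len(nP)) {
        if (j == i) next
        sr <- em$Snat[i, j]
        for (w in seq_len(nW)) sr <- sr + em$Scyt[w, i, j] * (n[nP + nZ + w] / K)
        if (sr > 0) {
          total <- total + n[i] * sr
          ck <- c(ck, 5L); ca <- c(ca, i); ct <- c(ct, j); cr <- c(cr, total)
        }
      }
    }
    for (z in seq_len(nZ)) {
      if (n[nP + z] <= 0 || frozenMask[nP + z]) next
      prey <- em$bT[z]
      for (p in seq_len(nP)) prey <- prey + em$Tprod[z, p] * (n[p] / K)
      total <- total + n[nP + z] * prey
      ck <- c(ck, 6L); ca <- c(ca, z); ct <- c(ct, -1L); cr <- c(cr, total)
      total <- total + n[nP + z] * em$dT[z]
      ck <- c(ck, 7L); ca <- c(ca, z); ct <- c(ct, -1L); cr <- c(cr, total)
    }
    for (w in seq_len(nW)) {
      if (n[nP + nZ + w] <= 0 || frozenMask[nP + nZ + w]) next
      total <- total + n[nP + nZ + w] * em$dW[w]
      ck <- c(ck, 8L); ca <- c(ca, w); ct <- c(ct, -1L); cr <- c(cr, total)
    }

    if (total <= 0) {
      if (sum(n) == 0) { stopReason <- "all_extinct"; break }
      if (schedIdx <= nSched && schedTimes[schedIdx] <= tMax) {
        tInj <- schedTimes[schedIdx]
        recUpTo(tInj); t <- tInj
        while (schedIdx <= nSched && schedTimes[schedIdx] <= t) {
          n[schedTrait[schedIdx]] <- n[schedTrait[schedIdx]] + schedCount[schedIdx]
          schedIdx <- schedIdx + 1L
        }
        next
      }
      recUpTo(tMax); t <- tMax; stopReason <- "t_max"; break
    }

    u1 <- stats::runif(1)
    dt <- -log(u1) / total
    u2 <- stats::runif(1)
    tNew <- t + dt
    if (schedIdx <= nSched && schedTimes[schedIdx] <= tNew && schedTimes[schedIdx] <= tMax) {
      tInj <- schedTimes[schedIdx]
      recUpTo(tInj); t <- tInj
      while (schedIdx <= nSched && schedTimes[schedIdx] <= t) {
        n[schedTrait[schedIdx]] <- n[schedTrait[schedIdx]] + schedCount[schedIdx]
        schedIdx <- schedIdx + 1L
      }
      next
    }
    if (tNew > tMax) { recUpTo(tMax); t <- tMax; stopReason <- "t_max"; break }
    recUpTo(tNew); t <- tNew

    targetVal <- u2 * total
    k <- length(cr)
    for (q in seq_along(cr)) {
      if (cr[q] >= targetVal) { k <- q; break }
    }
    kind <- ck[k]; a <- ca[k]; tg <- ct[k]
    if (kind == 0L) {             # cancer birth
      mutant <- FALSE
      if (em$muP[a] > 0) mutant <- stats::runif(1) < em$muP[a]
      if (mutant) {
        u4 <- stats::runif(1)
        acc <- 0; dest <- a
        for (j in seq_len(nP)) {
          acc <- acc + em$mlaw[a, j]
          if (u4 < acc) { dest <- j; break }
        }
        cumMut <- cumMut + 1
        evCount[10] <- evCount[10] + 1
        if (!frozenMask[dest]) n[dest] <- n[dest] + 1
      } else {
        n[a] <- n[a] + 1
      }
      evCount[1] <- evCount[1] + 1
    } else if (kind %in% c(1L, 2L, 3L)) {
      n[a] <- n[a] - 1
      evCount[kind + 1L] <- evCount[kind + 1L] + 1
    } else if (kind == 4L) {      # therapy kill by T-cell tg
      n[a] <- n[a] - 1
      for (w in seq_len(nW)) {
        wi <- nP + nZ + w
        if (!frozenMask[wi]) n[wi] <- n[wi] + em$killBurst[a, tg, w]
      }
      evCount[5] <- evCount[5] + 1
    } else if (kind == 5L) {      # switch
      n[a] <- n[a] - 1
      n[tg] <- n[tg] + 1
      evCount[6] <- evCount[6] + 1
    } else if (kind == 6L) {      # T-cell birth
      n[nP + a] <- n[nP + a] + 1
      for (w in seq_len(nW)) {
        wi <- nP + nZ + w
        if (!frozenMask[wi]) n[wi] <- n[wi] + em$repBurst[a, w]
      }
      evCount[7] <- evCount[7] + 1
    } else if (kind == 7L) {
      n[nP + a] <- n[nP + a] - 1
      evCount[8] <- evCount[8] + 1
    } else {
      n[nP + nZ + a] <- n[nP + nZ + a] - 1
      evCount[9] <- evCount[9] + 1
    }
    nEvents <- nEvents + 1

    if (useThr) {
      g <- sum(n[thrIdx])
      if (g >= thresholdCount) { stopReason <- "threshold"; break }
      if (g <= 0) { stopReason <- "group_extinct"; break }
    }
    if (sum(n) == 0) {
      if (schedIdx <= nSched && schedTimes[schedIdx] <= tMax) next
      stopReason <- "all_extinct"; break
    }
    if (stopTumourExtinct && sum(n[seq_len(nP)]) == 0) {
      stopReason <- "tumour_extinct"; break
    }
  }
  if (length(rows) == 0L || rows[[length(rows)]][1] < t - 1e-12) rec(t)
  m <- do.call(rbind, rows)
  list(times = m[, 1], counts = m[, 2:(nT + 1), drop = FALSE],
       cumMutations = m[, nT + 2], stopReason = stopReason,
       eventCounts = evCount, nEvents = nEvents,
       finalTime = t, finalCounts = n)
}

# Trajectory accessors -------------------------------------------------------------

#' Trajectory accessors
#'
#' `trajTimes()` returns record times, `trajCounts()` the raw count matrix,
#' `scaledCounts()` counts divided by K, `stopReason()` why the run ended,
#' `cumMutations()` the cumulative mutant-birth count at each record,
#' `eventCounts()` total event tallies by kind.
#'
#' @param traj a [Trajectory-class].
#' @name trajectory-accessors
NULL

#' @rdname trajectory-accessors
#' @export
trajTimes <- function(traj) traj@times

#' @rdname trajectory-accessors
#' @export
trajCounts <- function(traj) traj@counts

#' @rdname trajectory-accessors
#' @export
scaledCounts <- function(traj) traj@counts / traj@K

#' @rdname trajectory-accessors
#' @export
stopReason <- function(traj) traj@stopReason

#' @rdname trajectory-accessors
#' @export
cumMutations <- function(traj) traj@cumMutations

#' @rdname trajectory-accessors
#' @export
eventCounts <- function(traj) traj@eventCounts

#' Final state of a trajectory
#' @param traj a [Trajectory-class].
#' @return named numeric vector of counts at the last record.
#' @export
finalCounts <- function(traj) {
  traj@counts[nrow(traj@counts), ]
}

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "records over",
      format(object@times[length(object@times)] - object@times[1]), "days;",
      "stop:", object@stopReason, "\n")
  cat("final counts:\n")
  print(finalCounts(object))
})

#' Coerce a trajectory to a data.frame
#' @param x a [Trajectory-class].
#' @param ... ignored.
#' @return data.frame with time, one raw-count column per trait, and the
#'   cumulative mutant-birth count.
#' @export
as.data.frame.Trajectory <- function(x, ...) {
  data.frame(time = x@times, x@counts, cumMutations = x@cumMutations,
             check.names = FALSE)
}
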