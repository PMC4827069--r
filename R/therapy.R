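# Therapy scenarios: replicate ensembles of the stochastic system with
# scheduled T-cell injections, and state-based classification of each run
# into the closed outcome set (cure, differentiated/dedifferentiated
# relapse, coexistence, T-cell extinctions).

#' Construct a therapy scenario
#'
#' @param params a [ModelParams-class].
#' @param initialCounts named integer vector: tumour initiation state.
#' @param schedule data.frame(time, trait, count): T-cell injections;
#'   times must be >= 0 and sorted, injected traits must be T-cell types.
#' @param tMax horizon (days).
#' @param replicates ensemble size.
#' @param baseSeed base RNG seed (replicate i uses baseSeed + i).
#' @param meta list of scenario metadata; recognised keys:
#'   `diffPhenotypes` (phenotypes counted as differentiated),
#'   `relapseFrac` (default 0.9: relapse when the tumour regains this
#'   fraction of its pre-treatment count), `microscopicFrac` (default 0.01:
#'   remission while below this fraction), `majorityFrac` (default 0.5),
#'   `recordDt`, `cellsPerMm3`, `description`.
#' @return a [Scenario-class].
#' @export
Scenario <- function(params, initialCounts, schedule = NULL, tMax,
                     replicates = 1, baseSeed = 1, meta = list()) {
  sp <- params@space
  init <- denseVec(initialCounts, traitNames(sp), "initialCounts")
  if (is.null(schedule)) {
    schedule <- data.frame(time = numeric(), trait = character(),
                           count = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(schedule)) {
    if (any(!schedule$trait %in% tcellTypes(sp))) {
      stop("injected traits must be T-cell types")
    }
    if (any(schedule$time < 0)) stop("injection times must be >= 0")
    if (is.unsorted(schedule$time)) stop("injection times must be sorted")
  }
  new("Scenario",
    params = params, initialCounts = init, schedule = schedule,
    tMax = as.numeric(tMax), replicates = as.numeric(replicates),
    baseSeed = as.numeric(baseSeed), meta = meta
  )
}

setMethod("show", "Scenario", function(object) {
  cat("Scenario:", if (!is.null(object@meta$description)) object@meta$description else "", "\n")
  cat("  K =", object@params@K, ", tMax =", object@tMax, "days,",
      object@replicates, "replicate(s)\n")
  nz <- object@initialCounts[object@initialCounts > 0]
  cat("  initial counts:", paste(sprintf("%s=%g", names(nz), nz), collapse = ", "), "\n")
  if (nrow(object@schedule)) {
    cat("  injections:\n")
    print(object@schedule)
  }
})

scenarioThresholds <- function(scenario) {
  meta <- scenario@meta
  sp <- scenario@params@space
  list(
    diffPhenotypes = if (!is.null(meta$diffPhenotypes)) meta$diffPhenotypes else phenotypes(sp)[1],
    relapseFrac = if (!is.null(meta$relapseFrac)) meta$relapseFrac else 0.9,
    microscopicFrac = if (!is.null(meta$microscopicFrac)) meta$microscopicFrac else 0.01,
    majorityFrac = if (!is.null(meta$majorityFrac)) meta$majorityFrac else 0.5
  )
}

#' Classify the outcome of a therapy run
#'
#' State-based classification: a run is a cure when the total tumour count
#' hits zero; a relapse when, after remission, the tumour regains the
#' relapse fraction of its pre-treatment count, subtyped by the majority
#' phenotype at the crossing time; otherwise coexistence (censored at the
#' horizon). Remission is the first contiguous period with total tumour
#' below the microscopic fraction of the pre-treatment count. T-cell
#' extinction times are recorded regardless of the final label, since the
#' system can pass from one scenario to another.
#'
#' @param traj a [Trajectory-class].
#' @param params the generating [ModelParams-class] (for the trait layout).
#' @param diffPhenotypes phenotypes counted as differentiated.
#' @param pretreatCount reference tumour count; default: total tumour at the
#'   treatment start time.
#' @param treatmentStart time of the first injection (0 if none).
#' @param relapseFrac,microscopicFrac,majorityFrac thresholds (fractions of
#'   the pre-treatment count / of the tumour composition).
#' @param tcellTraits T-cell types whose extinction should be tracked
#'   (default: all that are ever positive).
#' @return list: `label`, `relapseTime`, `remissionStart`,
#'   `remissionDuration`, `remissionCensored`, `diffFracAtRelapse`,
#'   `tcellExtinctions` (named vector of first-passage-to-zero times, NA if
#'   never), `cureTime`, `pretreatCount`.
#' @export
classifyOutcome <- function(traj, params, diffPhenotypes,
                            pretreatCount = NULL, treatmentStart = 0,
                            relapseFrac = 0.9, microscopicFrac = 0.01,
                            majorityFrac = 0.5, tcellTraits = NULL) {
  sp <- params@space
  P <- phenotypes(sp)
  if (!length(P)) stop("trajectory without tumour traits")
  X <- trajCounts(traj)
  tt <- trajTimes(traj)
  tum <- rowSums(X[, P, drop = FALSE])
  if (is.null(tcellTraits)) {
    zAll <- tcellTypes(sp)
    tcellTraits <- zAll[colSums(X[, zAll, drop = FALSE]) > 0]
  }
  if (is.null(pretreatCount)) {
    iRef <- max(which(tt <= treatmentStart + 1e-9), 1)
    pretreatCount <- tum[iRef]
  }

  # T-cell extinction times: first hit of zero after having been positive
  tcellExt <- stats::setNames(rep(NA_real_, length(tcellTraits)), tcellTraits)
  for (z in tcellTraits) {
    col <- X[, z]
    pos <- which(col > 0)
    if (length(pos)) {
      zero <- which(col == 0 & seq_along(col) > pos[1])
      if (length(zero)) tcellExt[z] <- tt[zero[1]]
    }
  }

  cureIdx <- which(tum == 0 & tt >= treatmentStart)
  if (length(which(tum == 0)) && tum[1] == 0 && all(tum == 0)) {
    cureIdx <- 1L   # degenerate flat-zero trajectory
  }
  cureTime <- if (length(cureIdx)) tt[cureIdx[1]] else NA_real_

  # remission: first contiguous sub-threshold period after treatment start
  micro <- microscopicFrac * pretreatCount
  after <- tt >= treatmentStart
  below <- tum < micro & after
  remStart <- remEnd <- NA_real_
  remCensored <- FALSE
  i0 <- which(below)
  if (length(i0)) {
    remStart <- tt[i0[1]]
    iUp <- which(tum >= micro & tt > remStart)
    if (length(iUp)) {
      remEnd <- tt[iUp[1]]
    } else {
      remEnd <- tt[length(tt)]
      remCensored <- TRUE
    }
  }
  remDur <- if (!is.na(remStart)) remEnd - remStart else NA_real_

  # relapse: regrowth past the threshold after remission began
  relapseTime <- NA_real_
  diffFrac <- NA_real_
  if (!is.na(remStart)) {
    iRel <- which(tum >= relapseFrac * pretreatCount & tt > remStart)
    if (length(iRel)) {
      relapseTime <- tt[iRel[1]]
      diffFrac <- sum(X[iRel[1], diffPhenotypes]) / tum[iRel[1]]
    }
  }

  label <- if (!is.na(cureTime) && (is.na(relapseTime) || cureTime < relapseTime)) {
    "cure"
  } else if (!is.na(relapseTime)) {
    if (diffFrac > majorityFrac) "relapse_differentiated" else "relapse_dedifferentiated"
  } else {
    extinct <- names(tcellExt)[!is.na(tcellExt)]
    if (length(tcellTraits) > 0 && length(extinct) == length(tcellTraits) &&
        length(tcellTraits) > 1) {
      "both_tcells_extinct"
    } else if (length(extinct) == 1) {
      paste0("tcell_", extinct, "_extinct")
    } else {
      "coexistence"
    }
  }
  list(
    label = label, relapseTime = relapseTime, remissionStart = remStart,
    remissionDuration = remDur, remissionCensored = remCensored,
    diffFracAtRelapse = diffFrac, tcellExtinctions = tcellExt,
    cureTime = cureTime, pretreatCount = pretreatCount
  )
}

wilsonCI <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Run a replicated therapy ensemble and classify every run
#'
#' Replicate i uses seed baseSeed + i, so the whole ensemble is
#' reproducible and embarrassingly parallel. Aggregate outcome frequencies
#' carry Wilson 95% confidence intervals.
#'
#' @param scenario a [Scenario-class].
#' @param engine simulation engine ("cpp" or "R").
#' @param keepTrajectories return the trajectories alongside the table.
#' @return an [OutcomeTable-class]; when `keepTrajectories`, the list of
#'   trajectories is attached as attribute `"trajectories"`.
#' @export
runEnsemble <- function(scenario, engine = "cpp", keepTrajectories = FALSE) {
  stopifnot(is(scenario, "Scenario"))
  params <- scenario@params
  th <- scenarioThresholds(scenario)
  treatStart <- if (nrow(scenario@schedule)) min(scenario@schedule$time) else 0
  recordDt <- if (!is.null(scenario@meta$recordDt)) scenario@meta$recordDt else 0.5
  n <- scenario@replicates
  rows <- vector("list", n)
  trajs <- if (keepTrajectories) vector("list", n) else NULL
  zTracked <- unique(c(
    scenario@schedule$trait,
    names(scenario@initialCounts)[scenario@initialCounts > 0 &
      names(scenario@initialCounts) %in% tcellTypes(params@space)]
  ))
  for (i in seq_len(n)) {
    seed <- scenario@baseSeed + i
    tr <- simulateSSA(populationState(params@space, scenario@initialCounts),
                      params, tMax = scenario@tMax, seed = seed,
                      recordDt = recordDt, schedule = scenario@schedule,
                      engine = engine)
    oc <- classifyOutcome(tr, params,
                          diffPhenotypes = th$diffPhenotypes,
                          treatmentStart = treatStart,
                          relapseFrac = th$relapseFrac,
                          microscopicFrac = th$microscopicFrac,
                          majorityFrac = th$majorityFrac,
                          tcellTraits = if (length(zTracked)) zTracked else NULL)
    row <- data.frame(
      seed = seed, label = oc$label, relapse_time = oc$relapseTime,
      remission_start = oc$remissionStart,
      remission_duration = oc$remissionDuration,
      remission_censored = oc$remissionCensored,
      diff_frac_at_relapse = oc$diffFracAtRelapse,
      cure_time = oc$cureTime,
      stringsAsFactors = FALSE
    )
    for (z in names(oc$tcellExtinctions)) {
      row[[paste0("ext_", z)]] <- oc$tcellExtinctions[[z]]
    }
    rows[[i]] <- row
    if (keepTrajectories) trajs[[i]] <- tr
  }
  per <- if (n > 0) do.call(rbind, rows) else
    data.frame(seed = numeric(), label = character(), relapse_time = numeric(),
               remission_start = numeric(), remission_duration = numeric(),
               remission_censored = logical(), diff_frac_at_relapse = numeric(),
               cure_time = numeric(), stringsAsFactors = FALSE)
  labs <- sort(unique(per$label))
  agg <- do.call(rbind, lapply(labs, function(l) {
    k <- sum(per$label == l)
    ci <- wilsonCI(k, n)
    data.frame(label = l, count = k, frequency = k / n,
               ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
  }))
  if (is.null(agg)) {
    agg <- data.frame(label = character(), count = numeric(),
                      frequency = numeric(), ci_lower = numeric(),
                      ci_upper = numeric(), stringsAsFactors = FALSE)
  }
  out <- new("OutcomeTable", perReplicate = per, aggregate = agg,
             scenarioName = if (!is.null(scenario@meta$name)) scenario@meta$name else "")
  if (keepTrajectories) attr(out, "trajectories") <- trajs
  out
}

setMethod("show", "OutcomeTable", function(object) {
  cat("OutcomeTable", if (nzchar(object@scenarioName)) paste0("(", object@scenarioName, ")"),
      ":", nrow(object@perReplicate), "replicate(s)\n")
  if (nrow(object@aggregate)) print(object@aggregate, row.names = FALSE)
})

#' Outcome table accessors
#' @param x an [OutcomeTable-class].
#' @name outcome-accessors
NULL

#' @rdname outcome-accessors
#' @export
perReplicate <- function(x) x@perReplicate

#' @rdname outcome-accessors
#' @export
outcomeFrequencies <- function(x) x@aggregate

# Diameter read-out ----------------------------------------------------------------

#' Tumour diameter from total cell count
#'
#' Maps a cell count to the diameter (mm) of a sphere holding that many
#' cells at the given tissue density: d = 2 (3N / (4 pi rho))^(1/3).
#' Monotone in N and zero at N = 0.
#'
#' @param N total cancer cell count (vectorized, >= 0).
#' @param cellsPerMm3 tissue density (cells per cubic millimetre).
#' @return diameter in millimetres.
#' @export
diameterFromCount <- function(N, cellsPerMm3 = 1e6) {
  if (any(N < 0)) stop("cell count must be non-negative")
  if (cellsPerMm3 <= 0) stop("cellsPerMm3 must be positive")
  2 * (3 * N / (4 * pi * cellsPerMm3))^(1 / 3)
}

#' Inverse of [diameterFromCount()]
#' @param mm diameter in millimetres.
#' @param cellsPerMm3 tissue density.
#' @return cell count.
#' @export
countFromDiameter <- function(mm, cellsPerMm3 = 1e6) {
  if (any(mm < 0)) stop("diameter must be non-negative")
  cellsPerMm3 * (4 / 3) * pi * (mm / 2)^3
}
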