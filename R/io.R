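# Configuration parsing, serialization and run manifests.

matToNested <- function(m) {
  out <- list()
  for (r in rownames(m)) {
    nz <- colnames(m)[m[r, ] != 0]
    if (length(nz)) out[[r]] <- as.list(stats::setNames(m[r, nz], nz))
  }
  out
}

arr3ToNested <- function(a) {
  dn <- dimnames(a)
  out <- list()
  for (i in dn[[1]]) {
    sub <- matToNested(a[i, , , drop = TRUE])
    # single middle dimension drops to a vector; rebuild
    if (length(dim(a)) == 3 && length(dn[[2]]) == 1) {
      m <- matrix(a[i, , ], 1, length(dn[[3]]), dimnames = list(dn[[2]], dn[[3]]))
      sub <- matToNested(m)
    }
    if (length(sub)) out[[i]] <- sub
  }
  out
}

vecToList <- function(v) {
  nz <- v[v != 0]
  as.list(nz)
}

#' Canonical list representation of a parameter set
#'
#' Stable key ordering; zero kernel entries are omitted (kernels are dense
#' with absent entries zero, so the representation round-trips exactly).
#'
#' @param params a [ModelParams-class].
#' @return nested list suitable for JSON/YAML serialization.
#' @export
paramsAsList <- function(params) {
  sp <- params@space
  list(
    space = list(
      genotypes = as.list(sp@genotypes),
      phenotypes = lapply(sp@phenotypesOf[sp@genotypes], as.list),
      tcells = as.list(sp@tcellTypes),
      cytokines = as.list(sp@cytokineTypes)
    ),
    cancer = list(
      b = vecToList(params@cancer$b),
      d = vecToList(params@cancer$d),
      c = matToNested(params@cancer$c),
      c_b = matToNested(params@cancer$c_b),
      t_kill = matToNested(params@cancer$t_kill),
      kill_burst = arr3ToNested(params@cancer$kill_burst),
      s_nat = matToNested(params@cancer$s_nat),
      s_cyt = arr3ToNested(params@cancer$s_cyt),
      mu = vecToList(params@cancer$mu),
      m_law = matToNested(params@cancer$m_law)
    ),
    tcells = list(
      b_T = vecToList(params@tcells$b_T),
      d_T = vecToList(params@tcells$d_T),
      t_prod = matToNested(params@tcells$t_prod),
      rep_burst = matToNested(params@tcells$rep_burst)
    ),
    cytokines = list(d_W = vecToList(params@cytokines$d_W)),
    K = params@K,
    mu_scaling = params@muScaling
  )
}

#' JSON round-trip serialization of model parameters
#'
#' @param params a [ModelParams-class].
#' @return JSON string with stable key ordering.
#' @export
paramsToJSON <- function(params) {
  as.character(jsonlite::toJSON(paramsAsList(params), auto_unbox = TRUE,
                                digits = NA))
}

listToParams <- function(cfg, where = "config") {
  need <- function(x, nm) {
    if (is.null(x)) stop(where, ": missing required section '", nm, "'")
    x
  }
  spc <- need(cfg$space, "space")
  known <- c("genotypes", "phenotypes", "tcells", "cytokines")
  unknown <- setdiff(names(spc), known)
  if (length(unknown)) stop(where, ": unknown key(s) in space: ", paste(unknown, collapse = ", "))
  space <- TraitSpace(
    genotypes = unlist(spc$genotypes),
    phenotypesOf = lapply(spc$phenotypes, unlist),
    tcellTypes = if (is.null(spc$tcells)) character() else unlist(spc$tcells),
    cytokineTypes = if (is.null(spc$cytokines)) character() else unlist(spc$cytokines)
  )
  if (length(tcellTypes(space)) && is.null(cfg$tcells)) {
    stop(where, ": T-cell traits declared but section 'tcells' is missing")
  }
  if (length(cytokineTypes(space)) && is.null(cfg$cytokines)) {
    stop(where, ": cytokine traits declared but section 'cytokines' is missing")
  }
  chkKeys <- function(sec, nm, known) {
    unknown <- setdiff(names(sec), known)
    if (length(unknown)) {
      stop(where, ": unknown key(s) in ", nm, ": ", paste(unknown, collapse = ", "))
    }
  }
  chkKeys(cfg$cancer, "cancer",
          c("b", "d", "c", "c_b", "t_kill", "kill_burst", "s_nat", "s_cyt", "mu", "m_law"))
  chkKeys(cfg$tcells, "tcells", c("b_T", "d_T", "t_prod", "rep_burst"))
  chkKeys(cfg$cytokines, "cytokines", "d_W")
  ModelParams(
    space = space,
    K = need(cfg$K, "K"),
    cancer = if (is.null(cfg$cancer)) list() else cfg$cancer,
    tcells = if (is.null(cfg$tcells)) list() else cfg$tcells,
    cytokines = if (is.null(cfg$cytokines)) list() else cfg$cytokines,
    muScaling = if (is.null(cfg$mu_scaling)) list(rule = "constant") else cfg$mu_scaling
  )
}

#' Parse model parameters from a JSON string
#' @param json output of [paramsToJSON()].
#' @return a [ModelParams-class].
#' @export
paramsFromJSON <- function(json) {
  listToParams(jsonlite::fromJSON(json, simplifyVector = FALSE), "json")
}

#' Load a model configuration file
#'
#' YAML configuration with sections `space`, `cancer`, `tcells`,
#' `cytokines`, `K`, `mu_scaling` plus optional `init` (initial counts) and
#' `run` (t_max, record_dt, replicates, base_seed, schedule, meta). Unknown
#' keys are rejected with their paths; the parameter set must pass
#' [validateParameters()].
#'
#' @param path file path.
#' @return list with `params` ([ModelParams-class]) and, when `init`/`run`
#'   are present, `scenario` ([Scenario-class]).
#' @examples
#' cfg <- system.file("extdata", "one_tcell_qualitative.yaml",
#'                    package = "immunoSSA")
#' loaded <- loadConfig(cfg)
#' traitNames(loaded$params)
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("space", "cancer", "tcells", "cytokines", "K", "mu_scaling",
             "init", "run")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("config: unknown top-level key(s): ", paste(unknown, collapse = ", "))
  }
  params <- listToParams(cfg, basename(path))
  viol <- validateParameters(params)
  if (length(viol)) {
    stop("invalid parameters in ", path, ":\n  ", paste(viol, collapse = "\n  "))
  }
  out <- list(params = params)
  if (!is.null(cfg$init) || !is.null(cfg$run)) {
    run <- if (is.null(cfg$run)) list() else cfg$run
    chk <- setdiff(names(run), c("t_max", "record_dt", "replicates",
                                 "base_seed", "schedule", "meta",
                                 "mutant_genotype", "brc"))
    if (length(chk)) stop("config: unknown key(s) in run: ", paste(chk, collapse = ", "))
    sched <- NULL
    if (!is.null(run$schedule)) {
      sched <- do.call(rbind, lapply(run$schedule, function(s) {
        data.frame(time = s$time, trait = s$trait, count = s$count,
                   stringsAsFactors = FALSE)
      }))
      sched <- sched[order(sched$time), , drop = FALSE]
    }
    init <- if (is.null(cfg$init$counts)) numeric() else unlist(cfg$init$counts)
    meta <- if (is.null(run$meta)) list() else run$meta
    if (!is.null(run$mutant_genotype)) meta$mutantGenotype <- run$mutant_genotype
    if (!is.null(run$brc)) meta$brc <- run$brc
    out$scenario <- Scenario(
      params = params, initialCounts = init, schedule = sched,
      tMax = if (is.null(run$t_max)) 100 else run$t_max,
      replicates = if (is.null(run$replicates)) 1 else run$replicates,
      baseSeed = if (is.null(run$base_seed)) 1 else run$base_seed,
      meta = c(meta, list(recordDt = if (is.null(run$record_dt)) 0.5 else run$record_dt))
    )
  }
  out
}

#' Write a scenario (parameters + run settings) as a YAML config
#' @param scenario a [Scenario-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeConfig <- function(scenario, path) {
  cfg <- paramsAsList(scenario@params)
  init <- scenario@initialCounts[scenario@initialCounts > 0]
  cfg$init <- list(counts = as.list(init))
  cfg$run <- list(
    t_max = scenario@tMax,
    replicates = scenario@replicates,
    base_seed = scenario@baseSeed
  )
  if (nrow(scenario@schedule)) {
    cfg$run$schedule <- lapply(seq_len(nrow(scenario@schedule)), function(i) {
      as.list(scenario@schedule[i, c("time", "trait", "count")])
    })
  }
  meta <- scenario@meta
  meta$recordDt <- NULL
  if (length(meta)) cfg$run$meta <- meta
  yaml::write_yaml(cfg, path)
  invisible(path)
}

fmt12 <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Write a trajectory as TSV with a JSON sidecar
#'
#' Tab-separated table (time, one raw-count column per trait, cumulative
#' mutation count) at 12 significant digits, plus `<path>.json` with the
#' parameter fingerprint, seed, K and stop reason.
#'
#' @param traj a [Trajectory-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeTrajectoryTSV <- function(traj, path) {
  df <- as.data.frame(traj)
  out <- vapply(df, fmt12, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(df)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  side <- list(params_hash = traj@paramsHash, seed = traj@seed, K = traj@K,
               stop_reason = traj@stopReason,
               event_counts = as.list(traj@eventCounts))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a fixed-point report as JSON
#' @param fps list of fixed points from [findFixedPoints()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeFixedPointReport <- function(fps, path) {
  rep <- lapply(fps, function(fp) {
    list(
      label = fp$label,
      support = as.list(fp$support),
      densities = as.list(fp$x),
      residual = fp$residual,
      eigenvalues_re = as.list(Re(fp$eigenvalues)),
      eigenvalues_im = as.list(Im(fp$eigenvalues)),
      classification = fp$classification,
      floor_active = fp$floorActive
    )
  })
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an invasion-fitness report as JSON
#' @param inv an [InvasionResult-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeFitnessReport <- function(inv, path) {
  rep <- list(
    genotype = inv@A@genotype,
    resident = as.list(inv@A@resident[inv@A@resident > 0]),
    A = apply(inv@A@A, 1, as.list),
    lambda1 = inv@lambda1,
    v = as.list(inv@v),
    supercritical = inv@supercritical,
    irreducible = inv@irreducible
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the command, config path and content hash, base seed, package
#' version, wall-clock start/end and every output file of the run.
#'
#' @param outDir output directory.
#' @param command CLI command or function name.
#' @param configPath path of the config used (optional).
#' @param baseSeed seed.
#' @param files character vector of output file names (relative to outDir).
#' @param started POSIXct start time.
#' @return path of the manifest, invisibly.
#' @export
writeManifest <- function(outDir, command, configPath = NULL, baseSeed = NA,
                          files = character(), started = Sys.time()) {
  cfgHash <- if (!is.null(configPath) && file.exists(configPath)) {
    djb2(paste(readLines(configPath, warn = FALSE), collapse = "\n"))
  } else NA_character_
  man <- list(
    command = command,
    config = configPath,
    config_hash = cfgHash,
    base_seed = baseSeed,
    version = as.character(utils::packageVersion("immunoSSA")),
    started = format(started, "%Y-%m-%dT%H:%M:%S"),
    ended = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    files = as.list(files)
  )
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
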