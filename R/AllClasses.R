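#' @import methods
NULL

#' Trait space of the tumour-immune model
#'
#' The finite set of actor types: cancer cells characterised by a
#' (genotype, phenotype) pair, T-cell types and cytokine types. Phenotype
#' identifiers must be globally unique so that per-phenotype rate maps are
#' unambiguous. The canonical ordering (genotypes in declared order,
#' phenotypes within genotype, then T-cells, then cytokines) fixes the
#' index layout of every vector and matrix downstream.
#'
#' @slot genotypes character vector of genotype identifiers.
#' @slot phenotypesOf named list mapping each genotype to its ordered
#'   phenotype identifiers.
#' @slot tcellTypes character vector of T-cell type identifiers.
#' @slot cytokineTypes character vector of cytokine identifiers.
#'
#' @seealso [TraitSpace()] for the user constructor.
#' @export
setClass("TraitSpace",
  representation(
    genotypes = "character",
    phenotypesOf = "list",
    tcellTypes = "character",
    cytokineTypes = "character"
  )
)

#' Full parameter set of the stochastic tumour-immune model
#'
#' Holds the trait space, all rate constants and kernels, and the carrying
#' capacity K that scales population sizes (an individual carries weight
#' 1/K in the scaled population measure). Kernels are stored dense over the
#' declared trait space; absent entries are zero.
#'
#' @slot space a [TraitSpace-class].
#' @slot cancer list of cancer-cell parameters: per-phenotype birth `b` and
#'   death `d` rates (per day), death-competition kernel `c` and
#'   birth-reducing competition kernel `c_b` (phenotype x phenotype, per day
#'   per unit of scaled density), therapy kill kernel `t_kill`
#'   (phenotype x T-cell type), integer cytokine bursts at kill events
#'   `kill_burst` (phenotype x T-cell x cytokine), natural switch kernel
#'   `s_nat` and cytokine-induced switch kernel `s_cyt` (within-genotype
#'   only), per-genotype mutation probability `mu`, and mutation law `m_law`
#'   (row-stochastic over target phenotypes, zero diagonal).
#' @slot tcells list: per-type birth `b_T` and death `d_T` rates, prey-driven
#'   reproduction kernel `t_prod` (T-cell x phenotype), integer cytokine
#'   bursts at reproduction `rep_burst` (T-cell x cytokine).
#' @slot cytokines list: per-type decay rate `d_W`.
#' @slot K numeric scalar carrying capacity (>= 1).
#' @slot muScaling list with elements `rule` ("constant" or "K_logK") and
#'   `mu_bar`; under "K_logK" the effective mutation probability is
#'   mu_bar / (K log K), the scaling under which a mutation of order one
#'   occurs while the population grows by order K.
#'
#' @seealso [ModelParams()], [validateParameters()]
#' @export
setClass("ModelParams",
  representation(
    space = "TraitSpace",
    cancer = "list",
    tcells = "list",
    cytokines = "list",
    K = "numeric",
    muScaling = "list"
  )
)

#' Integer population state at a time point
#'
#' Raw individual counts per trait. The scaled measure assigns each trait
#' the value counts/K.
#'
#' @slot time time in days.
#' @slot counts named integer vector over all traits in canonical order.
#' @export
setClass("PopulationState",
  representation(time = "numeric", counts = "numeric")
)

#' Recorded time series of a stochastic or deterministic run
#'
#' @slot times strictly increasing record times (days).
#' @slot counts numeric matrix, one row per record, one column per trait
#'   (raw counts for stochastic runs, scaled densities times K are not
#'   stored -- use [scaledCounts()]).
#' @slot cumMutations cumulative number of mutant birth events at each
#'   record time (stochastic runs; zeros for deterministic).
#' @slot K carrying capacity used.
#' @slot seed RNG seed of the run (NA for deterministic).
#' @slot stopReason one of "t_max", "all_extinct", "tumour_extinct",
#'   "max_events", "threshold", "group_extinct", "deterministic".
#' @slot paramsHash fingerprint of the generating [ModelParams-class].
#' @slot eventCounts named numeric vector of total event counts by kind.
#' @export
setClass("Trajectory",
  representation(
    times = "numeric",
    counts = "matrix",
    cumMutations = "numeric",
    K = "numeric",
    seed = "numeric",
    stopReason = "character",
    paramsHash = "character",
    eventCounts = "numeric"
  )
)

#' A therapy experiment: model, initial state, injection schedule, ensemble size
#'
#' @slot params a [ModelParams-class].
#' @slot initialCounts named integer vector of initial individual counts.
#' @slot schedule data.frame with columns time, trait, count: T-cell
#'   injections applied at the given times.
#' @slot tMax simulation horizon in days.
#' @slot replicates ensemble size.
#' @slot baseSeed base RNG seed; replicate i uses baseSeed + i.
#' @slot meta list of scenario metadata (differentiated phenotypes, outcome
#'   thresholds, diameter calibration, human-readable description).
#' @export
setClass("Scenario",
  representation(
    params = "ModelParams",
    initialCounts = "numeric",
    schedule = "data.frame",
    tMax = "numeric",
    replicates = "numeric",
    baseSeed = "numeric",
    meta = "list"
  )
)

#' Per-replicate outcomes and ensemble frequencies of a therapy scenario
#'
#' @slot perReplicate data.frame with one row per replicate: seed, label,
#'   relapse time (days, NA if none), remission duration (days, NA if none),
#'   tumour composition at relapse, T-cell extinction times.
#' @slot aggregate data.frame: label, frequency, Wilson 95% confidence bounds.
#' @slot scenarioName character.
#' @export
setClass("OutcomeTable",
  representation(
    perReplicate = "data.frame",
    aggregate = "data.frame",
    scenarioName = "character"
  )
)

#' Mean matrix of the multi-type branching process for a rare mutant
#'
#' The generator A of the mean dynamics dn/dt = A n of a mutant clone with
#' phenotype structure, evaluated against a resident equilibrium. Column j
#' feeds row i: A[i, j] for i != j is the switch rate from phenotype j to
#' phenotype i (so off-diagonal entries are non-negative).
#'
#' @slot A square numeric matrix over the mutant genotype's phenotypes.
#' @slot phenotypes character vector naming rows/columns.
#' @slot genotype the mutant genotype.
#' @slot resident named numeric vector of resident equilibrium densities.
#' @export
setClass("MeanMatrix",
  representation(
    A = "matrix",
    phenotypes = "character",
    genotype = "character",
    resident = "numeric"
  )
)

#' Invasion fitness of a phenotype-structured mutant
#'
#' @slot lambda1 largest real eigenvalue of the mean matrix (per day); the
#'   invasion fitness: the clone grows with positive probability iff
#'   lambda1 > 0.
#' @slot v normalized right eigenvector: asymptotic phenotype proportions of
#'   a surviving clone.
#' @slot supercritical logical, lambda1 > 0.
#' @slot irreducible logical: the switch graph is strongly connected.
#' @slot A the underlying [MeanMatrix-class].
#' @export
setClass("InvasionResult",
  representation(
    lambda1 = "numeric",
    v = "numeric",
    supercritical = "logical",
    irreducible = "logical",
    A = "MeanMatrix"
  )
)
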