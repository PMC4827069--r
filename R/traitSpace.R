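#' Construct a trait space
#'
#' @param genotypes character vector of genotype identifiers.
#' @param phenotypesOf named list mapping each genotype to its phenotype
#'   identifiers. Phenotype identifiers must be unique across genotypes.
#' @param tcellTypes character vector of T-cell type identifiers (may be
#'   empty).
#' @param cytokineTypes character vector of cytokine identifiers (may be
#'   empty).
#'
#' @return a [TraitSpace-class] object.
#' @examples
#' sp <- TraitSpace(
#'   genotypes = "mel",
#'   phenotypesOf = list(mel = c("D", "U")),
#'   tcellTypes = "zx", cytokineTypes = "tnf"
#' )
#' traitNames(sp)
#' @export
TraitSpace <- function(genotypes, phenotypesOf, tcellTypes = character(),
                       cytokineTypes = character()) {
  obj <- new("TraitSpace",
    genotypes = as.character(genotypes),
    phenotypesOf = lapply(phenotypesOf, as.character),
    tcellTypes = as.character(tcellTypes),
    cytokineTypes = as.character(cytokineTypes)
  )
  validObject(obj)
  obj
}

setValidity("TraitSpace", function(object) {
  msg <- character()
  if (length(object@genotypes) == 0L) {
    msg <- c(msg, "at least one genotype is required")
  }
  if (anyDuplicated(object@genotypes)) {
    msg <- c(msg, "duplicate genotype identifiers")
  }
  if (!setequal(names(object@phenotypesOf), object@genotypes)) {
    msg <- c(msg, "phenotypesOf must have exactly one entry per genotype")
  }
  phen <- unlist(object@phenotypesOf, use.names = FALSE)
  if (length(phen) == 0L) {
    msg <- c(msg, "at least one phenotype is required")
  }
  if (anyDuplicated(phen)) {
    msg <- c(msg, "phenotype identifiers must be unique across genotypes")
  }
  if (anyDuplicated(object@tcellTypes)) {
    msg <- c(msg, "duplicate T-cell type identifiers")
  }
  if (anyDuplicated(object@cytokineTypes)) {
    msg <- c(msg, "duplicate cytokine identifiers")
  }
  all <- c(phen, object@tcellTypes, object@cytokineTypes)
  if (anyDuplicated(all)) {
    msg <- c(msg, "trait identifiers must be unique across classes")
  }
  if (length(msg)) msg else TRUE
})

#' Trait accessors
#'
#' `phenotypes()` returns all cancer phenotypes in canonical order;
#' `tcellTypes()` and `cytokineTypes()` the other actor classes;
#' `traitNames()` the full canonical trait vector (phenotypes, then T-cells,
#' then cytokines); `genotypeOf()` the genotype of each phenotype;
#' `nTraits()` the total trait count.
#'
#' @param space a [TraitSpace-class] (or [ModelParams-class], whose space is
#'   used).
#' @return character vectors (named, for `genotypeOf`).
#' @name trait-accessors
NULL

asSpace <- function(space) {
  if (is(space, "ModelParams")) space@space else space
}

#' @rdname trait-accessors
#' @export
phenotypes <- function(space) {
  space <- asSpace(space)
  unlist(space@phenotypesOf[space@genotypes], use.names = FALSE)
}

#' @rdname trait-accessors
#' @export
tcellTypes <- function(space) asSpace(space)@tcellTypes

#' @rdname trait-accessors
#' @export
cytokineTypes <- function(space) asSpace(space)@cytokineTypes

#' @rdname trait-accessors
#' @export
traitNames <- function(space) {
  space <- asSpace(space)
  c(phenotypes(space), space@tcellTypes, space@cytokineTypes)
}

#' @rdname trait-accessors
#' @export
genotypeOf <- function(space) {
  space <- asSpace(space)
  g <- rep(space@genotypes, vapply(space@phenotypesOf[space@genotypes],
    length,
    integer(1)
  ))
  names(g) <- phenotypes(space)
  g
}

#' @rdname trait-accessors
#' @export
nTraits <- function(space) length(traitNames(space))

setMethod("show", "TraitSpace", function(object) {
  cat("TraitSpace:", length(phenotypes(object)), "cancer (genotype,phenotype) pairs,",
      length(object@tcellTypes), "T-cell type(s),",
      length(object@cytokineTypes), "cytokine(s)\n")
  for (g in object@genotypes) {
    cat("  genotype", g, ": phenotypes",
        paste(object@phenotypesOf[[g]], collapse = ", "), "\n")
  }
  if (length(object@tcellTypes)) {
    cat("  T-cells:", paste(object@tcellTypes, collapse = ", "), "\n")
  }
  if (length(object@cytokineTypes)) {
    cat("  cytokines:", paste(object@cytokineTypes, collapse = ", "), "\n")
  }
})
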