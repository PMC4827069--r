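# Small model builders used across the suite.

# single cancer type, constant rates, optional competition
singleTypeModel <- function(b = 2, d = 1, c = 0, c_b = 0, K = 100) {
  sp <- TraitSpace("g", list(g = "p"))
  ModelParams(sp, K = K, cancer = list(
    b = c(p = b), d = c(p = d),
    c = matrix(c, 1, 1, dimnames = list("p", "p")),
    c_b = matrix(c_b, 1, 1, dimnames = list("p", "p"))
  ))
}

# two phenotypes of one genotype with symmetric natural switching
twoPhenotypeModel <- function(b = c(2, 2), d = c(1, 1), s12 = 0.5, s21 = 0.5,
                              c = 0, K = 100) {
  sp <- TraitSpace("g", list(g = c("p1", "p2")))
  ModelParams(sp, K = K, cancer = list(
    b = c(p1 = b[1], p2 = b[2]), d = c(p1 = d[1], p2 = d[2]),
    c = matrix(c, 2, 2, dimnames = list(c("p1", "p2"), c("p1", "p2"))),
    s_nat = list(p1 = list(p2 = s12), p2 = list(p1 = s21))
  ))
}

# resident genotype g (one phenotype) + mutant genotype gm (k phenotypes)
residentMutantModel <- function(bMut, dMut, cMutRes, sw, K = 1e4,
                                bRes = 3, dRes = 1, cRes = 1, mu = 0) {
  k <- length(bMut)
  phen <- paste0("q", seq_len(k))
  sp <- TraitSpace(c("g", "gm"), list(g = "p", gm = phen))
  cmat <- matrix(0, k + 1, k + 1, dimnames = list(c("p", phen), c("p", phen)))
  cmat["p", "p"] <- cRes
  for (i in seq_len(k)) cmat[phen[i], "p"] <- cMutRes[i]
  snat <- matrix(0, k + 1, k + 1, dimnames = dimnames(cmat))
  if (k > 1) {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) snat[phen[i], phen[j]] <- sw[i, j]
    }
  }
  mlaw <- NULL
  if (mu > 0) {
    mlaw <- matrix(0, k + 1, k + 1, dimnames = dimnames(cmat))
    mlaw["p", phen] <- 1 / k
  }
  ModelParams(sp, K = K, cancer = list(
    b = stats::setNames(c(bRes, bMut), c("p", phen)),
    d = stats::setNames(c(dRes, dMut), c("p", phen)),
    c = cmat, s_nat = snat,
    mu = c(g = mu, gm = 0), m_law = mlaw
  ))
}
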