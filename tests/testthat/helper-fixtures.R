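# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# tiny two-site toy with hand-computable AMOVA decomposition:
# 2 sites x 2 mothers x 2 gametes, 1 locus; alleles 1,1,2,2 | 1,1,2,2
toyGametes <- function() {
  list(A = matrix(c("1", "1", "2", "2", "1", "1", "2", "2"), ncol = 1,
                  dimnames = list(NULL, "L01")),
       site = rep(c("s1", "s2"), each = 4),
       mother = rep(c("m1", "m1", "m2", "m2"), 2))
}

# small simulated world for fast property loops
smallScenario <- function(seed, fct = 0, fsc = 0, nSites = 6L,
                          mothersPerSite = 3L, fruitsPerMother = 3L,
                          seedsPerFruit = 2L, nLoci = 5L,
                          selfingRate = 0, fruitCorr = 0,
                          diversity = "high") {
  simulationScenario(name = "test", nSites = nSites,
                     mothersPerSite = mothersPerSite,
                     fruitsPerMother = fruitsPerMother,
                     seedsPerFruit = seedsPerFruit, nLoci = nLoci,
                     diversity = diversity, fct = fct, fsc = fsc,
                     selfingRate = selfingRate,
                     fruitPaternityCorrelation = fruitCorr, seed = seed)
}

# write a 2-row (1 mother, 1 seed) wide CSV and return its path
writeMinimalTable <- function(dir = tempdir()) {
  path <- file.path(dir, "minimal.csv")
  writeLines(c("role,site,mother,fruit,seed,L1.1,L1.2",
               "mother,s1,m1,,,100,102",
               "seed,s1,m1,f1,x1,100,102"), path)
  path
}

# independent SSD oracle: one-hot allele coordinates; per locus
# |x_i - x_j|^2 = 2 * [a_i != a_j], so every SSD equals half the coordinate
# sum of squares around the relevant centroids
ssdOracleOneHot <- function(A, site, mother) {
  X <- NULL
  for (l in seq_len(ncol(A))) {
    lv <- sort(unique(A[!is.na(A[, l]), l]))
    M <- outer(A[, l], lv, `==`) * 1
    M[is.na(M)] <- 0
    X <- cbind(X, M)
  }
  css <- function(idx) {
    xb <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, xb)^2)
  }
  key <- paste(site, mother)
  total <- css(seq_len(nrow(X))) / 2
  within <- sum(vapply(split(seq_len(nrow(X)), key), css, numeric(1))) / 2
  bySite <- sum(vapply(split(seq_len(nrow(X)), site), css, numeric(1))) / 2
  c(amongSites = total - bySite,
    amongMothersWithinSites = bySite - within,
    withinMothers = within, total = total)
}
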