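test_that("squared gamete distance equals the per-locus indicator sum", {
  h1 <- c("a", "b", "c", NA, "e")
  h2 <- c("a", "x", "y", "d", NA)
  A <- rbind(h1, h2, h1)
  D <- pollenDistanceMatrix(A)
  expect_equal(D[1, 2], 2)      # differ at loci 2 and 3; missings contribute 0
  expect_equal(D[1, 3], 0)      # identical haplotypes
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3))
  # brute-force loop oracle on random haplotypes with missingness
  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(sample(c(letters[1:4], NA), 8 * 6, replace = TRUE), 8, 6)
    D <- pollenDistanceMatrix(A)
    for (i in 1:7) for (j in (i + 1):8) {
      d <- 0
      for (l in 1:6)
        if (!is.na(A[i, l]) && !is.na(A[j, l]) && A[i, l] != A[j, l])
          d <- d + 1
      expect_equal(D[i, j], d)
    }
  }
})

test_that("toy decomposition reproduces the hand-computed SSDs, components and Phi", {
  toy <- toyGametes()
  D <- pollenDistanceMatrix(toy$A)
  sp <- ssdPartition(D, toy$site, toy$mother)
  expect_equal(unname(sp$ssd), c(0, 2, 0, 2))
  expect_equal(unname(sp$df), c(1, 2, 4))
  vc <- varianceComponents(D, toy$site, toy$mother)
  expect_equal(unname(vc$coef), c(2, 2, 4))        # n', n'', n'''
  expect_equal(unname(vc$sigma2), c(-0.25, 0.5, 0))
  expect_true("negativeComponent" %in% vc$flags)   # reported, never truncated
  phi <- phiStatistics(vc$sigma2)
  expect_equal(phi[["phiSC"]], 1)
  expect_equal(phi[["phiCT"]], -1)                 # -0.25 / 0.25
})

test_that("SSD partition matches the one-hot coordinate oracle and conserves the total", {
  for (s in c(101, 202, 303)) {
    sim <- simulateDataset(smallScenario(seed = s, fct = 0.05, fsc = 0.08,
                                         nSites = 4L, nLoci = 4L))
    haps <- inferPollenPool(sim$dataset)
    keep <- rowSums(is.na(haps@alleles)) == 0
    A <- haps@alleles[keep, , drop = FALSE]
    site <- as.character(haps@seeds$site[keep])
    mom <- as.character(haps@seeds$mother[keep])
    D <- pollenDistanceMatrix(A)
    sp <- ssdPartition(D, site, mom)
    oracle <- ssdOracleOneHot(A, site, mom)
    expect_equal(sp$ssd[names(oracle)], oracle, tolerance = 1e-9)
    expect_equal(sum(sp$ssd[1:3]), sp$ssd[["total"]], tolerance = 1e-9)
    expect_equal(sum(sp$df), nrow(A) - 1)
  }
})

test_that("balanced designs agree with an independent moment-solver oracle", {
  # oracle route: coordinate ANOVA mean squares + the balanced expectation
  # matrix E[MS] = C %*% sigma2, solved with solve(); never touches the
  # package's coefficient code
  sim <- simulateDataset(smallScenario(seed = 404, fct = 0.04, fsc = 0.1,
                                       nSites = 5L, mothersPerSite = 3L,
                                       fruitsPerMother = 2L, seedsPerFruit = 3L))
  haps <- inferPollenPool(sim$dataset)
  A <- haps@alleles
  stopifnot(!anyNA(A))
  site <- as.character(haps@seeds$site); mom <- as.character(haps@seeds$mother)
  D <- pollenDistanceMatrix(A)
  vc <- varianceComponents(D, site, mom)
  o <- ssdOracleOneHot(A, site, mom)
  n <- 6; m <- 3; g <- 5                     # seeds/mother, mothers/site, sites
  ms <- c(o[["amongSites"]] / (g - 1),
          o[["amongMothersWithinSites"]] / (g * m - g),
          o[["withinMothers"]] / (g * m * n - g * m))
  C <- rbind(c(n * m, n, 1),
             c(0,     n, 1),
             c(0,     0, 1))
  sig <- solve(C, ms)
  expect_equal(unname(vc$sigma2), unname(sig), tolerance = 1e-9)
})

test_that("Phi is invariant to distance scaling and label relabeling", {
  sim <- simulateDataset(smallScenario(seed = 55, fct = 0.03, fsc = 0.06))
  haps <- inferPollenPool(sim$dataset)
  site <- as.character(haps@seeds$site); mom <- as.character(haps@seeds$mother)
  D <- pollenDistanceMatrix(haps)
  phi1 <- phiStatistics(varianceComponents(D, site, mom)$sigma2)
  phi2 <- phiStatistics(varianceComponents(3.7 * D, site, mom)$sigma2)
  expect_equal(phi1, phi2, tolerance = 1e-12)
  # consistent relabeling of sites and mothers changes nothing
  site2 <- paste0("X", site); mom2 <- paste0("Y", mom)
  phi3 <- phiStatistics(varianceComponents(D, site2, mom2)$sigma2)
  expect_equal(phi1, phi3, tolerance = 1e-12)
})

test_that("degenerate designs are rejected with a named stratum", {
  toy <- toyGametes()
  D <- pollenDistanceMatrix(toy$A)
  expect_error(varianceComponents(D, rep("s1", 8), toy$mother),
               "fewer than 2 sites")
  expect_error(
    varianceComponents(D, toy$site, rep(c("m1", "m2"), c(4, 4))),
    "no replicate mothers|fewer than 2 sites")
})

test_that("zero-variance and no-differentiation edge cases behave", {
  toy <- toyGametes()
  A0 <- matrix("1", 8, 1)
  D0 <- pollenDistanceMatrix(A0)
  sp <- ssdPartition(D0, toy$site, toy$mother)
  expect_equal(unname(sp$ssd), c(0, 0, 0, 0))
  phi0 <- phiStatistics(c(0, 0, 1))
  expect_equal(unname(phi0[c("phiCT", "phiSC")]), c(0, 0))
  phiNA <- phiStatistics(c(0, 0, 0))
  expect_true(attr(phiNA, "zeroVariance"))
  expect_true(all(is.na(phiNA)))
})

test_that("phi ratio reproduces symmetry and flags a zero denominator", {
  expect_equal(unname(phiRatio(0.05, 0.05)), c(0.5, 0.5), ignore_attr = TRUE)
  bad <- phiRatio(0.02, -0.02)
  expect_true(attr(bad, "undefined"))
  expect_true(all(is.na(bad)))
})

test_that("permutation tests are valid, reproducible, and respect their strata", {
  sim <- simulateDataset(smallScenario(seed = 66, fsc = 0.15, fct = 0.05,
                                       diversity = "low"))
  haps <- inferPollenPool(sim$dataset)
  expect_error(permutationTestWithin(haps, nPerm = 0), "nPerm")
  w1 <- permutationTestWithin(haps, nPerm = 99, seed = 9)
  w2 <- permutationTestWithin(haps, nPerm = 99, seed = 9)
  expect_identical(w1$pSC, w2$pSC)
  expect_identical(w1$permPhi, w2$permPhi)
  a1 <- permutationTestAmong(haps, nPerm = 99, seed = 9)
  a2 <- permutationTestAmong(haps, nPerm = 99, seed = 9)
  expect_identical(a1$pCT, a2$pCT)
  # p-values live on the add-one grid
  expect_true(w1$pSC >= 1 / 100 && w1$pSC <= 1)
  expect_equal((w1$pSC * 100) %% 1, 0, tolerance = 1e-9)
  # strong within-site signal is detected
  expect_lte(w1$pSC, 0.05)
})

test_that("null permutation p-values are uniform (KS over replicate worlds)", {
  nrep <- 120
  pSC <- pCT <- numeric(nrep)
  for (r in seq_len(nrep)) {
    sim <- simulateDataset(smallScenario(seed = 5000 + r, nSites = 5L,
                                         mothersPerSite = 3L,
                                         fruitsPerMother = 2L,
                                         seedsPerFruit = 2L, nLoci = 4L))
    haps <- inferPollenPool(sim$dataset)
    D <- pollenDistanceMatrix(haps)
    lb <- list(s = as.character(haps@seeds$site),
               m = as.character(haps@seeds$mother))
    pSC[r] <- permutationTestWithin(haps, 99, siteLabels = lb$s,
                                    motherLabels = lb$m, D = D)$pSC
    pCT[r] <- permutationTestAmong(haps, 99, siteLabels = lb$s,
                                   motherLabels = lb$m, D = D)$pCT
  }
  # scaled-down replicate count (budget); KS at alpha = 0.01
  expect_gt(suppressWarnings(ks.test(pSC, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(pCT, "punif"))$p.value, 0.01)
})

test_that("hierAmova assembles a valid result object and report table", {
  sim <- simulateDataset(smallScenario(seed = 88, fct = 0.05, fsc = 0.1))
  haps <- inferPollenPool(sim$dataset)
  fit <- hierAmova(haps, nPerm = 49, seed = 3)
  expect_s4_class(fit, "AmovaResult")
  expect_true(validObject(fit))
  tab <- amovaTable(fit)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$df, unname(fit@df))
  expect_equal(tab$p[1:2], unname(fit@pvalues[c("pCT", "pSC")]))
  # study-shaped design bookkeeping: df = (G-1, S-G, N-S)
  expect_equal(unname(fit@df),
               c(nSites(sim$dataset) - 1,
                 nMothers(sim$dataset) - nSites(sim$dataset),
                 nSeeds(sim$dataset) - nMothers(sim$dataset)))
})
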