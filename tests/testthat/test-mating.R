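# enumeration oracles for the identity and exclusion probabilities: loop over
# every (mother, father/offspring, candidate) genotype combination under HWE

pidOracle <- function(p) {
  k <- length(p)
  tot <- 0
  for (a in 1:k) for (b in 1:k) for (x in 1:k) for (y in 1:k) {
    same <- setequal(c(a, b), c(x, y))
    tot <- tot + p[a] * p[b] * p[x] * p[y] * same
  }
  tot
}

peOracle <- function(p) {
  k <- length(p)
  tot <- 0
  for (a in 1:k) for (b in 1:k) {          # mother ordered genotype (a,b)
    pm <- p[a] * p[b]
    for (mAll in c(a, b)) {                # transmitted maternal allele
      for (cc in 1:k) {                    # true paternal allele
        off <- c(mAll, cc)
        # paternal allele set: z in offspring with the other allele maternal
        S <- unique(off[vapply(seq_along(off), function(i)
          off[-i][1] %in% c(a, b), logical(1))])
        pS <- sum(p[S])
        tot <- tot + pm * 0.5 * p[cc] * (1 - pS)^2
      }
    }
  }
  tot
}

test_that("probability of identity matches enumeration to 1e-12", {
  expect_equal(probabilityOfIdentity(list(c(0.5, 0.5)))$perLocus, 0.375,
               ignore_attr = TRUE)
  expect_equal(probabilityOfIdentity(list(c(1)))$perLocus, 1,
               ignore_attr = TRUE)  # monomorphic locus
  set.seed(7)
  for (k in 2:4) {
    p <- as.numeric(pollenflow:::.rdirichlet(rep(1, k)))
    expect_equal(probabilityOfIdentity(list(p))$perLocus, pidOracle(p),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # multilocus product
  fr <- list(c(0.5, 0.5), c(0.25, 0.75))
  pid <- probabilityOfIdentity(fr)
  expect_equal(pid$multilocus, prod(pid$perLocus), tolerance = 1e-15)
})

test_that("paternity exclusion matches enumeration to 1e-12", {
  expect_equal(exclusionProbability(list(c(0.5, 0.5)))$perLocus, 0.1875,
               ignore_attr = TRUE)
  expect_equal(exclusionProbability(list(c(1)))$perLocus, 0,
               ignore_attr = TRUE)  # nobody excludable at a monomorphic locus
  set.seed(11)
  for (k in 2:4) for (rep in 1:3) {
    p <- as.numeric(pollenflow:::.rdirichlet(rep(1, k)))
    expect_equal(exclusionProbability(list(p))$perLocus, peOracle(p),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("a diverse 11-locus battery discriminates fathers and genotypes", {
  set.seed(3)
  freqs <- lapply(1:11, function(i) {
    k <- sample(6:17, 1)
    as.numeric(pollenflow:::.rdirichlet(rep(1, k)))
  })
  pe <- exclusionProbability(freqs)
  pid <- probabilityOfIdentity(freqs)
  expect_gte(pe$multilocus, 0.99)      # analogue of a near-1 exclusion power
  expect_lt(pid$multilocus, 0.001)     # two random plants almost never match
})

test_that("selfing classifier: compatibility logic", {
  fr <- list(c(a = 0.5, b = 0.3, c = 0.2))
  # incompatible locus -> outcrossed regardless of likelihoods
  out <- classifySelfing(c("a", "b"), c("c", "c"), fr)
  expect_equal(out$call, "outcrossed")
  expect_false(out$compatible)
  expect_equal(out$posterior, 0)
  # mother homozygous everywhere, identical seed -> compatible
  fr2 <- list(c(a = 0.9, b = 0.1), c(a = 0.9, b = 0.1))
  out2 <- classifySelfing(matrix(c("a", "a", "a", "a"), 2, 2, byrow = TRUE),
                          matrix(c("a", "a", "a", "a"), 2, 2, byrow = TRUE),
                          fr2)
  expect_true(out2$compatible)
  # all loci missing -> ambiguous
  out3 <- classifySelfing(c(NA, NA), c(NA, NA), fr)
  expect_equal(out3$call, "ambiguous")
  expect_equal(out3$nInformative, 0L)
})

test_that("selfing fraction and recall recover the 10% generator truth", {
  sim <- simulateDataset(simulationScenario(
    seed = 314, fct = 0.02, fsc = 0.05, selfingRate = 0.1,
    fruitPaternityCorrelation = 0, diversity = "high",
    allelesPerLocus = 5:12))
  ds <- sim$dataset
  haps <- inferPollenPool(ds)
  calls <- selfingCalls(ds, haps@pollenFreqs, priorSelfing = 0.1)
  truth <- sim$truth$selfed
  called <- calls$call == "selfed"
  # recall of true selfed seeds at the 0.9 posterior threshold
  expect_gte(mean(called[truth]), 0.9)
  # estimated fraction within 3 binomial SE of the generating 0.1
  n <- length(truth)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(called) - 0.1), 3 * se + 1e-12)
})

test_that("Model A/B/C datasets have the right sizes and nesting", {
  sim <- simulateDataset(simulationScenario(seed = 99, selfingRate = 0.1,
                                            fruitPaternityCorrelation = 0.3))
  ds <- sim$dataset
  haps <- inferPollenPool(ds)
  calls <- selfingCalls(ds, haps@pollenFreqs)
  C <- buildModelDataset(haps, "C")
  B <- buildModelDataset(haps, "B", seed = 1)
  A <- buildModelDataset(haps, "A", calls = calls, seed = 1)
  nFruit <- nrow(unique(ds@seeds[, c("site", "mother", "fruit")]))
  expect_equal(nrow(C@seeds), 720L)      # all seeds retained
  expect_equal(nrow(B@seeds), nFruit)    # exactly one seed per fruit
  expect_lte(nrow(A@seeds), nrow(B@seeds))
  expect_lte(nrow(B@seeds), nrow(C@seeds))
  # reproducibility of the per-fruit draw
  B2 <- buildModelDataset(haps, "B", seed = 1)
  expect_identical(B@seeds, B2@seeds)
  # Model A drops every seed called selfed
  ak <- with(A@seeds, paste(site, mother, fruit, seed))
  sk <- with(calls[calls$call == "selfed", ], paste(site, mother, fruit, seed))
  expect_length(intersect(ak, sk), 0)
})

test_that("Models A and B refuse datasets without fruit identifiers", {
  sim <- simulateDataset(smallScenario(seed = 44))
  haps <- inferPollenPool(sim$dataset)
  haps@seeds$fruit <- ""
  expect_error(buildModelDataset(haps, "B"), "fruit")
  expect_s4_class(buildModelDataset(haps, "C"), "PollenHaplotypeSet")
})
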