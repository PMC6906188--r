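test_that("single-locus subtraction covers all four cases", {
  cases <- list(
    # mother, seed, expected allele, expected status
    list(c("1", "2"), c("1", "3"), "3", "unambiguous"),  # one non-maternal allele
    list(c("1", "1"), c("1", "1"), "1", "unambiguous"),  # homozygous seed
    list(c("1", "2"), c("2", "2"), "2", "unambiguous"),  # homozygous seed, het mother
    list(c("1", "2"), c("3", "4"), NA_character_, "mismatch"),
    list(c(NA, NA), c("1", "2"), NA_character_, "missing"),
    list(c("1", "2"), c("1", NA), NA_character_, "missing"))
  for (cs in cases) {
    out <- inferLocusGamete(cs[[1]], cs[[2]])
    expect_equal(out$allele, cs[[3]])
    expect_equal(out$status, cs[[4]])
  }
})

test_that("ambiguous heterozygote pairs resolve by pollen-pool posterior", {
  # both maternal-transmission hypotheses at prior 1/2, weighted by pollen
  # frequencies: P(paternal = 1) = 0.1 / (0.1 + 0.3) = 0.25 -> MAP allele 2
  out <- inferLocusGamete(c("1", "2"), c("1", "2"), c("1" = 0.1, "2" = 0.3))
  expect_equal(out$allele, "2")
  expect_equal(out$status, "resolved")
  expect_equal(out$weight, 0.75)
  expect_false(out$flag)
  # zero pollen frequencies fall back to uniform and are flagged
  out0 <- inferLocusGamete(c("1", "2"), c("1", "2"), c("1" = 0, "2" = 0))
  expect_equal(out0$weight, 0.5)
  expect_true(out0$flag)
  # posteriors are invariant to rescaling all pollen frequencies
  o1 <- inferLocusGamete(c("1", "2"), c("1", "2"), c("1" = 0.2, "2" = 0.6))
  expect_equal(o1$weight, out$weight)
  expect_equal(o1$allele, out$allele)
})

test_that("all-homozygous mothers force a fully unambiguous pollen pool", {
  mothers <- data.frame(site = c("s1", "s1"), mother = c("m1", "m2"))
  mA <- matrix(c("1", "1", "2", "2"), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("L1.1", "L1.2")))
  seeds <- data.frame(site = "s1", mother = c("m1", "m2"),
                      fruit = "f1", seed = c("x1", "x2"))
  sA <- matrix(c("1", "3", "2", "2"), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("L1.1", "L1.2")))
  ds <- genotypeDataset(mothers, mA, seeds, sA)
  haps <- inferPollenPool(ds)
  expect_true(all(haps@status == "unambiguous"))
  expect_equal(haps@report$resolved, 0L)
  expect_equal(unname(haps@alleles[, 1]), c("3", "2"))
})

test_that("inference recovers the simulated truth", {
  sim <- simulateDataset(simulationScenario(seed = 77, fct = 0.03, fsc = 0.08,
                                            selfingRate = 0.1,
                                            fruitPaternityCorrelation = 0.2))
  haps <- inferPollenPool(sim$dataset, policy = "MAP")
  expect_equal(nrow(haps@alleles), 720L)  # one haplotype per seed
  una <- haps@status == "unambiguous"
  expect_true(all(haps@alleles[una] == sim$truth$paternal[una]))
  # mismatches cannot occur in error-free data
  expect_equal(sum(haps@status == "mismatch"), 0L)
  res <- haps@status == "resolved"
  expect_gt(sum(res), 50)
  expect_true(all(haps@weight[res] >= 0.5))  # MAP keeps the majority posterior
})

test_that("resolved-locus accuracy is calibrated against the recorded posterior", {
  # calibrated world: undifferentiated pollen pools, no selfing, so the
  # whole-dataset pollen frequencies are the true resolving prior; under
  # posterior sampling P(hit) = E[q^2 + (1-q)^2] = E[recorded weight]
  set.seed(2718)
  sim <- simulateDataset(simulationScenario(seed = 161, fct = 0, fsc = 0,
                                            selfingRate = 0,
                                            fruitPaternityCorrelation = 0))
  haps <- inferPollenPool(sim$dataset, policy = "SAMPLE")
  res <- haps@status == "resolved"
  expect_gt(sum(res), 50)
  hit <- haps@alleles[res] == sim$truth$paternal[res]
  w <- haps@weight[res]
  mcse <- sqrt(sum(w * (1 - w))) / sum(res)
  expect_gte(mean(hit), mean(w) - 3 * mcse)
})

test_that("reconstruction invariant: paternal + a maternal allele rebuilds the seed", {
  sim <- simulateDataset(smallScenario(seed = 5, fct = 0.02, fsc = 0.05))
  ds <- sim$dataset
  haps <- inferPollenPool(ds)
  mk <- paste(ds@mothers$site, ds@mothers$mother)
  mi <- match(paste(ds@seeds$site, ds@seeds$mother), mk)
  for (l in seq_along(ds@loci)) {
    cols <- c(2L * l - 1L, 2L * l)
    for (i in seq_len(nSeeds(ds))) {
      if (haps@status[i, l] %in% c("mismatch", "missing")) next
      pat <- unname(haps@alleles[i, l])
      seedG <- sort(unname(ds@seedAlleles[i, cols]))
      mom <- unname(ds@motherAlleles[mi[i], cols])
      rebuilt <- vapply(mom, function(m) identical(sort(c(m, pat)), seedG),
                        logical(1))
      expect_true(any(rebuilt))
    }
  }
})

test_that("SAMPLE policy is reproducible under a fixed seed and differs from MAP occasionally", {
  sim <- simulateDataset(smallScenario(seed = 13, fsc = 0.1, nLoci = 8L))
  set.seed(123); h1 <- inferPollenPool(sim$dataset, policy = "SAMPLE")
  set.seed(123); h2 <- inferPollenPool(sim$dataset, policy = "SAMPLE")
  expect_identical(h1@alleles, h2@alleles)
  expect_identical(h1@weight, h2@weight)
})

test_that("a locus with zero unambiguous assignments falls back to uniform frequencies", {
  # single heterozygous mother whose seeds all share her genotype
  mothers <- data.frame(site = "s1", mother = "m1")
  mA <- matrix(c("1", "2"), 1, 2, dimnames = list(NULL, c("L1.1", "L1.2")))
  seeds <- data.frame(site = "s1", mother = "m1", fruit = "f1",
                      seed = c("x1", "x2"))
  sA <- matrix(c("1", "2", "1", "2"), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("L1.1", "L1.2")))
  ds <- genotypeDataset(mothers, mA, seeds, sA)
  haps <- inferPollenPool(ds)
  expect_true(haps@report$uniformFallback[1])
  expect_equal(unname(haps@pollenFreqs[[1]]), c(0.5, 0.5))
  expect_true(all(haps@status == "resolved"))
  expect_true(all(haps@weight == 0.5))
})

test_that("haplotype table export has one row per seed with status columns", {
  sim <- simulateDataset(smallScenario(seed = 17))
  haps <- inferPollenPool(sim$dataset)
  path <- file.path(tempdir(), "haps.csv")
  writeHaplotypeTable(haps, path)
  tab <- read.csv(path, colClasses = "character")
  expect_equal(nrow(tab), nSeeds(sim$dataset))
  expect_true(all(paste0(lociNames(haps), ".status") %in% names(tab)))
})
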