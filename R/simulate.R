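## Hierarchical pollen-pool world generator. Allele-frequency hierarchies use
## the Balding-Nichols construction: a subpool at differentiation F from its
## parent pool is a Dirichlet draw with concentration parent * (1 - F) / F,
## whose expected fixation index relative to the parent is F.

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(x)
  if (s == 0) {            # numerically extinct draw; put mass on argmax alpha
    x[which.max(alpha)] <- 1
    s <- 1
  }
  x / s
}

#' Draw a differentiated subpool of allele frequencies
#'
#' Balding-Nichols hierarchical Dirichlet draw: `F = 0` returns the parent
#' frequencies unchanged; `F > 0` draws
#' `Dirichlet(parent * (1 - F) / F)`, so the total concentration is
#' `(1 - F) / F` whatever the allele count and the expected fixation index of
#' many subpools relative to the parent equals `F`.
#'
#' @param parentFreqs probability vector of parent-pool allele frequencies.
#' @param F differentiation parameter in `[0, 1)`.
#' @return frequency vector of the same length (names preserved).
#' @export
drawSubpool <- function(parentFreqs, F) {
  if (F < 0 || F >= 1) stop("F must lie in [0, 1)")
  if (abs(sum(parentFreqs) - 1) > 1e-8) stop("parentFreqs must sum to 1")
  if (F == 0) return(parentFreqs)
  out <- .rdirichlet(parentFreqs * (1 - F) / F)
  stats::setNames(out, names(parentFreqs))
}

#' Construct a simulation scenario
#'
#' Defaults mirror the emulated field design: 18 sites x 4 mothers x 5 fruits
#' x 2 seeds (720 seeds), 11 microsatellite loci, high diversity (10-17
#' alleles per locus), 10% selfing, a modest within-fruit correlated-paternity
#' probability, and hierarchical pollen-pool differentiation F_CT = 0.03 /
#' F_SC = 0.06 bracketing the observed Phi range.
#'
#' @param name scenario label.
#' @param nSites,mothersPerSite,fruitsPerMother,seedsPerFruit,nLoci design sizes.
#' @param diversity `"high"` (10-17 alleles/locus) or `"low"` (4-6).
#' @param allelesPerLocus optional explicit allele-count set overriding the
#'   diversity default; each locus draws its count uniformly from this set.
#' @param fct,fsc site- and mother-level differentiation parameters.
#' @param selfingRate per-seed selfing probability.
#' @param fruitPaternityCorrelation probability all seeds of a fruit share one
#'   paternal gamete draw.
#' @param seed RNG seed (`NA` = use current RNG state).
#' @return a [SimulationScenario-class].
#' @export
simulationScenario <- function(name = "study",
                               nSites = 18L, mothersPerSite = 4L,
                               fruitsPerMother = 5L, seedsPerFruit = 2L,
                               nLoci = 11L,
                               diversity = c("high", "low"),
                               allelesPerLocus = NULL,
                               fct = 0.03, fsc = 0.06,
                               selfingRate = 0.1,
                               fruitPaternityCorrelation = 0.1,
                               seed = NA_real_) {
  diversity <- match.arg(diversity)
  if (is.null(allelesPerLocus))
    allelesPerLocus <- if (diversity == "high") 10:17 else 4:6
  new("SimulationScenario",
      name = name,
      nSites = as.integer(nSites), mothersPerSite = as.integer(mothersPerSite),
      fruitsPerMother = as.integer(fruitsPerMother),
      seedsPerFruit = as.integer(seedsPerFruit),
      nLoci = as.integer(nLoci),
      allelesPerLocus = as.integer(allelesPerLocus),
      diversity = diversity,
      fct = fct, fsc = fsc, selfingRate = selfingRate,
      fruitPaternityCorrelation = fruitPaternityCorrelation,
      seed = as.numeric(seed))
}

#' Simulate a mother-seed genotype dataset with known truth
#'
#' Per locus, global allele frequencies are a symmetric Dirichlet(1) draw;
#' site pollen pools differentiate from the global pool at `F_CT` and mother
#' pollen pools from their site pool at `F_SC` (Balding-Nichols draws).
#' Mother genotypes are HWE draws from the site-level frequencies. Each
#' fruit's seeds share a single paternal gamete draw with probability
#' `fruitPaternityCorrelation`, otherwise fathers are independent; with
#' probability `selfingRate` a seed's paternal gamete is replaced by a second
#' maternal gamete. Seed genotypes are maternal gamete + paternal gamete, so
#' generated data are Mendelian-consistent by construction.
#'
#' @param sc a [SimulationScenario-class].
#' @return list with `dataset` (a [GenotypeDataset-class]) and `truth` (list:
#'   `paternal` character matrix of true paternal gametes, `selfed` logical,
#'   `globalFreqs`, `siteFreqs`, `motherPools`).
#' @export
simulateDataset <- function(sc) {
  stopifnot(is(sc, "SimulationScenario"))
  validObject(sc)
  if (!is.na(sc@seed)) set.seed(sc@seed)
  G <- sc@nSites; M <- sc@mothersPerSite
  Fr <- sc@fruitsPerMother; Sd <- sc@seedsPerFruit
  L <- sc@nLoci
  nM <- G * M
  nS <- nM * Fr * Sd

  lociNamesV <- sprintf("L%02d", seq_len(L))
  k <- sample(sc@allelesPerLocus, L, replace = TRUE)
  globalFreqs <- lapply(seq_len(L), function(l) {
    f <- .rdirichlet(rep(1, k[l]))
    stats::setNames(f, sprintf("%03d", seq_len(k[l])))
  })
  names(globalFreqs) <- lociNamesV

  siteIds <- sprintf("S%02d", seq_len(G))
  siteFreqs <- lapply(seq_len(G), function(g)
    lapply(globalFreqs, function(f) drawSubpool(f, sc@fct)))
  names(siteFreqs) <- siteIds

  mothers <- data.frame(
    site = rep(siteIds, each = M),
    mother = rep(sprintf("M%d", seq_len(M)), times = G),
    stringsAsFactors = FALSE)
  motherPools <- vector("list", nM)
  motherAlleles <- matrix(NA_character_, nM, 2L * L)
  colnames(motherAlleles) <- as.vector(rbind(paste0(lociNamesV, ".1"),
                                             paste0(lociNamesV, ".2")))
  for (i in seq_len(nM)) {
    g <- match(mothers$site[i], siteIds)
    motherPools[[i]] <- lapply(siteFreqs[[g]], function(f) drawSubpool(f, sc@fsc))
    for (l in seq_len(L)) {
      f <- siteFreqs[[g]][[l]]
      motherAlleles[i, c(2L * l - 1L, 2L * l)] <-
        sample(names(f), 2L, replace = TRUE, prob = f)
    }
  }

  seeds <- data.frame(
    site = rep(mothers$site, each = Fr * Sd),
    mother = rep(mothers$mother, each = Fr * Sd),
    fruit = rep(rep(sprintf("F%d", seq_len(Fr)), each = Sd), times = nM),
    seed = rep(sprintf("s%d", seq_len(Sd)), times = nM * Fr),
    stringsAsFactors = FALSE)
  seedAlleles <- matrix(NA_character_, nS, 2L * L,
                        dimnames = list(NULL, colnames(motherAlleles)))
  paternal <- matrix(NA_character_, nS, L, dimnames = list(NULL, lociNamesV))
  selfed <- logical(nS)

  drawGamete <- function(pool) vapply(pool, function(f)
    sample(names(f), 1L, prob = f), character(1))
  row <- 0L
  for (i in seq_len(nM)) {
    momG <- matrix(motherAlleles[i, ], ncol = 2, byrow = TRUE)
    pool <- motherPools[[i]]
    for (fr in seq_len(Fr)) {
      sharedFather <- stats::runif(1) < sc@fruitPaternityCorrelation
      fruitGamete <- if (sharedFather) drawGamete(pool) else NULL
      for (sdi in seq_len(Sd)) {
        row <- row + 1L
        matG <- momG[cbind(seq_len(L), sample.int(2L, L, replace = TRUE))]
        isSelf <- stats::runif(1) < sc@selfingRate
        patG <- if (isSelf)
          momG[cbind(seq_len(L), sample.int(2L, L, replace = TRUE))]
        else if (sharedFather) fruitGamete
        else drawGamete(pool)
        selfed[row] <- isSelf
        paternal[row, ] <- patG
        seedAlleles[row, seq(1L, 2L * L, by = 2L)] <- matG
        seedAlleles[row, seq(2L, 2L * L, by = 2L)] <- patG
      }
    }
  }

  ## registry inferred from observed alleles (rare pool alleles may go unseen)
  ds <- genotypeDataset(mothers, motherAlleles, seeds, seedAlleles)
  list(dataset = ds,
       truth = list(paternal = paternal, selfed = selfed,
                    globalFreqs = globalFreqs, siteFreqs = siteFreqs,
                    motherPools = stats::setNames(
                      motherPools, paste(mothers$site, mothers$mother))))
}

#' The factorial grid of standard simulation scenarios
#'
#' All combinations of diversity (high, low) with among-site differentiation
#' `F_CT` in (0, 0.01, 0.05) and among-mother-within-site differentiation
#' `F_SC` in (0, 0.01, 0.08): 18 named, seeded scenarios on the study-shaped
#' design (18 sites x 4 mothers x 5 fruits x 2 seeds, 11 loci, no selfing, no
#' fruit-level paternity correlation -- the test-calibration world).
#'
#' @param baseSeed integer; scenario seeds are `baseSeed + 1:18`.
#' @return named list of [SimulationScenario-class] objects; the two
#'   no-differentiation members are named `null_high` and `null_low`.
#' @export
scenarioPresets <- function(baseSeed = 20190) {
  grid <- expand.grid(diversity = c("high", "low"),
                      fct = c(0, 0.01, 0.05),
                      fsc = c(0, 0.01, 0.08),
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  nm <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- grid$diversity[i]; a <- grid$fct[i]; b <- grid$fsc[i]
    nm[i] <- if (a == 0 && b == 0) paste0("null_", d)
             else sprintf("%s_ct%02.0f_sc%02.0f", d, 100 * a, 100 * b)
    out[[i]] <- simulationScenario(
      name = nm[i], diversity = d, fct = a, fsc = b,
      selfingRate = 0, fruitPaternityCorrelation = 0,
      seed = baseSeed + i)
  }
  stats::setNames(out, nm)
}
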