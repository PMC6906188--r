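#' @import methods
#' @importFrom stats rgamma rbinom runif sd var qnorm setNames
#' @importFrom utils read.csv write.csv head
NULL

## Central containers. Allele labels are opaque strings throughout: fragment
## sizes carry no ordering semantics here, all distances depend on identity
## only. Missing calls are NA; a half-called locus is treated as fully missing.

#' GenotypeDataset: hierarchical mother-seed codominant genotype container
#'
#' Holds the diploid multilocus genotypes of mother plants and of the seeds
#' sampled from them, keyed by site -> mother -> fruit -> seed, together with
#' the locus registry (observed allele labels per locus).
#'
#' @slot loci named list; one character vector of unique allele labels per locus.
#' @slot mothers data.frame with columns `site`, `mother` (one row per mother).
#' @slot motherAlleles character matrix, `nrow(mothers)` x `2 * nLoci`;
#'   columns are `<locus>.1`, `<locus>.2`; `NA` marks a missing locus
#'   (always both columns together).
#' @slot seeds data.frame with columns `site`, `mother`, `fruit`, `seed`.
#' @slot seedAlleles character matrix like `motherAlleles`, one row per seed.
#'
#' @export
setClass("GenotypeDataset",
  representation(
    loci = "list",
    mothers = "data.frame",
    motherAlleles = "matrix",
    seeds = "data.frame",
    seedAlleles = "matrix"
  )
)

setValidity("GenotypeDataset", function(object) {
  msg <- character()
  L <- length(object@loci)
  if (L < 1L) msg <- c(msg, "at least one locus required")
  if (is.null(names(object@loci)) || anyDuplicated(names(object@loci)))
    msg <- c(msg, "loci must be uniquely named")
  for (nm in names(object@loci)) {
    al <- object@loci[[nm]]
    if (length(al) < 1L || anyDuplicated(al))
      msg <- c(msg, sprintf("locus %s: allele labels must be unique and non-empty", nm))
  }
  if (ncol(object@motherAlleles) != 2L * L || ncol(object@seedAlleles) != 2L * L)
    msg <- c(msg, "allele matrices must have 2 columns per locus")
  if (nrow(object@motherAlleles) != nrow(object@mothers))
    msg <- c(msg, "motherAlleles rows must match mothers")
  if (nrow(object@seedAlleles) != nrow(object@seeds))
    msg <- c(msg, "seedAlleles rows must match seeds")
  mk <- paste(object@mothers$site, object@mothers$mother, sep = "\r")
  if (anyDuplicated(mk)) msg <- c(msg, "duplicate (site, mother) entries")
  if (nrow(object@seeds) > 0) {
    sk <- paste(object@seeds$site, object@seeds$mother,
                object@seeds$fruit, object@seeds$seed, sep = "\r")
    if (anyDuplicated(sk)) msg <- c(msg, "duplicate (site, mother, fruit, seed) entries")
    smk <- paste(object@seeds$site, object@seeds$mother, sep = "\r")
    if (!all(smk %in% mk)) msg <- c(msg, "every seed's mother must be present")
  }
  ## allele labels must belong to the locus registry (NA allowed)
  for (l in seq_len(L)) {
    cols <- c(2L * l - 1L, 2L * l)
    vals <- c(object@motherAlleles[, cols], object@seedAlleles[, cols])
    bad <- !is.na(vals) & !(vals %in% object@loci[[l]])
    if (any(bad))
      msg <- c(msg, sprintf("locus %s: allele label(s) outside registry", names(object@loci)[l]))
  }
  if (length(msg)) msg else TRUE
})

#' PollenHaplotypeSet: inferred haploid paternal gametes
#'
#' One row per seed: the paternal allele inferred at each locus by maternal
#' subtraction, with a per-locus provenance status and, for posterior-resolved
#' loci, the posterior weight of the chosen allele.
#'
#' @slot seeds data.frame with columns `site`, `mother`, `fruit`, `seed`.
#' @slot alleles character matrix (seeds x loci); `NA` = missing/mismatch.
#' @slot status character matrix (seeds x loci); one of `"unambiguous"`,
#'   `"resolved"`, `"mismatch"`, `"missing"`.
#' @slot weight numeric matrix (seeds x loci); posterior weight in `[0.5, 1]`
#'   for resolved loci, `NA` elsewhere.
#' @slot pollenFreqs named list of per-locus pollen-pool allele frequencies
#'   (the pass-1 frequencies used for resolution).
#' @slot report data.frame of per-locus status counts.
#'
#' @export
setClass("PollenHaplotypeSet",
  representation(
    seeds = "data.frame",
    alleles = "matrix",
    status = "matrix",
    weight = "matrix",
    pollenFreqs = "list",
    report = "data.frame"
  )
)

setValidity("PollenHaplotypeSet", function(object) {
  msg <- character()
  if (!all(dim(object@alleles) == dim(object@status)) ||
      !all(dim(object@alleles) == dim(object@weight)))
    msg <- c(msg, "alleles, status and weight matrices must share dimensions")
  if (nrow(object@alleles) != nrow(object@seeds))
    msg <- c(msg, "one haplotype row per seed required")
  ok <- object@status %in% c("unambiguous", "resolved", "mismatch", "missing")
  if (!all(ok)) msg <- c(msg, "invalid status code")
  ## MAP resolution guarantees weight >= 0.5; posterior sampling may keep the
  ## minor-posterior allele, so the container only enforces (0, 1]
  w <- object@weight[object@status == "resolved"]
  if (any(!is.na(w) & (w <= 0 | w > 1 + 1e-12)))
    msg <- c(msg, "resolved weights must lie in (0, 1]")
  if (any(!is.na(object@alleles[object@status %in% c("mismatch", "missing")])))
    msg <- c(msg, "mismatch/missing loci must carry NA alleles")
  if (length(msg)) msg else TRUE
})

#' AmovaResult: nested AMOVA decomposition of pollen haplotype distances
#'
#' Sums of squared deviations, degrees of freedom, unbalanced-design
#' coefficients, variance components, Phi-statistics and stratified
#' permutation p-values for the two-level design sites / mothers-in-sites.
#'
#' @slot ssd named numeric: `amongSites`, `amongMothersWithinSites`,
#'   `withinMothers`, `total`.
#' @slot df named numeric: degrees of freedom per stratum (`G-1`, `S-G`, `N-S`).
#' @slot ms named numeric mean squares per stratum.
#' @slot coef named numeric: unbalanced coefficients `n1` (n'), `n2` (n''),
#'   `n3` (n''').
#' @slot sigma2 named numeric variance components: `amongSites` (sigma2_a),
#'   `amongMothers` (sigma2_b), `withinMothers` (sigma2_c).
#' @slot phi named numeric: `phiCT`, `phiSC`, `phiST` (component convention
#'   `(a+b)/total`) and `phiSTadd` (additive convention `phiSC + phiCT`).
#' @slot pvalues named numeric: `pCT`, `pSC` (`NA` when not tested).
#' @slot nPerm integer number of permutations used.
#' @slot design named numeric: `nSites`, `nMothers`, `nGametes`.
#' @slot flags character vector of quality flags.
#'
#' @export
setClass("AmovaResult",
  representation(
    ssd = "numeric", df = "numeric", ms = "numeric", coef = "numeric",
    sigma2 = "numeric", phi = "numeric", pvalues = "numeric",
    nPerm = "integer", design = "numeric", flags = "character"
  )
)

setValidity("AmovaResult", function(object) {
  msg <- character()
  need <- c("amongSites", "amongMothersWithinSites", "withinMothers", "total")
  if (!all(need %in% names(object@ssd))) msg <- c(msg, "incomplete ssd slot")
  else if (abs(sum(object@ssd[need[1:3]]) - object@ssd["total"]) >
           1e-9 * max(1, abs(object@ssd["total"])))
    msg <- c(msg, "SSD components must sum to SSD total")
  if (length(object@df) == 3 && "nGametes" %in% names(object@design) &&
      abs(sum(object@df) - (object@design[["nGametes"]] - 1)) > 1e-9)
    msg <- c(msg, "df must sum to N - 1")
  if (length(msg)) msg else TRUE
})

#' SimulationScenario: generator parameters for synthetic mother-seed arrays
#'
#' Describes one hierarchical pollen-pool world: sampling design sizes, locus
#' diversity, Balding-Nichols differentiation parameters at the site
#' (`fct`) and mother-within-site (`fsc`) levels, the selfing rate and the
#' within-fruit correlated-paternity probability.
#'
#' @slot name scenario label.
#' @slot nSites,mothersPerSite,fruitsPerMother,seedsPerFruit,nLoci design sizes.
#' @slot allelesPerLocus integer vector of candidate allele counts per locus;
#'   each locus draws its count uniformly from this set.
#' @slot diversity `"high"` or `"low"` (sets `allelesPerLocus` default).
#' @slot fct,fsc differentiation parameters in `[0, 1)` for pollen pools among
#'   sites and among mothers within sites.
#' @slot selfingRate probability a seed is selfed.
#' @slot fruitPaternityCorrelation probability all seeds of a fruit share a
#'   single paternal gamete draw.
#' @slot seed RNG seed (`NA` = use current RNG state).
#'
#' @export
setClass("SimulationScenario",
  representation(
    name = "character",
    nSites = "integer", mothersPerSite = "integer",
    fruitsPerMother = "integer", seedsPerFruit = "integer",
    nLoci = "integer", allelesPerLocus = "integer", diversity = "character",
    fct = "numeric", fsc = "numeric",
    selfingRate = "numeric", fruitPaternityCorrelation = "numeric",
    seed = "numeric"
  )
)

setValidity("SimulationScenario", function(object) {
  msg <- character()
  cnt <- c(object@nSites, object@mothersPerSite, object@fruitsPerMother,
           object@seedsPerFruit, object@nLoci)
  if (any(cnt < 1L)) msg <- c(msg, "all design counts must be >= 1")
  if (any(object@allelesPerLocus < 2L)) msg <- c(msg, "loci need >= 2 alleles")
  if (object@fct < 0 || object@fct >= 1 || object@fsc < 0 || object@fsc >= 1)
    msg <- c(msg, "fct and fsc must lie in [0, 1)")
  if (object@selfingRate < 0 || object@selfingRate > 1)
    msg <- c(msg, "selfingRate must lie in [0, 1]")
  if (object@fruitPaternityCorrelation < 0 || object@fruitPaternityCorrelation > 1)
    msg <- c(msg, "fruitPaternityCorrelation must lie in [0, 1]")
  if (!object@diversity %in% c("high", "low"))
    msg <- c(msg, "diversity must be 'high' or 'low'")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn GenotypeDataset-accessors number of seeds
#' @export
nSeeds <- function(x) nrow(x@seeds)

#' Accessors for GenotypeDataset and PollenHaplotypeSet
#'
#' Small accessor helpers: design counts, locus names, seed keys.
#'
#' @param x a `GenotypeDataset` or `PollenHaplotypeSet`.
#' @return `nSeeds`, `nMothers`, `nSites`: integer counts. `lociNames`:
#'   character vector. `seedKeys`: data.frame of `site`, `mother`, `fruit`,
#'   `seed` identifiers.
#' @name GenotypeDataset-accessors
NULL

#' @describeIn GenotypeDataset-accessors number of mother plants
#' @export
nMothers <- function(x) {
  if (is(x, "GenotypeDataset")) nrow(x@mothers)
  else nrow(unique(x@seeds[, c("site", "mother")]))
}

#' @describeIn GenotypeDataset-accessors number of sites
#' @export
nSites <- function(x) {
  df <- if (is(x, "GenotypeDataset")) x@mothers else x@seeds
  length(unique(df$site))
}

#' @describeIn GenotypeDataset-accessors locus names
#' @export
lociNames <- function(x) {
  if (is(x, "GenotypeDataset")) names(x@loci) else colnames(x@alleles)
}

#' @describeIn GenotypeDataset-accessors seed identifier table
#' @export
seedKeys <- function(x) x@seeds[, c("site", "mother", "fruit", "seed")]

#' Extract the Phi-statistics of an AMOVA fit
#'
#' @param x an `AmovaResult`.
#' @return named numeric vector `phiCT`, `phiSC`, `phiST`, `phiSTadd`.
#' @export
phiValues <- function(x) x@phi

#' Extract the permutation p-values of an AMOVA fit
#'
#' @param x an `AmovaResult`.
#' @return named numeric vector `pCT`, `pSC`.
#' @export
pValues <- function(x) x@pvalues

setMethod("show", "GenotypeDataset", function(object) {
  cat(sprintf(
    "GenotypeDataset: %d seeds / %d fruits / %d mothers / %d sites, %d loci\n",
    nrow(object@seeds),
    nrow(unique(object@seeds[, c("site", "mother", "fruit")])),
    nrow(object@mothers), length(unique(object@mothers$site)),
    length(object@loci)))
  k <- vapply(object@loci, length, integer(1))
  cat(sprintf("alleles per locus: %d-%d (median %g)\n",
              min(k), max(k), stats::median(k)))
})

setMethod("show", "PollenHaplotypeSet", function(object) {
  cat(sprintf("PollenHaplotypeSet: %d gametes x %d loci\n",
              nrow(object@alleles), ncol(object@alleles)))
  tab <- table(factor(object@status,
                      c("unambiguous", "resolved", "mismatch", "missing")))
  cat("locus status: ",
      paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "AmovaResult", function(object) {
  cat("Hierarchical AMOVA (sites / mothers within sites)\n")
  src <- c("Among sites", "Among mothers within sites", "Within mothers")
  tab <- data.frame(
    source = src,
    df = object@df,
    SSD = round(object@ssd[1:3], 3),
    MS = round(object@ms, 4),
    row.names = NULL)
  print(tab, row.names = FALSE)
  cat(sprintf("sigma2: a=%.5f b=%.5f c=%.5f\n",
              object@sigma2[["amongSites"]], object@sigma2[["amongMothers"]],
              object@sigma2[["withinMothers"]]))
  cat(sprintf("PhiCT=%.4f PhiSC=%.4f PhiST=%.4f (additive %.4f)\n",
              object@phi[["phiCT"]], object@phi[["phiSC"]],
              object@phi[["phiST"]], object@phi[["phiSTadd"]]))
  if (!all(is.na(object@pvalues)))
    cat(sprintf("p (CT)=%s  p (SC)=%s  [%d permutations]\n",
                format(object@pvalues[["pCT"]]), format(object@pvalues[["pSC"]]),
                object@nPerm))
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf(
    "SimulationScenario '%s': %d sites x %d mothers x %d fruits x %d seeds, %d loci (%s diversity)\n",
    object@name, object@nSites, object@mothersPerSite, object@fruitsPerMother,
    object@seedsPerFruit, object@nLoci, object@diversity))
  cat(sprintf("F_CT=%g F_SC=%g selfing=%g fruit paternity correlation=%g seed=%s\n",
              object@fct, object@fsc, object@selfingRate,
              object@fruitPaternityCorrelation, format(object@seed)))
})
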