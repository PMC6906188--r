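## Two-level nested AMOVA (sites / mothers within sites) on haploid pollen
## gametes. Distances are per-locus identity indicators (0 same allele,
## 1 different); loci missing in either gamete contribute 0. The SSD
## partition follows the standard quadratic-form identities on squared
## distances; variance components use the unbalanced-design coefficients
## n', n'', n''' and are never truncated at zero.

#' Squared AMOVA distance matrix between pollen gametes
#'
#' `d2[i, j]` counts the loci at which gametes i and j carry different
#' alleles; loci missing in either gamete contribute 0 (optionally the count
#' is rescaled by the fraction of loci shared).
#'
#' @param haps a [PollenHaplotypeSet-class], or a character matrix of gametic
#'   alleles (rows = gametes, columns = loci, `NA` = missing).
#' @param rescale if `TRUE`, divide each pairwise count by the fraction of
#'   loci non-missing in both gametes (default `FALSE`).
#' @return numeric N x N symmetric matrix with zero diagonal; attribute
#'   `noSharedLoci` lists index pairs with zero shared loci (their distance is
#'   0 and, under `rescale`, undefined -> left 0 and flagged).
#' @export
pollenDistanceMatrix <- function(haps, rescale = FALSE) {
  A <- if (is(haps, "PollenHaplotypeSet")) haps@alleles else as.matrix(haps)
  n <- nrow(A); L <- ncol(A)
  D <- matrix(0, n, n)
  shared <- if (rescale) matrix(0, n, n) else NULL
  for (l in seq_len(L)) {
    a <- match(A[, l], sort(unique(A[!is.na(A[, l]), l])))
    obs <- !is.na(a)
    both <- outer(obs, obs, "&")
    dif <- outer(a, a, "!=")
    dif[!both] <- FALSE
    D <- D + dif
    if (rescale) shared <- shared + both
  }
  flagPairs <- NULL
  if (rescale) {
    none <- shared == 0
    if (any(none[upper.tri(none)]))
      flagPairs <- which(none & upper.tri(none), arr.ind = TRUE)
    shared[shared == 0] <- 1L
    D <- D * (L / shared)
  } else {
    ## zero-shared-loci pairs are detectable without the shared matrix only
    ## when requested; keep the cheap path unflagged unless all-missing rows
    allMiss <- rowSums(!is.na(A)) == 0L
    if (any(allMiss))
      flagPairs <- cbind(which(allMiss), NA_integer_)
  }
  diag(D) <- 0
  attr(D, "noSharedLoci") <- flagPairs
  D
}

## mother-level pair-sum matrix: B[k, l] (k != l) = sum of d2 over cross
## pairs; B[k, k] = sum over unordered within-mother pairs
.motherPairSums <- function(D, motherIdx) {
  f <- factor(motherIdx)
  M <- rowsum(D, f, reorder = TRUE)
  B <- rowsum(t(M), f, reorder = TRUE)
  diag(B) <- diag(B) / 2
  list(B = B, levels = levels(f))
}

## full decomposition from the mother-level pair sums. nk: gametes per mother,
## motherSite: site of each mother (both ordered like rows of B).
.amovaFromB <- function(B, nk, motherSite) {
  ms <- factor(motherSite)
  N <- sum(nk); S <- length(nk); G <- nlevels(ms)
  Ng <- as.numeric(rowsum(nk, ms))
  ssdWithin <- sum(diag(B) / nk)
  siteTot <- rowsum(t(rowsum(B, ms)), ms)           # G x G full sums
  pairSumSite <- (diag(siteTot) + as.numeric(rowsum(diag(B), ms))) / 2
  Tg <- pairSumSite / Ng
  totalPairSum <- (sum(B) + sum(diag(B))) / 2
  ssdTotal <- totalPairSum / N
  ssdMothers <- sum(Tg) - ssdWithin
  ssdSites <- ssdTotal - sum(Tg)
  df <- c(amongSites = G - 1, amongMothersWithinSites = S - G,
          withinMothers = N - S)
  sumk2g <- as.numeric(rowsum(nk^2, ms))
  A1 <- sum(sumk2g / Ng)
  n1 <- (N - A1) / (S - G)
  n2 <- (A1 - sum(nk^2) / N) / (G - 1)
  n3 <- (N - sum(Ng^2) / N) / (G - 1)
  msq <- c(if (G > 1) ssdSites / (G - 1) else NA_real_,
           ssdMothers / (S - G),
           ssdWithin / (N - S))
  s2c <- msq[3]
  s2b <- (msq[2] - s2c) / n1
  s2a <- if (G > 1) (msq[1] - s2c - n2 * s2b) / n3 else NA_real_
  list(ssd = c(amongSites = ssdSites, amongMothersWithinSites = ssdMothers,
               withinMothers = ssdWithin, total = ssdTotal),
       df = df, ms = msq, coef = c(n1 = n1, n2 = n2, n3 = n3),
       sigma2 = c(amongSites = s2a, amongMothers = s2b, withinMothers = s2c),
       N = N, S = S, G = G, Tg = Tg, Ng = Ng)
}

#' Partition the total SSD across the nested strata
#'
#' Gower-type decomposition of squared inter-gamete distances: total,
#' within-mother, among-mothers-within-sites and among-sites sums of squared
#' deviations, with degrees of freedom `(G-1, S-G, N-S)`.
#'
#' @param D squared distance matrix (see [pollenDistanceMatrix()]).
#' @param siteLabels,motherLabels vectors assigning each gamete (row of `D`)
#'   to its site and mother; mothers must nest within sites.
#' @return list with `ssd` (named numeric, components + total) and `df`.
#' @export
ssdPartition <- function(D, siteLabels, motherLabels) {
  key <- paste(siteLabels, motherLabels, sep = "\r")
  bp <- .motherPairSums(D, key)
  ord <- bp$levels
  nk <- as.numeric(table(factor(key, levels = ord)))
  msite <- sub("\r.*$", "", ord)
  if (length(unique(msite)) < 2)
    stop("among-sites stratum undefined: fewer than 2 sites")
  fit <- .amovaFromB(bp$B, nk, msite)
  list(ssd = fit$ssd, df = fit$df)
}

#' Variance components of the nested design
#'
#' Method-of-moments solution of the two-level nested model on squared
#' distances: `sigma2_c = SSD_within/(N-S)`, `sigma2_b = (MSD_b - sigma2_c)/n'`,
#' `sigma2_a = (MSD_a - sigma2_c - n'' sigma2_b)/n'''`, with the
#' unbalanced-design coefficients computed from the group sizes. Negative
#' components are reported as-is with a flag.
#'
#' @param D squared distance matrix.
#' @param siteLabels,motherLabels stratum assignments per gamete.
#' @return list with `ssd`, `df`, `ms`, `coef` (`n1`,`n2`,`n3`), `sigma2`,
#'   and `flags`.
#' @export
varianceComponents <- function(D, siteLabels, motherLabels) {
  key <- paste(siteLabels, motherLabels, sep = "\r")
  bp <- .motherPairSums(D, key)
  nk <- as.numeric(table(factor(key, levels = bp$levels)))
  msite <- sub("\r.*$", "", bp$levels)
  G <- length(unique(msite)); S <- length(nk)
  if (G < 2) stop("among-sites stratum undefined: fewer than 2 sites")
  if (S - G < 1) stop("among-mothers stratum undefined: no replicate mothers within sites")
  fit <- .amovaFromB(bp$B, nk, msite)
  if (fit$coef[["n1"]] <= 0)
    stop("degenerate design: coefficient n' <= 0 in the among-mothers stratum")
  if (fit$coef[["n3"]] <= 0)
    stop("degenerate design: coefficient n''' <= 0 in the among-sites stratum")
  flags <- character()
  if (any(fit$sigma2 < 0, na.rm = TRUE)) flags <- c(flags, "negativeComponent")
  c(fit[c("ssd", "df", "ms", "coef", "sigma2")], list(flags = flags))
}

#' Phi-statistics from variance components
#'
#' `PhiCT = sigma2_a / total`, `PhiSC = sigma2_b / (sigma2_b + sigma2_c)`,
#' `PhiST = (sigma2_a + sigma2_b) / total`. Values may be slightly negative in
#' the absence of differentiation and are never truncated.
#'
#' @param sigma2 named or positional numeric of length 3: among-sites,
#'   among-mothers, within-mothers components.
#' @return named numeric `phiCT`, `phiSC`, `phiST`, plus `phiSTadd`
#'   (`phiSC + phiCT`, the additive total-differentiation convention) and an
#'   attribute `zeroVariance` when the total variance is 0.
#' @export
phiStatistics <- function(sigma2) {
  a <- sigma2[[1]]; b <- sigma2[[2]]; cc <- sigma2[[3]]
  tot <- a + b + cc
  if (!is.finite(tot) || tot == 0) {
    out <- c(phiCT = NA_real_, phiSC = NA_real_, phiST = NA_real_,
             phiSTadd = NA_real_)
    attr(out, "zeroVariance") <- TRUE
    return(out)
  }
  phiCT <- a / tot
  phiSC <- if (b + cc == 0) 0 else b / (b + cc)
  c(phiCT = phiCT, phiSC = phiSC, phiST = (a + b) / tot,
    phiSTadd = phiSC + phiCT)
}

#' Split total pollen-pool differentiation into its two hierarchical shares
#'
#' Uses the additive total `PhiST = PhiSC + PhiCT`: the average
#' differentiation between pollen pools of two mothers from different sites
#' decomposes into a within-site share `PhiSC / (PhiSC + PhiCT)` and an
#' among-site share `PhiCT / (PhiSC + PhiCT)`.
#'
#' @param phiSC,phiCT the two Phi-statistics.
#' @return named numeric `withinFraction`, `amongFraction` (also rounded to 3
#'   decimals in attributes `withinFraction3`, `amongFraction3`); `NA` with a
#'   flag attribute when `phiSC + phiCT == 0`.
#' @export
phiRatio <- function(phiSC, phiCT) {
  tot <- phiSC + phiCT
  if (!is.finite(tot) || tot == 0) {
    out <- c(withinFraction = NA_real_, amongFraction = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- c(withinFraction = phiSC / tot, amongFraction = phiCT / tot)
  attr(out, "withinFraction3") <- round(out[[1]], 3)
  attr(out, "amongFraction3") <- round(out[[2]], 3)
  out
}

## permutation engines ------------------------------------------------------

## PhiSC under permutation of seed -> mother assignment within sites.
## Site totals (sum Tg), ssdTotal, and all coefficients are invariant; only
## SSD_within moves, so each permutation costs one grouped submatrix sum per
## site.
.permWithin <- function(D, siteLabels, motherLabels, nPerm, obsFit) {
  sites <- unique(siteLabels)
  ## per site: the submatrix plus the fixed mother blocks (sizes preserved
  ## under permutation; only which seeds fill each block changes)
  parts <- lapply(sites, function(s) {
    idx <- which(siteLabels == s)
    blocks <- split(seq_along(idx), motherLabels[idx])
    list(D = D[idx, idx, drop = FALSE],
         blocks = unname(blocks),
         nk = lengths(blocks), ns = length(idx))
  })
  N <- obsFit$N; S <- obsFit$S
  sumTg <- sum(obsFit$Tg)
  n1 <- obsFit$coef[["n1"]]
  dfW <- N - S; dfB <- S - obsFit$G
  phi <- numeric(nPerm)
  for (p in seq_len(nPerm)) {
    ssdW <- 0
    for (pt in parts) {
      idx <- sample.int(pt$ns)
      for (k in seq_along(pt$blocks)) {
        v <- idx[pt$blocks[[k]]]
        ## full submatrix sum double-counts each unordered pair
        ssdW <- ssdW + sum(pt$D[v, v]) / (2 * pt$nk[k])
      }
    }
    s2c <- ssdW / dfW
    msb <- (sumTg - ssdW) / dfB
    s2b <- (msb - s2c) / n1
    phi[p] <- if (s2b + s2c == 0) 0 else s2b / (s2b + s2c)
  }
  phi
}

## PhiCT under permutation of whole mothers among sites (mother keeps her
## gametes; the number of mothers per site is preserved). Works on the
## mother-level pair-sum matrix; coefficients are recomputed per permutation
## because site compositions change under unbalanced mother sizes.
.permAmong <- function(B, nk, motherSite, nPerm) {
  S <- length(nk); N <- sum(nk)
  blocks <- unname(split(seq_len(S), motherSite))   # mothers-per-site counts fixed
  G <- length(blocks)
  diagB <- diag(B)
  ssdW <- sum(diagB / nk)                 # invariant: mothers keep their seeds
  totalPairSum <- (sum(B) + sum(diagB)) / 2
  ssdTotal <- totalPairSum / N
  sumnk2 <- sum(nk^2)
  s2c <- ssdW / (N - S)
  phi <- numeric(nPerm)
  for (p in seq_len(nPerm)) {
    idx <- sample.int(S)
    sumTg <- 0; A1 <- 0; sumNg2 <- 0
    for (g in seq_len(G)) {
      v <- idx[blocks[[g]]]
      Ng <- sum(nk[v])
      sumTg <- sumTg + (sum(B[v, v]) + sum(diagB[v])) / (2 * Ng)
      A1 <- A1 + sum(nk[v]^2) / Ng
      sumNg2 <- sumNg2 + Ng^2
    }
    ssdB <- sumTg - ssdW
    ssdA <- ssdTotal - sumTg
    n1 <- (N - A1) / (S - G)
    n2 <- (A1 - sumnk2 / N) / (G - 1)
    n3 <- (N - sumNg2 / N) / (G - 1)
    s2b <- (ssdB / (S - G) - s2c) / n1
    s2a <- (ssdA / (G - 1) - s2c - n2 * s2b) / n3
    tot <- s2a + s2b + s2c
    phi[p] <- if (tot == 0) 0 else s2a / tot
  }
  phi
}

#' Stratified permutation test of among-mother (within-site) differentiation
#'
#' Permutes the gamete-to-mother assignment independently within each site,
#' preserving per-mother gamete counts and all site memberships, and compares
#' the observed `PhiSC` with its permutation distribution. The p-value uses
#' the add-one convention `(#\{Phi_perm >= Phi_obs\} + 1) / (nPerm + 1)`.
#'
#' @param haps a [PollenHaplotypeSet-class] (or character allele matrix with
#'   `siteLabels`/`motherLabels` supplied).
#' @param nPerm number of permutations (>= 1).
#' @param seed optional RNG seed for reproducibility.
#' @param siteLabels,motherLabels stratum labels (taken from `haps` when it is
#'   a `PollenHaplotypeSet`).
#' @param D optional precomputed distance matrix.
#' @return list with `pSC`, `phiSC` (observed), `permPhi`, and
#'   `singleMotherSites` (sites contributing no permutation freedom).
#' @export
permutationTestWithin <- function(haps, nPerm = 999, seed = NULL,
                                  siteLabels = NULL, motherLabels = NULL,
                                  D = NULL) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  lb <- .amovaLabels(haps, siteLabels, motherLabels)
  if (is.null(D)) D <- pollenDistanceMatrix(haps)
  if (!is.null(seed)) set.seed(seed)
  key <- paste(lb$site, lb$mother, sep = "\r")
  bp <- .motherPairSums(D, key)
  nk <- as.numeric(table(factor(key, levels = bp$levels)))
  obs <- .amovaFromB(bp$B, nk, sub("\r.*$", "", bp$levels))
  phiObs <- phiStatistics(obs$sigma2)[["phiSC"]]
  perm <- .permWithin(D, lb$site, key, nPerm, obs)
  single <- names(which(tapply(lb$mother, lb$site,
                               function(m) length(unique(m))) == 1L))
  list(pSC = (sum(perm >= phiObs - 1e-12) + 1) / (nPerm + 1),
       phiSC = phiObs, permPhi = perm, singleMotherSites = single)
}

#' Stratified permutation test of among-site differentiation
#'
#' Permutes whole families (a mother together with all her gametes) among
#' sites, preserving the number of mothers per site, and compares the observed
#' `PhiCT` with its permutation distribution (add-one p-value).
#'
#' @inheritParams permutationTestWithin
#' @return list with `pCT`, `phiCT` (observed) and `permPhi`.
#' @export
permutationTestAmong <- function(haps, nPerm = 999, seed = NULL,
                                 siteLabels = NULL, motherLabels = NULL,
                                 D = NULL) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  lb <- .amovaLabels(haps, siteLabels, motherLabels)
  if (is.null(D)) D <- pollenDistanceMatrix(haps)
  if (!is.null(seed)) set.seed(seed)
  key <- paste(lb$site, lb$mother, sep = "\r")
  bp <- .motherPairSums(D, key)
  nk <- as.numeric(table(factor(key, levels = bp$levels)))
  msite <- sub("\r.*$", "", bp$levels)
  obs <- .amovaFromB(bp$B, nk, msite)
  phiObs <- phiStatistics(obs$sigma2)[["phiCT"]]
  perm <- .permAmong(bp$B, nk, msite, nPerm)
  list(pCT = (sum(perm >= phiObs - 1e-12) + 1) / (nPerm + 1),
       phiCT = phiObs, permPhi = perm)
}

.amovaLabels <- function(haps, siteLabels, motherLabels) {
  if (is(haps, "PollenHaplotypeSet"))
    list(site = as.character(haps@seeds$site),
         mother = as.character(haps@seeds$mother))
  else {
    if (is.null(siteLabels) || is.null(motherLabels))
      stop("siteLabels and motherLabels required for a bare allele matrix")
    list(site = as.character(siteLabels), mother = as.character(motherLabels))
  }
}

#' Fit the full hierarchical AMOVA with both permutation tests
#'
#' One-call wrapper: distance matrix, SSD partition, unbalanced variance
#' components, Phi-statistics and the two stratified permutation tests.
#'
#' @param haps a [PollenHaplotypeSet-class] or character allele matrix.
#' @param nPerm permutations per test (0 skips testing).
#' @param seed RNG seed for the permutation streams.
#' @param siteLabels,motherLabels stratum labels for a bare matrix input.
#' @param rescale passed to [pollenDistanceMatrix()].
#' @return an [AmovaResult-class].
#' @export
hierAmova <- function(haps, nPerm = 999, seed = NULL,
                      siteLabels = NULL, motherLabels = NULL,
                      rescale = FALSE) {
  lb <- .amovaLabels(haps, siteLabels, motherLabels)
  D <- pollenDistanceMatrix(haps, rescale = rescale)
  vc <- varianceComponents(D, lb$site, lb$mother)
  phi <- phiStatistics(vc$sigma2)
  flags <- vc$flags
  if (isTRUE(attr(phi, "zeroVariance"))) flags <- c(flags, "zeroVariance")
  pv <- c(pCT = NA_real_, pSC = NA_real_)
  if (nPerm >= 1) {
    if (!is.null(seed)) set.seed(seed)
    pv[["pSC"]] <- permutationTestWithin(haps, nPerm,
                                         siteLabels = lb$site,
                                         motherLabels = lb$mother, D = D)$pSC
    pv[["pCT"]] <- permutationTestAmong(haps, nPerm,
                                        siteLabels = lb$site,
                                        motherLabels = lb$mother, D = D)$pCT
  }
  new("AmovaResult",
      ssd = vc$ssd, df = vc$df,
      ms = stats::setNames(vc$ms, names(vc$df)),
      coef = vc$coef, sigma2 = vc$sigma2,
      phi = phi[c("phiCT", "phiSC", "phiST", "phiSTadd")],
      pvalues = pv, nPerm = as.integer(nPerm),
      design = c(nSites = length(unique(lb$site)),
                 nMothers = length(unique(paste(lb$site, lb$mother, sep = "\r"))),
                 nGametes = length(lb$site)),
      flags = flags)
}

#' Export an AMOVA result as a tidy report table
#'
#' Mirrors the usual published layout: source of variation, df, sums of
#' squares, mean squares, Phi-statistic and permutation p-value.
#'
#' @param x an [AmovaResult-class].
#' @return data.frame with one row per stratum.
#' @export
amovaTable <- function(x) {
  data.frame(
    source = c("Among sites", "Among mothers within sites", "Within mothers"),
    df = unname(x@df),
    SSD = unname(x@ssd[1:3]),
    MS = unname(x@ms),
    phi = c(x@phi[["phiCT"]], x@phi[["phiSC"]], NA_real_),
    statistic = c("PhiCT", "PhiSC", ""),
    p = c(x@pvalues[["pCT"]], x@pvalues[["pSC"]], NA_real_),
    stringsAsFactors = FALSE)
}
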