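## Paternity-adjacent statistics and the seed-filtering model constructions.
## Probability of identity and paternity exclusion are closed-form functions
## of allele frequencies under HWE; the selfing classifier combines a strict
## Mendelian compatibility check with a per-locus likelihood ratio of
## self-fertilization against outcrossing into the pollen pool.

#' Probability of identity of a marker battery
#'
#' Per locus, the probability that two random HWE individuals share a
#' genotype: `P_ID = sum_i p_i^4 + sum_{i<j} (2 p_i p_j)^2`. The multilocus
#' value is the product over loci.
#'
#' @param freqs list of per-locus allele-frequency vectors.
#' @return list with `perLocus` (named numeric) and `multilocus`; empty loci
#'   are excluded with a warning.
#' @export
probabilityOfIdentity <- function(freqs) {
  keep <- vapply(freqs, length, integer(1)) > 0L
  if (any(!keep)) warning("excluding ", sum(!keep), " empty locus/loci")
  per <- vapply(freqs[keep], function(p) {
    p <- p / sum(p)
    g2 <- outer(p, p)           # genotype prob of ordered pair / see below
    ## unordered genotype probabilities: homozygotes p_i^2, heterozygotes 2 p_i p_j
    sum(diag(g2)^2) + sum((2 * g2[upper.tri(g2)])^2)
  }, numeric(1))
  list(perLocus = per, multilocus = prod(per))
}

#' Paternity exclusion probability with a known mother
#'
#' Per locus, the probability that a random HWE individual carries no allele
#' compatible with the paternal contribution of a random mother-offspring
#' pair (mother genotype and true father drawn under HWE, offspring by
#' Mendelian segregation; the candidate is excluded when neither of its
#' alleles belongs to the offspring's possible paternal allele set given the
#' mother). Computed in closed form as an O(k^2) sum over mother genotype
#' classes; the multilocus probability is `1 - prod(1 - P_E)`.
#'
#' @param freqs list of per-locus allele-frequency vectors.
#' @return list with `perLocus` (named numeric) and `multilocus`.
#' @export
exclusionProbability <- function(freqs) {
  keep <- vapply(freqs, length, integer(1)) > 0L
  if (any(!keep)) warning("excluding ", sum(!keep), " empty locus/loci")
  per <- vapply(freqs[keep], function(p) {
    p <- p / sum(p)
    k <- length(p)
    if (k < 2) return(0)
    ## E[(1 - P_S)^2] terms; q(c) = p_c (1 - p_c)^2 summed over paternal allele c
    qAll <- sum(p * (1 - p)^2)
    ## homozygous mothers (a,a): paternal set is always the single transmitted
    ## allele c, so E = sum_c p_c (1 - p_c)^2 regardless of a
    pe <- sum(p^2) * qAll
    ## heterozygous mothers (a,b): offspring {a,b} leaves the paternal allele
    ## ambiguous -> exclusion needs the candidate to miss both a and b
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      pa <- p[a]; pb <- p[b]
      w <- 2 * pa * pb
      e <- 0.5 * (pa + pb) * (1 - pa - pb)^2 +        # offspring het {a,b}
        0.5 * (pa * (1 - pa)^2 + pb * (1 - pb)^2) +   # offspring hom {m,m}
        (qAll - pa * (1 - pa)^2 - pb * (1 - pb)^2)    # novel paternal allele
      pe <- pe + w * e
    }
    pe
  }, numeric(1))
  list(perLocus = per, multilocus = 1 - prod(1 - per))
}

## P(seed genotype | selfing) and P(seed genotype | outcross into pollen pool)
## at one locus; genotypes are length-2 character vectors.
.pSelf <- function(mother, seed) {
  a <- mother[1]; b <- mother[2]
  if (a == b) return(if (seed[1] == a && seed[2] == a) 1 else 0)
  s <- sort(seed)
  if (s[1] == s[2]) {
    if (s[1] %in% c(a, b)) 0.25 else 0
  } else if (setequal(s, c(a, b))) 0.5 else 0
}

.pOutcross <- function(mother, seed, freqs) {
  pf <- function(x) if (x %in% names(freqs)) freqs[[x]] else 0
  a <- mother[1]; b <- mother[2]
  s1 <- seed[1]; s2 <- seed[2]
  pm <- function(x) if (a == b) as.numeric(x == a) else 0.5 * ((x == a) + (x == b))
  if (s1 == s2) pm(s1) * pf(s1)
  else pm(s1) * pf(s2) + pm(s2) * pf(s1)
}

#' Classify a seed as selfed or outcrossed
#'
#' Step 1, strict compatibility: at every non-missing locus the seed genotype
#' must be producible from two maternal gametes; any incompatible locus rules
#' out selfing. Step 2, posterior: over the informative loci,
#' `LR = prod P(seed | self) / P(seed | outcross)` with outcross paternal
#' alleles drawn from the pollen-pool frequencies, and
#' `posterior = prior * LRself / (prior * LRself + (1 - prior) * LRout)`.
#' Calls `selfed` when the posterior reaches `threshold`, `outcrossed` when it
#' falls below `1 - threshold`, otherwise `ambiguous`.
#'
#' @param mother,seed two-column character matrices (one row per locus) or
#'   length-2 vectors for a single locus.
#' @param pollenFreqs list of per-locus pollen-pool frequency vectors (named
#'   by locus, same order as the rows).
#' @param priorSelfing prior selfing rate (default 0.1).
#' @param threshold posterior call threshold (default 0.90).
#' @return list with `call`, `compatible`, `likelihoodRatio`, `posterior`,
#'   `nInformative`.
#' @export
classifySelfing <- function(mother, seed, pollenFreqs,
                            priorSelfing = 0.1, threshold = 0.90) {
  if (is.null(dim(mother))) mother <- matrix(mother, ncol = 2)
  if (is.null(dim(seed))) seed <- matrix(seed, ncol = 2)
  L <- nrow(mother)
  logSelf <- 0; logOut <- 0; nInf <- 0L; compatible <- TRUE
  for (l in seq_len(L)) {
    m <- mother[l, ]; s <- seed[l, ]
    if (anyNA(m) || anyNA(s)) next
    ps <- .pSelf(m, s)
    if (ps == 0) { compatible <- FALSE; break }
    po <- .pOutcross(m, s, pollenFreqs[[l]])
    if (po <= 0) po <- .Machine$double.xmin   # seed allele absent from pool
    nInf <- nInf + 1L
    logSelf <- logSelf + log(ps)
    logOut <- logOut + log(po)
  }
  if (!compatible)
    return(list(call = "outcrossed", compatible = FALSE,
                likelihoodRatio = 0, posterior = 0, nInformative = nInf))
  if (nInf == 0L)
    return(list(call = "ambiguous", compatible = TRUE,
                likelihoodRatio = NA_real_, posterior = NA_real_,
                nInformative = 0L))
  lr <- exp(logSelf - logOut)
  post <- priorSelfing * lr / (priorSelfing * lr + (1 - priorSelfing))
  call <- if (post >= threshold) "selfed"
          else if (post <= 1 - threshold) "outcrossed" else "ambiguous"
  list(call = call, compatible = TRUE, likelihoodRatio = lr,
       posterior = post, nInformative = nInf)
}

#' Selfing calls for every seed of a dataset
#'
#' Applies [classifySelfing()] to each mother-seed pair, using the pollen-pool
#' frequencies of an inferred [PollenHaplotypeSet-class] (or any per-locus
#' frequency list).
#'
#' @param ds a [GenotypeDataset-class].
#' @param pollenFreqs list of per-locus pollen frequencies, e.g. the
#'   `pollenFreqs` slot of [inferPollenPool()]'s result.
#' @param priorSelfing,threshold see [classifySelfing()].
#' @return data.frame: seed keys + `call`, `compatible`, `posterior`,
#'   `nInformative`.
#' @export
selfingCalls <- function(ds, pollenFreqs, priorSelfing = 0.1,
                         threshold = 0.90) {
  L <- length(ds@loci)
  mk <- paste(ds@mothers$site, ds@mothers$mother, sep = "\r")
  mi <- match(paste(ds@seeds$site, ds@seeds$mother, sep = "\r"), mk)
  n <- nrow(ds@seeds)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    mg <- matrix(ds@motherAlleles[mi[i], ], ncol = 2, byrow = TRUE)
    sg <- matrix(ds@seedAlleles[i, ], ncol = 2, byrow = TRUE)
    res[[i]] <- classifySelfing(mg, sg, pollenFreqs, priorSelfing, threshold)
  }
  cbind(ds@seeds,
        data.frame(
          call = vapply(res, `[[`, character(1), "call"),
          compatible = vapply(res, `[[`, logical(1), "compatible"),
          posterior = vapply(res, `[[`, numeric(1), "posterior"),
          nInformative = vapply(res, `[[`, integer(1), "nInformative"),
          stringsAsFactors = FALSE))
}

#' Build the Model A/B/C analysis datasets
#'
#' Model C keeps all seeds; Model B keeps one random seed per fruit (selfed
#' seeds retained); Model A first drops seeds called selfed, then keeps one
#' random seed per fruit among the remainder (fruits left empty are dropped).
#' Sampling uses the supplied seed for exact reproducibility.
#'
#' @param haps a [PollenHaplotypeSet-class].
#' @param model `"A"`, `"B"` or `"C"`.
#' @param calls selfing-call data.frame from [selfingCalls()] (required for
#'   Model A; seeds with `call == "selfed"` are excluded).
#' @param seed RNG seed for the per-fruit draw.
#' @return a [PollenHaplotypeSet-class] restricted to the selected seeds.
#' @export
buildModelDataset <- function(haps, model = c("C", "B", "A"), calls = NULL,
                              seed = NULL) {
  model <- match.arg(model)
  keep <- seq_len(nrow(haps@seeds))
  if (model == "C") return(haps)
  if (any(!nzchar(haps@seeds$fruit)) || anyNA(haps@seeds$fruit))
    stop("Models A and B require fruit identifiers for every seed")
  if (model == "A") {
    if (is.null(calls)) stop("Model A requires selfing calls")
    ck <- paste(calls$site, calls$mother, calls$fruit, calls$seed, sep = "\r")
    hk <- paste(haps@seeds$site, haps@seeds$mother, haps@seeds$fruit,
                haps@seeds$seed, sep = "\r")
    selfed <- ck[calls$call == "selfed"]
    keep <- keep[!(hk %in% selfed)]
  }
  if (!is.null(seed)) set.seed(seed)
  fk <- paste(haps@seeds$site[keep], haps@seeds$mother[keep],
              haps@seeds$fruit[keep], sep = "\r")
  pick <- unlist(lapply(split(keep, fk), function(idx)
    if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]),
    use.names = FALSE)
  pick <- sort(pick)
  new("PollenHaplotypeSet",
      seeds = haps@seeds[pick, , drop = FALSE],
      alleles = haps@alleles[pick, , drop = FALSE],
      status = haps@status[pick, , drop = FALSE],
      weight = haps@weight[pick, , drop = FALSE],
      pollenFreqs = haps@pollenFreqs,
      report = haps@report)
}
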