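## Monte Carlo harness: empirical type-I error and power of the stratified
## permutation tests over replicated synthetic worlds, with the
## normal-approximation binomial band used to judge nominal behaviour.

#' Binomial confidence band for a proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p (1 - p) / n)`; an exact
#' Clopper-Pearson variant is available. For `p = 0.05`, `n = 500` the 95%
#' band rounds to `(0.03, 0.07)`.
#'
#' @param p the proportion (0 < p < 1).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @param method `"normal"` or `"exact"` (Clopper-Pearson around the count
#'   closest to `n * p`).
#' @return named numeric `lower`, `upper`; attributes `lower2`/`upper2` hold
#'   the bounds rounded to 2 decimals.
#' @export
binomialCI <- function(p, n, level = 0.95, method = c("normal", "exact")) {
  method <- match.arg(method)
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)")
  if (n < 1) stop("n must be >= 1")
  if (method == "normal") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    out <- c(lower = p - half, upper = p + half)
  } else {
    x <- round(n * p)
    a <- 1 - level
    lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
    out <- c(lower = lo, upper = hi)
  }
  attr(out, "lower2") <- round(out[["lower"]], 2)
  attr(out, "upper2") <- round(out[["upper"]], 2)
  out
}

#' Empirical rejection rates of the permutation tests over simulated worlds
#'
#' For each replicate: simulate a dataset from the scenario, infer the pollen
#' haplotypes (maternal subtraction, MAP resolution), and run the within-site
#' and/or among-site stratified permutation tests. Reports the fraction of
#' replicates rejecting at `alpha` per level, the binomial band around the
#' nominal `alpha`, and the mean/SD of the estimated Phi-statistics.
#'
#' @param sc a [SimulationScenario-class] (its own `seed` slot is ignored;
#'   per-replicate seeds derive from `seed`).
#' @param nReplicates number of simulated datasets (>= 10).
#' @param nPerm permutations per test.
#' @param alpha nominal significance level.
#' @param seed master RNG seed.
#' @param tests subset of `c("within", "among")`.
#' @param policy gamete resolution policy; the default `"SAMPLE"` preserves
#'   within-site exchangeability of resolved gametes (deterministic MAP
#'   resolution hands all ambiguous seeds of a mother the same majority
#'   allele, manufacturing spurious among-mother differentiation and grossly
#'   inflating the within-site type-I error).
#' @return list (a rejection report): `scenario`, `nReplicates`, `nPerm`,
#'   `alpha`, `rejectionRate` (named per test), `band` (binomial band for
#'   `alpha` at `nReplicates`), `phiMean`, `phiSD`, `pValues` (matrix), and
#'   `failures` (replicate indices that errored).
#' @export
estimateRejectionRates <- function(sc, nReplicates = 500, nPerm = 199,
                                   alpha = 0.05, seed = 1,
                                   tests = c("within", "among"),
                                   policy = "SAMPLE") {
  if (nReplicates < 10) stop("nReplicates must be >= 10")
  tests <- match.arg(tests, several.ok = TRUE)
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
  pSC <- rep(NA_real_, nReplicates); pCT <- rep(NA_real_, nReplicates)
  phiSC <- rep(NA_real_, nReplicates); phiCT <- rep(NA_real_, nReplicates)
  fail <- integer()
  for (r in seq_len(nReplicates)) {
    res <- tryCatch({
      sci <- sc; sci@seed <- as.numeric(repSeeds[r])
      sim <- simulateDataset(sci)
      haps <- inferPollenPool(sim$dataset, policy = policy)
      D <- pollenDistanceMatrix(haps)
      lb <- list(site = as.character(haps@seeds$site),
                 mother = as.character(haps@seeds$mother))
      out <- list()
      if ("within" %in% tests)
        out$w <- permutationTestWithin(haps, nPerm, siteLabels = lb$site,
                                       motherLabels = lb$mother, D = D)
      if ("among" %in% tests)
        out$a <- permutationTestAmong(haps, nPerm, siteLabels = lb$site,
                                      motherLabels = lb$mother, D = D)
      out
    }, error = function(e) e)
    if (inherits(res, "error")) { fail <- c(fail, r); next }
    if (!is.null(res$w)) { pSC[r] <- res$w$pSC; phiSC[r] <- res$w$phiSC }
    if (!is.null(res$a)) { pCT[r] <- res$a$pCT; phiCT[r] <- res$a$phiCT }
  }
  if (length(fail) > 0.01 * nReplicates)
    stop("more than 1% of replicates failed: ",
         paste(utils::head(fail, 10), collapse = ", "))
  rate <- c(
    within = if ("within" %in% tests) mean(pSC <= alpha, na.rm = TRUE) else NA_real_,
    among = if ("among" %in% tests) mean(pCT <= alpha, na.rm = TRUE) else NA_real_)
  list(scenario = sc@name, nReplicates = nReplicates, nPerm = nPerm,
       alpha = alpha,
       rejectionRate = rate,
       band = binomialCI(alpha, nReplicates),
       phiMean = c(phiSC = mean(phiSC, na.rm = TRUE),
                   phiCT = mean(phiCT, na.rm = TRUE)),
       phiSD = c(phiSC = stats::sd(phiSC[!is.na(phiSC)]),
                 phiCT = stats::sd(phiCT[!is.na(phiCT)])),
       pValues = cbind(pSC = pSC, pCT = pCT),
       failures = fail)
}
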