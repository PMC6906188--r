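## TwoGener maternal subtraction: recover the haploid paternal gamete of each
## seed from the mother-seed genotype pair. The only genuinely ambiguous case
## is a heterozygous mother whose seed shares her exact genotype; there the
## paternal allele is resolved by its posterior under the pollen-pool allele
## frequencies (both maternal-transmission hypotheses have prior 1/2, so the
## posterior for paternal = a given seed {a, b} is p_a / (p_a + p_b)).

#' Infer the paternal allele at a single locus
#'
#' Case analysis for one mother-seed genotype pair: (i) homozygous seed
#' carrying a maternal allele -> that allele, unambiguous; (ii) heterozygous
#' seed with exactly one allele absent from the mother -> the absent allele,
#' unambiguous; (iii) seed identical to a heterozygous mother -> posterior
#' resolution from pollen-pool frequencies (MAP or sampled); (iv) no seed
#' allele in the mother -> mismatch.
#'
#' @param mother length-2 character vector (mother's alleles), or `NA`s.
#' @param seed length-2 character vector (seed's alleles), or `NA`s.
#' @param pollenFreqs named numeric vector of pollen-pool allele frequencies.
#' @param policy `"MAP"` (argmax posterior; ties broken toward the
#'   alphabetically first allele) or `"SAMPLE"` (draw from the posterior with
#'   the current RNG).
#' @return list with `allele` (character or `NA`), `status` (one of
#'   `"unambiguous"`, `"resolved"`, `"mismatch"`, `"missing"`), `weight`
#'   (posterior of the chosen allele for resolved loci, else `NA`), and
#'   `flag` (`TRUE` when both pollen frequencies were zero and the posterior
#'   fell back to uniform).
#' @export
inferLocusGamete <- function(mother, seed, pollenFreqs = NULL,
                             policy = c("MAP", "SAMPLE")) {
  policy <- match.arg(policy)
  if (anyNA(mother) || anyNA(seed))
    return(list(allele = NA_character_, status = "missing",
                weight = NA_real_, flag = FALSE))
  inMom <- seed %in% mother
  if (!any(inMom))
    return(list(allele = NA_character_, status = "mismatch",
                weight = NA_real_, flag = FALSE))
  if (seed[1] == seed[2])
    return(list(allele = seed[1], status = "unambiguous",
                weight = NA_real_, flag = FALSE))
  if (!all(inMom)) {
    return(list(allele = seed[!inMom][1], status = "unambiguous",
                weight = NA_real_, flag = FALSE))
  }
  ## heterozygous seed, both alleles maternal: mother must be the same
  ## heterozygote {a, b}; resolve a vs b by pollen-pool posterior
  ab <- sort(seed)
  pa <- if (!is.null(pollenFreqs) && ab[1] %in% names(pollenFreqs))
    pollenFreqs[[ab[1]]] else 0
  pb <- if (!is.null(pollenFreqs) && ab[2] %in% names(pollenFreqs))
    pollenFreqs[[ab[2]]] else 0
  flag <- FALSE
  if (pa + pb <= 0) { pa <- pb <- 0.5; flag <- TRUE }
  post <- c(pa, pb) / (pa + pb)
  pick <- if (policy == "MAP") which.max(post)   # ties -> first (lower label)
          else sample.int(2L, 1L, prob = post)
  list(allele = ab[pick], status = "resolved", weight = post[pick], flag = flag)
}

## vectorized per-locus status classification used by inferPollenPool;
## returns integer codes 1=unambiguous 2=resolved(ambiguous) 3=mismatch 4=missing
.locusCase <- function(m1, m2, s1, s2) {
  out <- integer(length(s1))
  miss <- is.na(m1) | is.na(s1)
  in1 <- s1 == m1 | s1 == m2
  in2 <- s2 == m1 | s2 == m2
  none <- !miss & !in1 & !in2
  hom <- !miss & !none & s1 == s2
  onenew <- !miss & !none & !hom & xor(in1, in2)
  amb <- !miss & !none & !hom & in1 & in2
  out[miss] <- 4L; out[none] <- 3L; out[hom | onenew] <- 1L; out[amb] <- 2L
  out
}

#' Infer the pollen haplotype of every seed in a dataset
#'
#' Two-pass maternal subtraction over all seeds: pass 1 assigns every
#' unambiguous locus and tallies the whole-dataset pollen-pool allele
#' frequencies from those assignments; pass 2 resolves the ambiguous loci
#' (mother and seed share a heterozygous genotype) against those frequencies,
#' by maximum posterior (default) or by posterior sampling. Mismatching loci
#' (seed shares no allele with its mother) are recorded as missing and
#' counted.
#'
#' @param ds a [GenotypeDataset-class].
#' @param policy `"MAP"` or `"SAMPLE"` (see [inferLocusGamete()]).
#' @return a [PollenHaplotypeSet-class]; its `report` slot counts statuses per
#'   locus and flags loci whose frequencies had to fall back to uniform.
#' @export
inferPollenPool <- function(ds, policy = c("SAMPLE", "MAP")) {
  policy <- match.arg(policy)
  L <- length(ds@loci)
  n <- nrow(ds@seeds)
  mk <- paste(ds@mothers$site, ds@mothers$mother, sep = "\r")
  mi <- match(paste(ds@seeds$site, ds@seeds$mother, sep = "\r"), mk)
  statusLv <- c("unambiguous", "resolved", "mismatch", "missing")

  alleles <- matrix(NA_character_, n, L, dimnames = list(NULL, names(ds@loci)))
  status <- matrix("missing", n, L, dimnames = list(NULL, names(ds@loci)))
  weight <- matrix(NA_real_, n, L, dimnames = list(NULL, names(ds@loci)))
  freqs <- vector("list", L); names(freqs) <- names(ds@loci)
  uniformFlag <- logical(L)

  caseMat <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    c1 <- 2L * l - 1L; c2 <- 2L * l
    m1 <- ds@motherAlleles[mi, c1]; m2 <- ds@motherAlleles[mi, c2]
    s1 <- ds@seedAlleles[, c1]; s2 <- ds@seedAlleles[, c2]
    cs <- .locusCase(m1, m2, s1, s2)
    caseMat[, l] <- cs
    ## pass 1: unambiguous assignments
    una <- cs == 1L
    hom <- una & s1 == s2
    alleles[hom, l] <- s1[hom]
    new1 <- una & !hom & !(s1 == m1 | s1 == m2)
    new2 <- una & !hom & !new1
    alleles[new1, l] <- s1[new1]
    alleles[new2, l] <- s2[new2]
    status[una, l] <- "unambiguous"
    status[cs == 2L, l] <- "resolved"
    status[cs == 3L, l] <- "mismatch"
    ## pass-1 pollen frequencies from unambiguous gametes only
    f <- alleleFrequencies(alleles[una, l], alleles = ds@loci[[l]])
    if (isTRUE(attr(f, "empty")) || !length(f)) {
      f <- stats::setNames(rep(1 / length(ds@loci[[l]]), length(ds@loci[[l]])),
                           ds@loci[[l]])
      uniformFlag[l] <- TRUE
    }
    freqs[[l]] <- f
    ## pass 2: resolve ambiguous heterozygote pairs
    amb <- which(cs == 2L)
    if (length(amb)) {
      a1 <- pmin(s1[amb], s2[amb]); a2 <- pmax(s1[amb], s2[amb])
      pa <- unname(f[a1]); pb <- unname(f[a2])
      pa[is.na(pa)] <- 0; pb[is.na(pb)] <- 0
      tot <- pa + pb
      zero <- tot <= 0
      pa[zero] <- 0.5; pb[zero] <- 0.5; tot[zero] <- 1
      postA <- pa / tot
      if (policy == "MAP") {
        takeA <- postA >= 0.5   # tie -> lower allele label
      } else {
        takeA <- stats::runif(length(amb)) < postA
      }
      alleles[amb, l] <- ifelse(takeA, a1, a2)
      weight[amb, l] <- ifelse(takeA, postA, 1 - postA)
    }
  }

  report <- data.frame(
    locus = names(ds@loci),
    unambiguous = colSums(caseMat == 1L),
    resolved = colSums(caseMat == 2L),
    mismatch = colSums(caseMat == 3L),
    missing = colSums(caseMat == 4L),
    uniformFallback = uniformFlag,
    row.names = NULL, stringsAsFactors = FALSE)

  new("PollenHaplotypeSet",
      seeds = ds@seeds, alleles = alleles,
      status = status, weight = weight,
      pollenFreqs = freqs, report = report)
}

#' Write a pollen haplotype table as CSV
#'
#' One row per seed: identifiers, one allele column per locus (missing written
#' as empty) and one `<locus>.status` column.
#'
#' @param haps a [PollenHaplotypeSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHaplotypeTable <- function(haps, path) {
  A <- haps@alleles; A[is.na(A)] <- ""
  S <- haps@status
  colnames(S) <- paste0(colnames(S), ".status")
  out <- cbind(haps@seeds, as.data.frame(A, stringsAsFactors = FALSE),
               as.data.frame(S, stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
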