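## Reading/writing codominant genotype tables and basic per-locus summaries.
## Two dialects are accepted: "wide" (two columns per locus, suffixes .1/.2,
## the default population-genetics spreadsheet layout) and "ab" (one column
## per locus, alleles joined by "/").

.normalizeMissing <- function(x, sentinel) {
  x <- trimws(as.character(x))
  x[x %in% c(sentinel, "", "NA")] <- NA_character_
  x
}

## enforce the full-locus-missing rule: one NA allele blanks the pair
.blankHalfCalls <- function(mat) {
  L <- ncol(mat) / 2L
  for (l in seq_len(L)) {
    cols <- c(2L * l - 1L, 2L * l)
    half <- is.na(mat[, cols[1]]) | is.na(mat[, cols[2]])
    mat[half, cols] <- NA_character_
  }
  mat
}

#' Construct a GenotypeDataset from its parts
#'
#' Lower-level constructor used by the parser and the simulator. The locus
#' registry is inferred from the observed alleles when not supplied. Half-called
#' loci (one of the two alleles missing) are blanked to fully missing.
#'
#' @param mothers data.frame with columns `site`, `mother`.
#' @param motherAlleles character matrix with two columns per locus, columns
#'   named `<locus>.1`, `<locus>.2`.
#' @param seeds data.frame with columns `site`, `mother`, `fruit`, `seed`.
#' @param seedAlleles character matrix like `motherAlleles`.
#' @param loci optional named list of allele labels per locus.
#' @return a validated [GenotypeDataset-class] object.
#' @export
genotypeDataset <- function(mothers, motherAlleles, seeds, seedAlleles,
                            loci = NULL) {
  motherAlleles <- .blankHalfCalls(as.matrix(motherAlleles))
  seedAlleles <- .blankHalfCalls(as.matrix(seedAlleles))
  cn <- colnames(motherAlleles)
  if (is.null(cn) || !identical(cn, colnames(seedAlleles)))
    stop("mother and seed allele matrices must share locus columns")
  locusNames <- unique(sub("\\.[12]$", "", cn))
  if (is.null(loci)) {
    loci <- lapply(locusNames, function(nm) {
      cols <- paste0(nm, c(".1", ".2"))
      obs <- c(motherAlleles[, cols], seedAlleles[, cols])
      sort(unique(obs[!is.na(obs)]))
    })
    names(loci) <- locusNames
  }
  empty <- names(loci)[vapply(loci, length, integer(1)) == 0L]
  for (nm in empty) loci[[nm]] <- "<none>"   # keeps registry valid for all-missing loci
  new("GenotypeDataset",
      loci = loci,
      mothers = as.data.frame(mothers)[, c("site", "mother")],
      motherAlleles = motherAlleles,
      seeds = as.data.frame(seeds)[, c("site", "mother", "fruit", "seed")],
      seedAlleles = seedAlleles)
}

#' Read a delimited mother-seed genotype table
#'
#' Expects a header row and one row per individual with columns `role`
#' (`"mother"` or `"seed"`), `site`, `mother`, and for seeds also `fruit` and
#' `seed`, followed by the genotype columns. In the `"wide"` dialect each locus
#' occupies two columns `<locus>.1`/`<locus>.2`; in the `"ab"` dialect one
#' column per locus holds `"allele1/allele2"`. The missing sentinel (default
#' `"0"`; empty cells always count as missing) is replaced by `NA` and
#' half-called loci are blanked.
#'
#' @param path file path of the delimited text table.
#' @param dialect `"wide"` or `"ab"`.
#' @param sep field separator (default `","`).
#' @param missing missing-data sentinel (default `"0"`).
#' @return a [GenotypeDataset-class].
#' @export
readGenotypeTable <- function(path, dialect = c("wide", "ab"), sep = ",",
                              missing = "0") {
  dialect <- match.arg(dialect)
  tab <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- c("role", "site", "mother")
  if (!all(need %in% names(tab)))
    stop("genotype table must contain columns: ", paste(need, collapse = ", "))
  meta <- intersect(c("role", "site", "mother", "fruit", "seed"), names(tab))
  gcols <- setdiff(names(tab), meta)
  if (!length(gcols)) stop("no genotype columns found")

  if (dialect == "wide") {
    base <- sub("\\.[12]$", "", gcols)
    lnames <- unique(base)
    for (nm in lnames)
      if (!all(paste0(nm, c(".1", ".2")) %in% gcols))
        stop("malformed allele columns for locus ", nm,
             ": need both ", nm, ".1 and ", nm, ".2")
    A <- as.matrix(tab[, as.vector(rbind(paste0(lnames, ".1"),
                                         paste0(lnames, ".2"))), drop = FALSE])
  } else {
    lnames <- gcols
    A <- matrix(NA_character_, nrow(tab), 2L * length(lnames))
    colnames(A) <- as.vector(rbind(paste0(lnames, ".1"), paste0(lnames, ".2")))
    for (j in seq_along(lnames)) {
      v <- trimws(tab[[lnames[j]]])
      parts <- strsplit(v, "/", fixed = TRUE)
      bad <- which(!is.na(v) & v != "" & lengths(parts) != 2L)
      if (length(bad))
        stop("malformed allele column '", lnames[j], "' at data row ", bad[1],
             ": expected 'a/b'")
      parts[lengths(parts) != 2L] <- list(c(NA_character_, NA_character_))
      m <- do.call(rbind, parts)
      A[, 2L * j - 1L] <- m[, 1]; A[, 2L * j] <- m[, 2]
    }
  }
  A <- apply(A, 2L, .normalizeMissing, sentinel = missing)
  if (!is.matrix(A)) A <- matrix(A, nrow = nrow(tab),
                                 dimnames = list(NULL, colnames(A)))

  role <- tolower(trimws(tab$role))
  if (!all(role %in% c("mother", "seed")))
    stop("column 'role' must be 'mother' or 'seed'")
  isM <- role == "mother"
  if (!any(isM)) stop("no mother rows found")
  if (!any(!isM)) stop("no seed rows found")
  if (!all(c("fruit", "seed") %in% names(tab)))
    stop("seed rows require 'fruit' and 'seed' columns")

  mothers <- data.frame(site = tab$site[isM], mother = tab$mother[isM],
                        stringsAsFactors = FALSE)
  mk <- paste(mothers$site, mothers$mother, sep = "\r")
  if (anyDuplicated(mk))
    stop("duplicate mother id at data row ",
         which(isM)[which(duplicated(mk))[1]])
  seeds <- data.frame(site = tab$site[!isM], mother = tab$mother[!isM],
                      fruit = tab$fruit[!isM], seed = tab$seed[!isM],
                      stringsAsFactors = FALSE)
  sk <- paste(seeds$site, seeds$mother, seeds$fruit, seeds$seed, sep = "\r")
  if (anyDuplicated(sk))
    stop("duplicate seed id at data row ",
         which(!isM)[which(duplicated(sk))[1]])
  smk <- paste(seeds$site, seeds$mother, sep = "\r")
  orphan <- which(!(smk %in% mk))
  if (length(orphan))
    stop("seed at data row ", which(!isM)[orphan[1]],
         " references unknown mother '", seeds$mother[orphan[1]],
         "' at site '", seeds$site[orphan[1]], "'")

  genotypeDataset(mothers, A[isM, , drop = FALSE],
                  seeds, A[!isM, , drop = FALSE])
}

#' Write a GenotypeDataset back to a delimited table
#'
#' Inverse of [readGenotypeTable()]; `readGenotypeTable(writeGenotypeTable(ds))`
#' is the identity on well-formed datasets.
#'
#' @param ds a [GenotypeDataset-class].
#' @param path output file path.
#' @param dialect `"wide"` or `"ab"`.
#' @param missing sentinel written for missing alleles.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(ds, path, dialect = c("wide", "ab"),
                               missing = "0") {
  dialect <- match.arg(dialect)
  nm <- nrow(ds@mothers); ns <- nrow(ds@seeds)
  meta <- data.frame(
    role = c(rep("mother", nm), rep("seed", ns)),
    site = c(ds@mothers$site, ds@seeds$site),
    mother = c(ds@mothers$mother, ds@seeds$mother),
    fruit = c(rep("", nm), ds@seeds$fruit),
    seed = c(rep("", nm), ds@seeds$seed),
    stringsAsFactors = FALSE)
  A <- rbind(ds@motherAlleles, ds@seedAlleles)
  A[is.na(A)] <- missing
  if (dialect == "wide") {
    out <- cbind(meta, as.data.frame(A, stringsAsFactors = FALSE))
  } else {
    L <- length(ds@loci)
    G <- matrix("", nrow(A), L, dimnames = list(NULL, names(ds@loci)))
    for (l in seq_len(L))
      G[, l] <- paste(A[, 2L * l - 1L], A[, 2L * l], sep = "/")
    out <- cbind(meta, as.data.frame(G, stringsAsFactors = FALSE))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Mother-offspring compatibility screen
#'
#' Flags every (seed, locus) where neither seed allele occurs in the mother's
#' genotype at that locus (both genotypes non-missing) -- a Mendelian
#' impossibility indicating genotyping error or null alleles -- and reports
#' the per-locus rate of impossible combinations and the per-locus missing
#' rate.
#'
#' @param ds a [GenotypeDataset-class].
#' @return list with `perLocus` (data.frame: locus, nCompared, nImpossible,
#'   impossibleRate, missingRate) and `flagged` (data.frame of seed keys and
#'   locus for each incompatibility).
#' @export
validateDataset <- function(ds) {
  L <- length(ds@loci)
  mk <- paste(ds@mothers$site, ds@mothers$mother, sep = "\r")
  smk <- paste(ds@seeds$site, ds@seeds$mother, sep = "\r")
  mi <- match(smk, mk)
  per <- data.frame(locus = names(ds@loci), nCompared = 0L, nImpossible = 0L,
                    impossibleRate = NA_real_, missingRate = NA_real_,
                    stringsAsFactors = FALSE)
  flagged <- list()
  n <- nrow(ds@seeds)
  for (l in seq_len(L)) {
    c1 <- 2L * l - 1L; c2 <- 2L * l
    s1 <- ds@seedAlleles[, c1]; s2 <- ds@seedAlleles[, c2]
    m1 <- ds@motherAlleles[mi, c1]; m2 <- ds@motherAlleles[mi, c2]
    ok <- !is.na(s1) & !is.na(m1)
    imp <- ok & s1 != m1 & s1 != m2 & s2 != m1 & s2 != m2
    per$nCompared[l] <- sum(ok)
    per$nImpossible[l] <- sum(imp)
    per$impossibleRate[l] <- if (sum(ok)) sum(imp) / sum(ok) else NA_real_
    per$missingRate[l] <- if (n) mean(is.na(s1)) else NA_real_
    if (any(imp))
      flagged[[length(flagged) + 1L]] <-
        cbind(ds@seeds[imp, , drop = FALSE], locus = names(ds@loci)[l])
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged)
             else cbind(ds@seeds[0, , drop = FALSE], locus = character())
  list(perLocus = per, flagged = flagged)
}

#' Allele frequencies of a gamete pool or genotype collection
#'
#' Counts alleles at one locus over haploid gametes (one allele per
#' observation) or diploid genotypes (two alleles per observation); missing
#' observations are excluded from the denominator.
#'
#' @param x for `haploid = TRUE`, a character vector of gametic alleles; for
#'   `haploid = FALSE`, a two-column character matrix of genotypes.
#' @param alleles optional character vector fixing the allele universe (zero
#'   frequencies are reported for unobserved alleles).
#' @param haploid logical.
#' @return named numeric vector of frequencies summing to 1; a zero-length
#'   vector with attribute `empty = TRUE` when there is no data.
#' @export
alleleFrequencies <- function(x, alleles = NULL, haploid = TRUE) {
  obs <- if (haploid) as.character(x) else as.character(as.matrix(x))
  obs <- obs[!is.na(obs)]
  if (!length(obs)) {
    out <- stats::setNames(numeric(0), character(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  if (is.null(alleles)) alleles <- sort(unique(obs))
  cnt <- table(factor(obs, levels = alleles))
  stats::setNames(as.numeric(cnt) / sum(cnt), alleles)
}

#' Export diploid genotypes in GenePop format
#'
#' Writes mothers (and optionally seeds) grouped by site as GenePop
#' populations with 3-digit allele codes assigned by registry order; `000`
#' encodes missing. Interoperability helper only.
#'
#' @param ds a [GenotypeDataset-class].
#' @param path output path.
#' @param includeSeeds include seed genotypes as additional individuals.
#' @param title header line.
#' @return `path`, invisibly.
#' @export
writeGenepop <- function(ds, path, includeSeeds = FALSE,
                         title = "pollenflow export") {
  L <- length(ds@loci)
  code <- lapply(ds@loci, function(a) stats::setNames(sprintf("%03d", seq_along(a)), a))
  enc <- function(A, i) {
    out <- character(L)
    for (l in seq_len(L)) {
      a1 <- A[i, 2L * l - 1L]; a2 <- A[i, 2L * l]
      out[l] <- if (is.na(a1)) "000000"
                else paste0(code[[l]][a1], code[[l]][a2])
    }
    paste(out, collapse = " ")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(names(ds@loci), con)
  for (s in unique(ds@mothers$site)) {
    writeLines("POP", con)
    for (i in which(ds@mothers$site == s))
      writeLines(sprintf("%s_%s ,  %s", s, ds@mothers$mother[i],
                         enc(ds@motherAlleles, i)), con)
    if (includeSeeds)
      for (i in which(ds@seeds$site == s))
        writeLines(sprintf("%s_%s_%s_%s ,  %s", s, ds@seeds$mother[i],
                           ds@seeds$fruit[i], ds@seeds$seed[i],
                           enc(ds@seedAlleles, i)), con)
  }
  invisible(path)
}
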