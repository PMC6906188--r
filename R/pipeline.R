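## End-to-end orchestration: genotype table (real or simulated) -> validation
## -> gamete inference -> selfing calls -> Model A/B/C filtering -> AMOVA with
## permutation tests -> report tables. Fully deterministic given the config.

#' Run the full pollen-pool differentiation pipeline
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{dataset}{a [GenotypeDataset-class], or `path` + optional
#'       `dialect`/`missing` to read one; alternatively `scenario` (a
#'       [SimulationScenario-class]) to simulate the input.}
#'     \item{models}{subset of `c("A", "B", "C")` (default all three).}
#'     \item{nPerm}{permutations per test (default 999).}
#'     \item{seed}{master RNG seed (required; drives haplotype resolution under
#'       `policy = "SAMPLE"`, per-fruit sampling and permutation streams).}
#'     \item{policy}{gamete resolution policy (default `"MAP"`).}
#'     \item{priorSelfing, threshold}{selfing classifier settings
#'       (defaults 0.1, 0.9).}
#'     \item{outDir}{optional directory; when set, CSV and JSON reports are
#'       written there.}
#'   }
#' @return list with `validation`, `inference` (per-locus status report),
#'   `selfing` (calls + summary), `models` (per model: `AmovaResult`, tidy
#'   table, `n`, `phiRatio`), and `log` (seeds, versions, decisions).
#' @export
runPipeline <- function(config) {
  if (is.null(config$seed)) stop("config$seed is required")
  models <- config$models %||% c("A", "B", "C")
  nPerm <- config$nPerm %||% 999
  policy <- config$policy %||% "SAMPLE"
  priorSelfing <- config$priorSelfing %||% 0.1
  threshold <- config$threshold %||% 0.9

  if (!is.null(config$dataset)) {
    ds <- config$dataset
  } else if (!is.null(config$path)) {
    ds <- readGenotypeTable(config$path,
                            dialect = config$dialect %||% "wide",
                            missing = config$missing %||% "0")
  } else if (!is.null(config$scenario)) {
    ds <- simulateDataset(config$scenario)$dataset
  } else stop("config must provide dataset, path or scenario")

  validation <- validateDataset(ds)
  set.seed(config$seed)
  haps <- inferPollenPool(ds, policy = policy)
  calls <- selfingCalls(ds, haps@pollenFreqs,
                        priorSelfing = priorSelfing, threshold = threshold)
  selfSummary <- c(
    selfed = sum(calls$call == "selfed"),
    outcrossed = sum(calls$call == "outcrossed"),
    ambiguous = sum(calls$call == "ambiguous"),
    fraction = mean(calls$call == "selfed"))

  modelSeeds <- stats::setNames(config$seed + seq_along(models), models)
  fits <- list()
  for (m in models) {
    hm <- buildModelDataset(haps, model = m, calls = calls,
                            seed = modelSeeds[[m]])
    fit <- hierAmova(hm, nPerm = nPerm, seed = modelSeeds[[m]] + 1000L)
    pr <- phiRatio(fit@phi[["phiSC"]], fit@phi[["phiCT"]])
    fits[[m]] <- list(model = m, n = nrow(hm@seeds), amova = fit,
                      table = amovaTable(fit), phiRatio = pr)
  }

  report <- list(
    validation = validation,
    inference = haps@report,
    selfing = list(calls = calls, summary = selfSummary),
    models = fits,
    log = list(seed = config$seed, nPerm = nPerm, policy = policy,
               priorSelfing = priorSelfing, threshold = threshold,
               rVersion = as.character(getRversion()),
               package = as.character(utils::packageVersion("pollenflow"))))

  if (!is.null(config$outDir)) .writePipelineReport(report, config$outDir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writePipelineReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$validation$perLocus,
                   file.path(dir, "validation.csv"), row.names = FALSE)
  utils::write.csv(report$inference,
                   file.path(dir, "inference_report.csv"), row.names = FALSE)
  utils::write.csv(report$selfing$calls,
                   file.path(dir, "selfing_calls.csv"), row.names = FALSE)
  js <- list()
  for (m in names(report$models)) {
    fm <- report$models[[m]]
    utils::write.csv(fm$table,
                     file.path(dir, sprintf("amova_model%s.csv", m)),
                     row.names = FALSE)
    js[[m]] <- list(
      n = fm$n,
      phi = as.list(fm$amova@phi),
      p = as.list(fm$amova@pvalues),
      ssd = as.list(fm$amova@ssd),
      df = as.list(fm$amova@df),
      phiRatio = as.list(unclass(fm$phiRatio)))
  }
  js$selfing <- as.list(report$selfing$summary)
  js$log <- report$log
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
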