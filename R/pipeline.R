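## Pipeline wiring: configuration, provenance stamping, staged execution.

#' Pipeline configuration
#'
#' All thresholds of the pipeline with their defaults, input/output paths
#' and the single seed behind every source of randomness.  Serialisable to
#' YAML via [writeConfig()] / [readConfig()].
#'
#' @param supportThreshold bootstrap threshold for splitting (0-100).
#' @param lengthFraction relative-length filter for rescue (0, 1].
#' @param lwrThreshold placement acceptance threshold `[0, 1]`.
#' @param evalueMax expect-value pre-filter on incoming hits.
#' @param absCutoff,devCutoff localization-outlier cutoffs `[0, 1]`.
#' @param minSpeciesOverlap species-overlap count for duplications.
#' @param outgroupSpecies species codes used for rooting.
#' @param seed integer seed.
#' @param paths named list of input/output paths (free-form; consumed by
#'   [runPipeline()]).
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(supportThreshold = 70L, lengthFraction = 0.75,
                           lwrThreshold = 0.5, evalueMax = 1e-20,
                           absCutoff = 0.5, devCutoff = 0.5,
                           minSpeciesOverlap = 1L,
                           outgroupSpecies = character(),
                           seed = 1L, paths = list()) {
  stopifnot(supportThreshold >= 0, supportThreshold <= 100,
            lengthFraction > 0, lengthFraction <= 1,
            lwrThreshold >= 0, lwrThreshold <= 1,
            evalueMax >= 0, absCutoff >= 0, absCutoff <= 1,
            devCutoff >= 0, devCutoff <= 1, minSpeciesOverlap >= 1)
  structure(list(supportThreshold = as.integer(supportThreshold),
                 lengthFraction = lengthFraction,
                 lwrThreshold = lwrThreshold,
                 evalueMax = evalueMax,
                 absCutoff = absCutoff, devCutoff = devCutoff,
                 minSpeciesOverlap = as.integer(minSpeciesOverlap),
                 outgroupSpecies = as.character(outgroupSpecies),
                 seed = as.integer(seed),
                 paths = paths),
            class = "PipelineConfig")
}

#' Serialise a pipeline configuration to YAML
#'
#' @param config a [pipelineConfig()].
#' @param path output file; `NULL` returns the YAML text.
#' @return the YAML string, invisibly when written.
#' @export
writeConfig <- function(config, path = NULL) {
  txt <- yaml::as.yaml(unclass(config))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [writeConfig()] (or hand-edited).
#' @return a [pipelineConfig()].
#' @export
readConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipelineConfig, obj)
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical YAML serialisation; embedded in every pipeline
#' output for provenance.
#'
#' @param config a [pipelineConfig()].
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(writeConfig(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the curation pipeline
#'
#' Executes the requested stages in order -- coalesce, seed, curate,
#' rescue, qc, compare -- over in-memory inputs, stamping the result with
#' the tool version, the configuration hash and per-stage edit counts.  A
#' stage failure aborts with the stage name.
#'
#' @param catalog an [OrthologCatalog-class] (FOGs assigned, HOGs optional).
#' @param config a [pipelineConfig()].
#' @param labeling named character vector protein id -> homolog label
#'   (stages coalesce/seed).
#' @param trees named list HOG id -> [GeneTree-class] (stage curate).
#' @param taxonomy a [SpeciesTaxonomy-class] (stage curate).
#' @param candidates,hits,placements rescue inputs (stage rescue), see
#'   [rescueProteins()].
#' @param localization localization table (stage qc).
#' @param external an [ExternalLabeling-class] (stage compare).
#' @param stages character vector of stages to run.
#' @return list with `catalog`, `reports` (per-stage outputs) and `stamp`
#'   (version, config hash, per-stage edit counts).
#' @export
runPipeline <- function(catalog, config = pipelineConfig(),
                        labeling = NULL, trees = NULL, taxonomy = NULL,
                        candidates = NULL, hits = NULL, placements = NULL,
                        localization = NULL, external = NULL,
                        stages = c("coalesce", "seed", "curate", "rescue",
                                   "qc", "compare")) {
  stages <- match.arg(stages, several.ok = TRUE)
  reports <- list()
  editCounts <- list()
  runStage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ccfg <- curationConfig(config$supportThreshold, config$outgroupSpecies,
                         config$minSpeciesOverlap)

  if ("coalesce" %in% stages && !is.null(labeling)) {
    res <- runStage("coalesce", function()
      coalesceFogsToHogs(catalog, labeling))
    catalog <- res$catalog
    reports$conflicts <- res$conflicts
    editCounts$coalesce <- nrow(res$conflicts)
  }
  if ("seed" %in% stages && !is.null(labeling)) {
    before <- nFogs(catalog)
    catalog <- runStage("seed", function()
      seedFogsForUnclustered(catalog, labeling))
    editCounts$seed <- nFogs(catalog) - before
  }
  if ("curate" %in% stages && !is.null(trees) && !is.null(taxonomy)) {
    res <- runStage("curate", function()
      curateCatalog(catalog, trees, taxonomy, ccfg))
    catalog <- res$catalog
    reports$curationLog <- res$log
    editCounts$curate_merges <- sum(res$log$op == "merge")
    editCounts$curate_splits <- sum(res$log$op == "split")
  }
  if ("rescue" %in% stages && !is.null(candidates)) {
    res <- runStage("rescue", function()
      rescueProteins(catalog, candidates, hits, placements,
                     evalueMax = config$evalueMax,
                     lengthFraction = config$lengthFraction,
                     lwrThreshold = config$lwrThreshold))
    catalog <- res$catalog
    reports$rescueLog <- res$log
    editCounts$rescue_accepted <- sum(res$log$decision == "accepted")
  }
  if ("qc" %in% stages && !is.null(localization)) {
    reports$qcFlags <- runStage("qc", function()
      catalogQC(catalog, localization, absCutoff = config$absCutoff,
                devCutoff = config$devCutoff,
                fraction = config$lengthFraction))
    editCounts$qc_flags <- nrow(reports$qcFlags)
  }
  if ("compare" %in% stages && !is.null(external)) {
    reports$congruence <- runStage("compare", function()
      summarizeComparison(catalog, external))
  }

  stamp <- list(tool = "OrthoCurator",
                version = as.character(utils::packageVersion("OrthoCurator")),
                configHash = configHash(config),
                editCounts = editCounts,
                statistics = catalogStatistics(catalog))
  list(catalog = catalog, reports = reports, stamp = stamp)
}
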