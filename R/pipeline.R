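# One-command orchestration: simulate -> extract -> symbolize -> encode ->
# describe -> cluster, with a YAML/list config and a JSON manifest.

#' Build and validate a pipeline configuration
#'
#' Assembles the full parameter set of the analysis with the method's
#' defaults: 1-second resampling, 40-degree turning threshold, two step
#' symbols, a 0.9 correlation filter, and all six matrix variants.
#' Validation happens up front so a bad parameter aborts before any
#' computation.
#'
#' @param outDir directory for all artifacts.
#' @param inputCsv trajectory CSV to analyze, or `NULL` to simulate.
#' @param simulate when `inputCsv` is `NULL`: a list of group specs as for
#'   [simulateCohort()]; the default simulates a sharp-turn-rich and a
#'   shallow-turn-rich cohort of 5 animals each.
#' @param deltaTs resampling interval (s).
#' @param thetaDeg turning-event threshold (degrees, in (0, 180)).
#' @param kStep number of step symbols (2..5).
#' @param kPath number of animal clusters.
#' @param matrixKinds subset of IMF, AMF, BAMF, BAAMF, IMFL, AMFL.
#' @param clusterKind the matrix kind whose descriptors drive animal
#'   clustering (must be in `matrixKinds`).
#' @param correlationThreshold descriptor correlation filter threshold.
#' @param useSelectedFeatures cluster on the correlation-filtered
#'   descriptor set (`TRUE`) or on all eleven (`FALSE`).
#' @param seed master seed; stage seeds are derived from it.
#' @param kmeansRestarts restarts for both k-means fits.
#' @return a validated config (list with class `"wormpathConfig"`).
#' @examples
#' cfg <- pipelineConfig(outDir = tempfile(), kPath = 2)
#' cfg$thetaDeg
#' @export
pipelineConfig <- function(outDir,
                           inputCsv = NULL,
                           simulate = list(
                             list(group = "sharp", params = sharpTurnParams(),
                                  nAnimals = 5),
                             list(group = "shallow", params = shallowTurnParams(),
                                  nAnimals = 5)),
                           deltaTs = 1.0, thetaDeg = 40,
                           kStep = 2L, kPath = 5L,
                           matrixKinds = .rleKinds,
                           clusterKind = "BAMF",
                           correlationThreshold = 0.9,
                           useSelectedFeatures = TRUE,
                           seed = 1L, kmeansRestarts = 10L) {
  cfg <- list(outDir = outDir, inputCsv = inputCsv, simulate = simulate,
              deltaTs = deltaTs, thetaDeg = thetaDeg,
              kStep = as.integer(kStep), kPath = as.integer(kPath),
              matrixKinds = matrixKinds, clusterKind = clusterKind,
              correlationThreshold = correlationThreshold,
              useSelectedFeatures = isTRUE(useSelectedFeatures),
              seed = as.integer(seed), kmeansRestarts = as.integer(kmeansRestarts))
  class(cfg) <- "wormpathConfig"
  validateConfig(cfg)
  cfg
}

#' @rdname pipelineConfig
#' @param cfg a config list.
#' @export
validateConfig <- function(cfg) {
  stopIfNot(cfg$deltaTs > 0, "deltaTs must be > 0")
  stopIfNot(cfg$thetaDeg > 0 && cfg$thetaDeg < 180,
            "thetaDeg must be in (0, 180)")
  stopIfNot(cfg$kStep >= 2L && cfg$kStep <= 5L, "kStep must be in [2, 5]")
  stopIfNot(cfg$kPath >= 1L, "kPath must be >= 1")
  stopIfNot(all(cfg$matrixKinds %in% .rleKinds),
            sprintf("matrixKinds must be among %s", paste(.rleKinds, collapse = ", ")))
  stopIfNot(cfg$clusterKind %in% cfg$matrixKinds,
            "clusterKind must be one of matrixKinds")
  stopIfNot(cfg$correlationThreshold > 0 && cfg$correlationThreshold <= 1,
            "correlationThreshold must be in (0, 1]")
  stopIfNot(!is.null(cfg$inputCsv) || length(cfg$simulate) >= 1,
            "config needs either inputCsv or a simulate block")
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys use snake_case (`delta_t_s`, `theta_deg`, `k_step`, `k_path`,
#' `matrix_kinds`, `cluster_kind`, `correlation_threshold`,
#' `use_selected_features`, `seed`, `kmeans_restarts`, `input_csv`,
#' `out_dir`); the optional `simulate` block is a list of
#' `{group, n_animals, params: {...simParams() arguments...}}` entries.
#'
#' @param path YAML file.
#' @param outDir overrides the config's `out_dir` when given.
#' @param seed overrides the config's `seed` when given.
#' @return a validated config list.
#' @export
readPipelineConfig <- function(path, outDir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  simBlock <- NULL
  if (!is.null(y$simulate)) {
    simBlock <- lapply(y$simulate, function(sp) {
      p <- do.call(simParams, as.list(sp$params %||% list()))
      list(group = sp$group, params = p, nAnimals = sp$n_animals %||% 1L)
    })
  }
  grab <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  pipelineConfig(
    outDir = outDir %||% grab("out_dir", "wormpath_out"),
    inputCsv = y$input_csv,
    simulate = simBlock %||% list(),
    deltaTs = grab("delta_t_s", 1.0), thetaDeg = grab("theta_deg", 40),
    kStep = grab("k_step", 2L), kPath = grab("k_path", 5L),
    matrixKinds = grab("matrix_kinds", .rleKinds),
    clusterKind = grab("cluster_kind", "BAMF"),
    correlationThreshold = grab("correlation_threshold", 0.9),
    useSelectedFeatures = grab("use_selected_features", TRUE),
    seed = seed %||% grab("seed", 1L),
    kmeansRestarts = grab("kmeans_restarts", 10L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.artifactPaths <- function(outDir) {
  list(trajectories = file.path(outDir, "trajectories.csv"),
       steps = file.path(outDir, "steps.csv"),
       symbols = file.path(outDir, "symbols.tsv"),
       clusterRanges = file.path(outDir, "step_cluster_ranges.csv"),
       matricesDir = file.path(outDir, "matrices"),
       descriptors = function(kind) file.path(outDir, sprintf("descriptors_%s.csv", kind)),
       selection = file.path(outDir, "descriptor_selection.json"),
       assignment = file.path(outDir, "clusters.csv"),
       composition = file.path(outDir, "composition.csv"),
       manifest = file.path(outDir, "manifest.json"))
}

#' Run the full path-analysis pipeline
#'
#' Orchestrates all stages: obtain trajectories (simulate or read), extract
#' and normalize steps, fit the step-symbol model and symbolize, build the
#' requested run-length matrices, compute and filter descriptors, and
#' cluster the animals. Every intermediate result is written as plain text
#' under `cfg$outDir` so any stage can be inspected or re-entered, and a
#' JSON manifest records the configuration (with an MD5 of the written
#' config), derived seeds, package version and collected warnings. Rerunning
#' the same config reproduces identical artifacts.
#'
#' @param cfg a config from [pipelineConfig()] or [readPipelineConfig()].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the main in-memory results (`stepTables`,
#'   `model`, `strings`, `descriptors`, `selection`, `clustering`,
#'   `composition`, `manifest`).
#' @examples
#' cfg <- pipelineConfig(outDir = tempfile(), kPath = 2,
#'   simulate = list(
#'     list(group = "sharp", params = sharpTurnParams(durationS = 60), nAnimals = 3),
#'     list(group = "shallow", params = shallowTurnParams(durationS = 60), nAnimals = 3)))
#' res <- runPipeline(cfg, quiet = TRUE)
#' res$composition
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  validateConfig(cfg)
  paths <- .artifactPaths(cfg$outDir)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(paths$matricesDir, showWarnings = FALSE)
  seeds <- deriveSeeds(cfg$seed, 3L)  # cohort, step k-means, worm k-means
  notes <- character()
  note <- function(w) notes <<- c(notes, conditionMessage(w))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(w); invokeRestart("muffleWarning")
    }), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  trajs <- stage("simulate", {
    if (!is.null(cfg$inputCsv)) {
      say("reading trajectories from %s", cfg$inputCsv)
      readTrajectoryCSV(cfg$inputCsv)
    } else {
      say("simulating %d group(s)", length(cfg$simulate))
      simulateCohort(cfg$simulate, seed = seeds[1])
    }
  })
  writeTrajectoryCSV(trajs, paths$trajectories)
  say("extracting steps from %d trajectories", length(trajs))
  stepTables <- stage("extract",
    extractSteps(trajs, deltaTs = cfg$deltaTs, thetaDeg = cfg$thetaDeg))
  writeStepTableCSV(stepTables, paths$steps)

  say("symbolizing with k_step = %d", cfg$kStep)
  model <- stage("symbolize-fit",
    fitStepClusters(stepTables, k = cfg$kStep, seed = seeds[2],
                    restarts = cfg$kmeansRestarts))
  write.csv(model@clusterRanges, paths$clusterRanges, row.names = FALSE,
            quote = FALSE)
  strings <- stage("symbolize", symbolize(stepTables, model))
  writeSymbolStrings(strings, paths$symbols)

  descTables <- list()
  for (kind in cfg$matrixKinds) {
    say("encoding %s matrices", kind)
    mats <- stage(paste0("encode-", kind), buildCohortMatrices(strings, kind))
    for (m in mats)
      writeRLEMatrixCSV(m, file.path(paths$matricesDir,
                                     sprintf("%s_%s.csv", m@animalId, kind)))
    descTables[[kind]] <- stage(paste0("describe-", kind), descriptorTable(mats))
    writeDescriptorCSV(descTables[[kind]], paths$descriptors(kind))
  }

  clusterTable <- descTables[[cfg$clusterKind]]
  selection <- stage("select",
    selectDescriptors(clusterTable, threshold = cfg$correlationThreshold))
  jsonlite::write_json(
    list(kind = cfg$clusterKind, threshold = cfg$correlationThreshold,
         kept = selection$kept, dropped = selection$dropped,
         correlation = selection$correlation),
    paths$selection, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

  feats <- if (cfg$useSelectedFeatures) selection$kept else rleDescriptorNames()
  say("clustering %d animals with k_path = %d on %s", nrow(clusterTable),
      cfg$kPath, paste(feats, collapse = ","))
  clustering <- stage("cluster",
    clusterWorms(clusterTable, features = feats, k = cfg$kPath,
                 seed = seeds[3], restarts = cfg$kmeansRestarts))
  assignDf <- data.frame(animal_id = names(clustering@assignment),
                         group = unname(clustering@groups),
                         cluster = unname(clustering@assignment))
  write.csv(assignDf, paths$assignment, row.names = FALSE, quote = FALSE)
  composition <- compositionTable(clustering)
  write.csv(composition, paths$composition, row.names = FALSE, quote = FALSE)

  cfgOnDisk <- cfg
  cfgOnDisk$simulate <- lapply(cfg$simulate, function(sp)
    list(group = sp$group, nAnimals = sp$nAnimals,
         params = sapply(slotNames("SimParams"),
                         function(sn) slot(sp$params, sn), simplify = FALSE)))
  cfgPath <- file.path(cfg$outDir, "config.json")
  jsonlite::write_json(unclass(cfgOnDisk), cfgPath, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(
    configMd5 = unname(tools::md5sum(cfgPath)),
    seeds = list(master = cfg$seed, cohort = seeds[1], stepKmeans = seeds[2],
                 wormKmeans = seeds[3]),
    packageVersion = as.character(utils::packageVersion("wormpath")),
    nAnimals = length(trajs),
    keptDescriptors = selection$kept,
    warnings = notes,
    files = list(trajectories = paths$trajectories, steps = paths$steps,
                 symbols = paths$symbols, assignment = paths$assignment,
                 composition = paths$composition))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  say("done: %d animals, %d clusters", length(trajs), cfg$kPath)
  invisible(list(stepTables = stepTables, model = model, strings = strings,
                 descriptors = descTables, selection = selection,
                 clustering = clustering, composition = composition,
                 manifest = manifest))
}
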