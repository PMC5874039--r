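# End-to-end workflow: simulate or load inputs, clean, screen variables,
# fit models, cross-validate, hindcast, diagnose, assign fossils, and write
# a manifest from which every artifact is reproducible.

subSeed <- function(seed, i)
  as.integer((as.numeric(seed) * 7919 + i) %% 2147483647)

#' Default pipeline configuration
#'
#' Defaults follow the conventional settings of the model family: maxent
#' with 1000 iterations, 1000 background points, regularization 1 and
#' convergence threshold 1e-5; 1000 pseudo-absences; 500 random-forest
#' trees; 50 cross-validation repetitions at a 75/25 split; a collinearity
#' threshold of 0.7; an assignment tie tolerance of 0.01.  Any override is
#' recorded in the output manifest.
#'
#' @param seed master RNG seed; every stage derives its own sub-seed.
#' @return a nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    scenario = NULL,              # set to list(nSpecies = ...) to simulate
    paths = list(climate_dir = NULL, occurrences = NULL, fossils = NULL),
    algorithms = c("maxent", "glm", "rf"),
    settings = list(
      maxent = list(iterations = 1000L, background = 1000L,
                    regularization = 1, tol = 1e-5),
      rf = list(trees = 500L),
      pseudoabsences = 1000L,
      evaluation = list(n_reps = 50L, split = 0.75),
      collinearity_threshold = 0.7,
      assignment = list(tie_tolerance = 0.01)
    )
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration from a YAML file
#'
#' Values in the file override the defaults of
#' \code{\link{pipelineConfig}}.
#'
#' @param path YAML file.
#' @return a configuration list.
#' @export
readPipelineConfig <- function(path) {
  mergeConfig(pipelineConfig(), yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Stages: simulate (or load) inputs, clean occurrences, select
#' non-collinear variables, fit each species x algorithm, cross-validate,
#' hindcast to each fossil's slices with clamping/MESS diagnostics, assign
#' or validate each fossil, and write models, maps, evaluation and
#' assignment JSON plus a manifest (configuration, seed, package version,
#' per-file checksums).  Re-running with an identical configuration and
#' seed reproduces every artifact, checksums included.
#'
#' @param config a configuration list (see \code{\link{pipelineConfig}}) or
#'   the path to a YAML file.
#' @param outDir output directory.
#' @return invisibly, a list with the in-memory stack, occurrence sets,
#'   models, evaluations, assignment reports, consensus table and the
#'   manifest path.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- mergeConfig(pipelineConfig(), config)
  badAlgo <- setdiff(config$algorithms, c("maxent", "glm", "rf"))
  if (length(badAlgo))
    stop(sprintf("unknown algorithm(s) in configuration: %s",
                 paste(badAlgo, collapse = ", ")))
  seed <- as.integer(config$seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  # ---- stage: inputs (simulate or load) ----
  if (!is.null(config$scenario)) {
    nSp <- config$scenario$nSpecies %||% 2L
    spec <- demoScenario(nSpecies = nSp, seed = seed)
    stack <- generateClimateStack(spec, seed = seed)
    slice0 <- getSlice(stack, 0)
    occSets <- lapply(seq_along(spec@species), function(i)
      sampleOccurrences(spec@species[[i]], slice0, spec@nOccurrences,
                        seed = subSeed(seed, i)))
    names(occSets) <- vapply(spec@species, speciesId, character(1))
    fossil <- plantFossil(spec@species[[1L]], stack,
                          targetSlice = spec@nSlices - 1L,
                          requireOutsideCurrent = TRUE,
                          seed = subSeed(seed, 100L),
                          candidates = names(occSets))
    fossils <- list(fossil)
    inputDir <- file.path(outDir, "inputs")
    writeClimateStack(stack, file.path(inputDir, "climate"))
    writeOccurrences(occSets, file.path(inputDir, "occurrences.csv"))
    writeFossils(fossils, file.path(inputDir, "fossils.csv"))
  } else {
    stack <- readClimateStack(config$paths$climate_dir)
    occSets <- readOccurrences(config$paths$occurrences)
    fossils <- readFossils(config$paths$fossils)
    slice0 <- getSlice(stack, 0)
  }

  # ---- stage: clean + variable screening ----
  occSets <- lapply(occSets, cleanOccurrences, grid = slice0)
  vars <- selectNoncollinear(slice0,
                             threshold = config$settings$collinearity_threshold)
  subGrid <- function(g) {
    g@variables <- g@variables[vars]
    g
  }
  stack@slices <- lapply(stack@slices, subGrid)
  slice0 <- getSlice(stack, 0)

  # ---- stage: fit + evaluate per species x algorithm ----
  st <- config$settings
  models <- list()
  evals <- list()
  modelDir <- file.path(outDir, "models")
  mapDir <- file.path(outDir, "maps")
  dir.create(modelDir, showWarnings = FALSE)
  dir.create(mapDir, showWarnings = FALSE)
  for (sp in names(occSets)) {
    occ <- occSets[[sp]]
    presEnv <- extractEnv(occ, slice0)
    i <- match(sp, names(occSets))
    bg <- drawBackground(slice0, st$maxent$background, "background",
                         seed = subSeed(seed, 200L + i))
    pa <- drawBackground(slice0, st$pseudoabsences, "pseudo-absence",
                         occurrences = occ, seed = subSeed(seed, 300L + i))
    bgEnv <- extractEnv(bg, slice0)
    paEnv <- extractEnv(pa, slice0)
    for (algo in config$algorithms) {
      fitFun <- switch(algo,
        maxent = function(p, b) fitMaxent(p, b, maxentSettings(
          st$maxent$iterations, st$maxent$regularization, st$maxent$tol)),
        glm = fitGlm,
        rf = function(p, a) fitRf(p, a, nTrees = st$rf$trees,
                                  seed = subSeed(seed, 400L + i)))
      contrast <- if (algo == "maxent") bgEnv else paEnv
      model <- fitFun(presEnv, contrast)
      key <- paste(sp, algo, sep = ".")
      models[[key]] <- model
      ev <- crossValidate(fitFun, presEnv, contrast,
                          nReps = st$evaluation$n_reps,
                          splitFraction = st$evaluation$split,
                          seed = subSeed(seed, 500L + i))
      evals[[key]] <- ev
      writeNicheModel(model, file.path(modelDir, paste0(key, ".json")))
      writeSuitabilityMap(predictMap(model, slice0, speciesId = sp),
                          file.path(mapDir, paste0(key, "_0kyr.asc")))
      jsonlite::write_json(
        list(species = sp, algorithm = algo, contrast = model@trainingSummary$contrastMode,
             mean_auc = ev@meanAuc, sd_auc = ev@sdAuc,
             mean_tss = ev@meanTss, sd_tss = ev@sdTss,
             per_rep = ev@perRep),
        file.path(outDir, paste0("evaluation_", key, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
    }
  }

  # ---- stage: inter-algorithm map agreement ----
  mapCor <- list()
  if (length(config$algorithms) > 1L) {
    for (sp in names(occSets)) {
      pairs <- utils::combn(config$algorithms, 2, simplify = FALSE)
      mapCor[[sp]] <- lapply(pairs, function(pr) {
        a <- predictMap(models[[paste(sp, pr[1], sep = ".")]], slice0,
                        speciesId = sp)
        b <- predictMap(models[[paste(sp, pr[2], sep = ".")]], slice0,
                        speciesId = sp)
        list(pair = paste(pr, collapse = "-"), r = mapCorrelation(a, b))
      })
    }
    jsonlite::write_json(mapCor, file.path(outDir, "map_correlations.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # ---- stage: fossil assignment / validation ----
  reports <- list()
  consensus <- list()
  for (f in fossils) {
    if (length(f@candidates)) {
      perAlgo <- lapply(config$algorithms, function(algo) {
        cands <- lapply(f@candidates, function(sp) list(
          species = sp, model = models[[paste(sp, algo, sep = ".")]],
          occurrences = occSets[[sp]]))
        assignFossil(cands, f, stack,
                     tieTolerance = st$assignment$tie_tolerance)
      })
      names(perAlgo) <- config$algorithms
      heads <- vapply(perAlgo, headline, character(1))
      consensus[[f@fossilId]] <- list(
        headlines = as.list(heads),
        agreement = max(table(heads)))
      reports[[f@fossilId]] <- perAlgo
      jsonlite::write_json(
        list(fossil = f@fossilId,
             slices = perAlgo[[1]]@slicesEvaluated,
             per_algorithm = lapply(perAlgo, function(r) list(
               headline = r@headline, ranking = r@ranking,
               per_candidate = r@perCandidate, diagnostics = r@diagnostics)),
             consensus = consensus[[f@fossilId]]),
        file.path(outDir, paste0("assignment_", f@fossilId, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
    } else {
      sp <- vapply(occSets, speciesId, character(1))[1]
      perAlgo <- lapply(config$algorithms, function(algo)
        validateAgainstFossil(models[[paste(sp, algo, sep = ".")]],
                              occSets[[sp]], f, stack))
      names(perAlgo) <- config$algorithms
      reports[[f@fossilId]] <- perAlgo
      jsonlite::write_json(
        list(fossil = f@fossilId, species = sp, per_algorithm = perAlgo),
        file.path(outDir, paste0("validation_", f@fossilId, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
    }
  }

  # ---- stage: manifest ----
  files <- sort(list.files(outDir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(outDir, files))
  manifest <- list(
    package = "paleoSDM",
    version = as.character(utils::packageVersion("paleoSDM")),
    seed = seed,
    config = config,
    variables_selected = vars,
    checksums = stats::setNames(as.list(unname(sums)), files))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(stack = stack, occurrences = occSets, models = models,
                 evaluations = evals, reports = reports,
                 consensus = consensus, manifest = manifestPath,
                 outDir = outDir))
}
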