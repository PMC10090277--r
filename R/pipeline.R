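## End-to-end orchestration: 2D stages (transform -> descriptors -> heuristic
## MLR -> GEP -> validation) and 3D stages (align -> fields -> PLS ->
## contours -> external validation -> candidate prediction) from one config,
## with deterministic JSON reports. Reports avoid timestamps so a rerun with
## the same config and seed is byte-identical.

writeReport <- function(x, path) {
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

linearModelToList <- function(m) {
  list(descriptors = names(m@coefficients),
       intercept = m@intercept,
       coefficients = as.list(m@coefficients),
       t_stats = as.list(m@tStats),
       r2 = m@r2, r2cv = m@r2cv, s2 = m@s2, f = m@fStat, n = m@n)
}

#' Run the QSAR pipeline from a single configuration
#'
#' `config` is a named list (or path to a JSON file holding one) with
#' entries:
#' \describe{
#'   \item{activities}{CSV path of the compound table
#'     (see [readCompoundTable()]); required.}
#'   \item{descriptors}{CSV path(s) of imported descriptors — enables the
#'     2D stages `hm`, `gep`.}
#'   \item{molecules}{JSON (or SDF) path of 3D molecules — enables the 3D
#'     stages `align`, `comsia`, and `predict` when `candidates` is given.}
#'   \item{candidates}{JSON/SDF path of candidate molecules to score.}
#'   \item{stages}{subset of c("hm","gep","comsia","predict"); defaults to
#'     every stage its inputs enable.}
#'   \item{seed}{integer master seed.}
#'   \item{outDir}{report directory (created if missing).}
#'   \item{offset, hm, gep, comsia}{optional per-module parameter lists.}
#' }
#'
#' Per-stage JSON reports, a combined `report.json`, and a `log.txt` with
#' the seeds and package version are written to `outDir`. Candidate
#' predictions are ranked by predicted activity, most active first.
#'
#' @param config named list or JSON file path.
#' @return the combined report, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$activities)) stop("config$activities is required")
  if (is.null(config$outDir)) stop("config$outDir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  offset <- if (is.null(config$offset)) 6 else config$offset

  dataset <- readCompoundTable(config$activities, offset = offset)
  stages <- config$stages
  if (is.null(stages)) {
    stages <- character(0)
    if (!is.null(config$descriptors)) stages <- c(stages, "hm", "gep")
    if (!is.null(config$molecules)) stages <- c(stages, "comsia")
    if (!is.null(config$candidates)) stages <- c(stages, "predict")
  }
  if ("predict" %in% stages && !"comsia" %in% stages)
    stop("stage 'predict' needs the comsia stage (missing upstream model)")

  report <- list(seed = seed, offset = offset,
                 n_compounds = length(dataset),
                 stages = as.list(stages))
  logLines <- c(paste0("mustardQSAR ",
                       as.character(utils::packageVersion("mustardQSAR"))),
                paste0("seed: ", seed),
                paste0("stages: ", paste(stages, collapse = ", ")))

  split <- splitLabels(dataset)
  act <- activities(dataset)
  trainIds <- names(split)[split == "train"]
  testIds <- names(split)[split == "test"]

  if (any(c("hm", "gep") %in% stages)) {
    if (is.null(config$descriptors))
      stop("stage 'hm'/'gep' needs config$descriptors (missing upstream input)")
    desc <- assembleDescriptors(dataset, imported = config$descriptors)
    Xall <- descriptorValues(desc)
    Xtr <- Xall[trainIds, , drop = FALSE]
    Xte <- Xall[testIds, , drop = FALSE]
  }

  if ("hm" %in% stages) {
    hmCfg <- config$hm
    trace <- heuristicSearch(
      Xtr, act[trainIds],
      maxSize = if (is.null(hmCfg$maxSize)) 7 else hmCfg$maxSize,
      collinearityMax = if (is.null(hmCfg$collinearityMax)) 0.8
                        else hmCfg$collinearityMax,
      beam = if (is.null(hmCfg$beam)) 10 else hmCfg$beam,
      delta = if (is.null(hmCfg$delta)) 0.02 else hmCfg$delta)
    model <- chosenModel(trace)
    hmVal <- if (length(testIds))
      validationToList(validationReport(
        act[trainIds], predict(model, Xtr),
        act[testIds], predict(model, Xte), q2Loo = model@r2cv),
        act[testIds], predict(model, Xte))
      else validationToList(validationReport(
        act[trainIds], predict(model, Xtr), q2Loo = model@r2cv))
    hmReport <- list(chosen_size = trace@chosenSize,
                     model = linearModelToList(model),
                     per_size = trace@sizeStats,
                     correlation_matrix = trace@correlationMatrix,
                     validation = hmVal)
    writeReport(hmReport, file.path(outDir, "hm.json"))
    report$hm <- hmReport
  }

  if ("gep" %in% stages) {
    gepCfg <- config$gep
    cfgArgs <- list(seed = seed + 101L)
    for (k in c("populationSize", "maxGenerations", "h", "nGenes"))
      if (!is.null(gepCfg[[k]])) cfgArgs[[k]] <- as.integer(gepCfg[[k]])
    if (!is.null(gepCfg$fitnessTarget))
      cfgArgs$fitnessTarget <- gepCfg$fitnessTarget
    if (!is.null(gepCfg$seed)) cfgArgs$seed <- as.integer(gepCfg$seed)
    gcfg <- do.call(new, c(list("GEPConfig"), cfgArgs))
    terminalMap <- stats::setNames(colnames(Xtr),
                                   paste0("X", seq_len(ncol(Xtr)) - 1L))
    Xg <- Xtr; colnames(Xg) <- names(terminalMap)
    Xgte <- Xte; if (ncol(Xgte)) colnames(Xgte) <- names(terminalMap)
    res <- evolveGEP(Xg, act[trainIds],
                     if (length(testIds)) Xgte else NULL,
                     if (length(testIds)) act[testIds] else NULL,
                     config = gcfg)
    gepReport <- list(expression = res@expression,
                      terminal_map = as.list(terminalMap),
                      train_r2 = res@trainR2, test_r2 = res@testR2,
                      train_mae = res@trainMAE, test_mae = res@testMAE,
                      generation_found = res@generationFound,
                      seed = gcfg@seed)
    writeReport(gepReport, file.path(outDir, "gep.json"))
    pred <- chromosomePredict(res@bestChromosome, Xg,
                              defaultFunctionSet(ncol(Xg)))
    utils::write.csv(
      data.frame(id = trainIds, observed = unname(act[trainIds]),
                 predicted = unname(pred)),
      file.path(outDir, "gep_train_predictions.csv"), row.names = FALSE,
      quote = FALSE)
    report$gep <- gepReport
    logLines <- c(logLines, paste0("gep seed: ", gcfg@seed))
  }

  comsiaFit <- NULL
  if ("comsia" %in% stages) {
    if (is.null(config$molecules))
      stop("stage 'comsia' needs config$molecules (missing upstream input)")
    molecules <- readAnyMolecules(config$molecules)
    molIds <- vapply(molecules, function(m) m@id, character(1))
    if (!all(compoundIds(dataset) %in% molIds))
      stop("molecule missing for compound: ",
           setdiff(compoundIds(dataset), molIds)[1L])
    molecules <- molecules[match(compoundIds(dataset), molIds)]
    cCfg <- config$comsia
    spacing <- if (is.null(cCfg$spacing)) 2 else cCfg$spacing
    margin <- if (is.null(cCfg$margin)) 4 else cCfg$margin
    alpha <- if (is.null(cCfg$alpha)) 0.3 else cCfg$alpha
    maxComp <- if (is.null(cCfg$maxComp)) 10 else cCfg$maxComp
    templateId <- if (is.null(cCfg$template))
      names(which.min(ic50Values(dataset))) else cCfg$template
    tpl <- molecules[[match(templateId, compoundIds(dataset))]]
    aligned <- lapply(molecules, function(m)
      if (identical(m@id, tpl@id)) m else kabschAlign(tpl, m)$molecule)
    grid <- buildGrid(aligned, spacing = spacing, margin = margin)
    rawFields <- comsiaFieldMatrix(aligned, grid, alpha = alpha)
    trIdx <- match(trainIds, compoundIds(dataset))
    teIdx <- match(testIds, compoundIds(dataset))
    rawTrain <- initialize(rawFields,
                           values = rawFields@values[trIdx, , drop = FALSE])
    fit <- comsiaPLS(rawTrain, act[trainIds], maxComp = maxComp)
    comsiaFit <- list(fit = fit, grid = grid, template = tpl,
                      alpha = alpha, raw = rawFields)
    valList <- NULL
    if (length(teIdx)) {
      rawTest <- initialize(rawFields,
                            values = rawFields@values[teIdx, , drop = FALSE])
      testProj <- comsiaApplyPretreat(rawTest, fit$fields)
      predTest <- predict(fit$model, testProj)
      valList <- validationToList(
        validationReport(act[trainIds], predict(fit$model, fit$fields),
                         act[testIds], predTest, q2Loo = fit$model@q2),
        act[testIds], predTest)
    }
    comsiaReport <- list(
      template = tpl@id, spacing = spacing, margin = margin, alpha = alpha,
      grid_counts = fit$fields@grid@counts,
      q2 = fit$model@q2, onc = fit$model@ncomp, r2 = fit$model@r2,
      see = fit$model@see, f = fit$model@fStat,
      field_fractions = as.list(fit$model@fieldFractions),
      contour_levels = fit$contours@levels,
      validation = valList)
    writeReport(comsiaReport, file.path(outDir, "comsia.json"))
    report$comsia <- comsiaReport
    logLines <- c(logLines, paste0("comsia template: ", tpl@id))
  }

  if ("predict" %in% stages) {
    if (is.null(config$candidates))
      stop("stage 'predict' needs config$candidates (missing upstream input)")
    cands <- readAnyMolecules(config$candidates)
    alignedC <- lapply(cands, function(m)
      kabschAlign(comsiaFit$template, m)$molecule)
    rawC <- comsiaFieldMatrix(alignedC, comsiaFit$grid,
                              fields = unique(comsiaFit$raw@fieldLabels),
                              alpha = comsiaFit$alpha)
    projC <- comsiaApplyPretreat(rawC, comsiaFit$fit$fields)
    predC <- predict(comsiaFit$fit$model, projC)
    ranked <- data.frame(
      name = vapply(alignedC, function(m) m@id, character(1)),
      predicted_activity = unname(predC))
    ranked <- ranked[order(-ranked$predicted_activity), ]
    rownames(ranked) <- NULL
    writeReport(ranked, file.path(outDir, "predictions.json"))
    utils::write.csv(ranked, file.path(outDir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    report$predictions <- ranked
  }

  writeReport(report, file.path(outDir, "report.json"))
  writeLines(logLines, file.path(outDir, "log.txt"))
  invisible(report)
}

## dispatch on file extension: the package's JSON interchange format or SDF
readAnyMolecules <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) readMoleculeSDF(path)
  else readMoleculeSet(path)
}
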