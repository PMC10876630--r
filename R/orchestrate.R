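#' Encode a dataset: bit matrices and similarity matrices per modality
#'
#' Reads the canonical drug-feature and interaction files, builds the
#' per-modality vocabulary, bit matrix and similarity matrix, and (when
#' `outputDir` is given) writes the matrices as compressed delimited
#' text.
#'
#' @param featuresPath drug-feature file (drug_id / modality / token).
#' @param interactionsPath interactions file (drug_a / drug_b / event).
#' @param metric similarity metric, "jaccard" (default) or "cosine".
#' @param modalities modality subset (default: all in the file).
#' @param outputDir optional artifact directory.
#' @param nEvents number of event classes (default inferred).
#' @return list with `featureTable`, `records`, `vocabularies`,
#'   `bitMatrices`, `similarities`.
#' @export
runEncode <- function(featuresPath, interactionsPath,
                      metric = "jaccard", modalities = NULL,
                      outputDir = NULL, nEvents = NULL) {
  if (!file.exists(featuresPath))
    stop(sprintf("features file not found: %s", featuresPath), call. = FALSE)
  if (!file.exists(interactionsPath))
    stop(sprintf("interactions file not found: %s", interactionsPath),
         call. = FALSE)
  featureTable <- readDrugFeatures(featuresPath)
  if (is.null(modalities)) modalities <- modalityNames(featureTable)
  records <- loadInteractions(interactionsPath, featureTable,
                              nEvents = nEvents)
  vocabularies <- lapply(modalities, function(m) buildVocabulary(featureTable, m))
  names(vocabularies) <- modalities
  bitMatrices <- lapply(vocabularies, function(v) encodeBitMatrix(featureTable, v))
  similarities <- lapply(bitMatrices, function(b) similarityMatrix(b, metric))
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    for (m in modalities) {
      writeBitMatrix(bitMatrices[[m]],
                     file.path(outputDir, sprintf("bits_%s.tsv.gz", m)))
      sim <- similarities[[m]]
      simDf <- data.frame(drug_id = sim@drugs, sim@values, check.names = FALSE)
      con <- gzfile(file.path(outputDir, sprintf("similarity_%s.tsv.gz", m)), "w")
      utils::write.table(simDf, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
  }
  list(featureTable = featureTable, records = records,
       vocabularies = vocabularies, bitMatrices = bitMatrices,
       similarities = similarities)
}

#' Assemble a fold-assigned PairDataset from encoded artifacts
#'
#' @param encoded result of [runEncode()].
#' @param k cross-validation folds.
#' @param seed fold seed.
#' @param augment include mirrored pair orientations.
#' @return a [PairDataset-class] with folds assigned.
#' @export
buildPairDataset <- function(encoded, k = 5L, seed = 1L, augment = FALSE) {
  ds <- pairDataset(encoded$records, encoded$similarities, augment = augment)
  assignFolds(ds, k = k, seed = seed)
}

#' Train the fused model on all records and save artifacts
#'
#' @param dataset a [PairDataset-class].
#' @param config a [modelConfig()]; defaults are derived from the dataset.
#' @param outputDir optional directory for the checkpoint
#'   (`model.bin` / `model.yaml` / `model.history.tsv`).
#' @param ... forwarded to [modelConfig()] when `config` is NULL.
#' @return the fitted `trainedModel`.
#' @export
runTrain <- function(dataset, config = NULL, outputDir = NULL, ...) {
  if (is.null(config)) {
    lens <- vapply(pairMatrices(dataset), ncol, 1L)
    config <- modelConfig(lens, nEvents(dataset), ...)
  }
  model <- trainModel(buildModel(config), pairMatrices(dataset),
                      interactionRecords(dataset)$event)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    saveModel(model, file.path(outputDir, "model"))
  }
  model
}

#' Cross-validated evaluation run
#'
#' @param dataset a fold-assigned [PairDataset-class].
#' @param config a [modelConfig()] or [baselineConfig()]; NULL uses the
#'   default fused model.
#' @param outputDir optional directory for `report.tsv` / `report.txt`.
#' @param ... forwarded to [evaluateCV()].
#' @return the per-fold `evalReport`.
#' @export
runEvaluate <- function(dataset, config = NULL, outputDir = NULL, ...) {
  if (is.null(config)) {
    lens <- vapply(pairMatrices(dataset), ncol, 1L)
    config <- modelConfig(lens, nEvents(dataset))
  }
  report <- evaluateCV(dataset, config, ...)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(outputDir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::capture.output(formatReport(report),
                          file = file.path(outputDir, "report.txt"))
  }
  report
}

# all non-empty modality subsets in canonical experiment-table order:
# singles, pairs, triples, the full set (each block in the order the
# modalities were declared)
modalitySubsets <- function(modalities) {
  out <- list()
  for (size in seq_along(modalities))
    out <- c(out, utils::combn(modalities, size, simplify = FALSE))
  out
}

#' Feature-set ablation over all modality subsets
#'
#' Trains and evaluates the fused model on every non-empty subset of the
#' available modalities (15 subsets for 4 modalities: 4 singles, 6 pairs,
#' 4 triples, 1 quadruple), sharing one fold assignment so rows are
#' comparable.
#'
#' @param dataset a fold-assigned [PairDataset-class].
#' @param config a [modelConfig()] template (input lengths are adapted
#'   per subset); NULL uses defaults.
#' @param foldsToRun optional fold subset (e.g. `1L` for a single
#'   held-out fold).
#' @param outputDir optional artifact directory.
#' @param verbose progress messages.
#' @return `evalReport` with one block of rows per subset, in table
#'   order.
#' @export
runAblation <- function(dataset, config = NULL, foldsToRun = NULL,
                        outputDir = NULL, verbose = FALSE) {
  modalities <- names(pairMatrices(dataset))
  if (length(modalities) < 2L)
    stop("ablation needs at least 2 modalities", call. = FALSE)
  if (is.null(config)) {
    lens <- vapply(pairMatrices(dataset), ncol, 1L)
    config <- modelConfig(lens, nEvents(dataset))
  }
  subsets <- modalitySubsets(modalities)
  reports <- lapply(subsets, function(sub) {
    evaluateCV(dataset, config, modalities = sub, foldsToRun = foldsToRun,
               verbose = verbose)
  })
  report <- do.call(rbind, reports)
  class(report) <- c("evalReport", "data.frame")
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(outputDir, "ablation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' Layer/activation hyperparameter grid
#'
#' Cross-product over dense-block count, input (convolution) activation
#' and dense activation, mirroring the hyperparameter experiment: each
#' cell trains/evaluates the fused model and contributes one summary row.
#' The dense widths for L blocks are the first L of 1024/512/256/128.
#'
#' @param dataset a fold-assigned [PairDataset-class].
#' @param layers integer vector of dense-block counts (default 2:4).
#' @param convActivations candidate input activations (default "tanh").
#' @param denseActivations candidate dense activations
#'   (default c("tanh", "elu", "relu")).
#' @param config training-hyperparameter template; NULL for defaults.
#' @param foldsToRun optional fold subset.
#' @param metricLabel similarity label stamped on each row (default
#'   "Jaccard").
#' @param outputDir optional artifact directory.
#' @param verbose progress messages.
#' @return data.frame with one row per grid cell: layers, inputActivation,
#'   denseActivation, similarity, ACC/F1/AUC/AUPR means.
#' @export
runGrid <- function(dataset, layers = 2:4, convActivations = "tanh",
                    denseActivations = c("tanh", "elu", "relu"),
                    config = NULL, foldsToRun = NULL,
                    metricLabel = "Jaccard", outputDir = NULL,
                    verbose = FALSE) {
  if (!length(layers) || !length(convActivations) || !length(denseActivations))
    stop("empty hyperparameter grid", call. = FALSE)
  widths <- c(1024L, 512L, 256L, 128L)
  if (max(layers) > length(widths))
    stop(sprintf("at most %d dense blocks supported", length(widths)),
         call. = FALSE)
  lens <- vapply(pairMatrices(dataset), ncol, 1L)
  if (is.null(config)) config <- modelConfig(lens, nEvents(dataset))
  cells <- expand.grid(layers = layers, convActivation = convActivations,
                       denseActivation = denseActivations,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    submodels <- lapply(lens, function(L)
      submodelSpec(L, convActivation = cell$convActivation,
                   denseSizes = widths[seq_len(cell$layers)],
                   denseActivation = cell$denseActivation))
    cfg <- modelConfig(lens, nEvents(dataset), fusion = config$fusion,
                       epochs = config$epochs, batchSize = config$batchSize,
                       learningRate = config$learningRate, seed = config$seed,
                       patience = config$patience,
                       validationFraction = config$validationFraction,
                       submodels = submodels)
    rep <- evaluateCV(dataset, cfg, foldsToRun = foldsToRun,
                      label = sprintf("L%d/%s/%s", cell$layers,
                                      cell$convActivation,
                                      cell$denseActivation),
                      verbose = verbose)
    agg <- summarizeReport(rep)
    data.frame(layers = cell$layers, inputActivation = cell$convActivation,
               denseActivation = cell$denseActivation,
               similarity = metricLabel, accuracy = agg$accuracy,
               f1Macro = agg$f1Macro, aucMicro = agg$aucMicro,
               auprMicro = agg$auprMicro)
  })
  grid <- do.call(rbind, rows)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(grid, file.path(outputDir, "grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  grid
}

#' Compare the fused model against baselines on shared folds
#'
#' Evaluates the fused model and every requested baseline on one shared
#' fold assignment, then runs a paired t-test of the fused model against
#' each baseline and a one-way ANOVA across all models, for every metric
#' column, at the given significance level.
#'
#' @param dataset a fold-assigned [PairDataset-class].
#' @param config fused-model [modelConfig()]; NULL for defaults.
#' @param baselines list of [baselineConfig()]s (default: random forest,
#'   KNN, logistic regression).
#' @param alpha significance level (default 0.05).
#' @param outputDir optional artifact directory.
#' @param verbose progress messages.
#' @return list with `report` (per-fold rows for all models), `summary`,
#'   `tTests` (fused vs each baseline per metric) and `anova` (per
#'   metric).
#' @export
runCompare <- function(dataset, config = NULL,
                       baselines = list(baselineConfig("random_forest"),
                                        baselineConfig("knn"),
                                        baselineConfig("logistic_regression")),
                       alpha = 0.05, outputDir = NULL, verbose = FALSE) {
  if (is.null(config)) {
    lens <- vapply(pairMatrices(dataset), ncol, 1L)
    config <- modelConfig(lens, nEvents(dataset))
  }
  main <- evaluateCV(dataset, config, verbose = verbose)
  reports <- c(list(main),
               lapply(baselines, function(b)
                 evaluateCV(dataset, b, verbose = verbose)))
  report <- do.call(rbind, reports)
  class(report) <- c("evalReport", "data.frame")
  metrics <- c("accuracy", "f1Macro", "aucMicro", "auprMicro")
  mainLabel <- main$model[1]
  tTests <- do.call(rbind, lapply(reports[-1], function(r) {
    do.call(rbind, lapply(metrics, function(m) {
      tt <- pairedTTest(main[[m]], r[[m]], alpha = alpha)
      data.frame(comparison = sprintf("%s vs %s", mainLabel, r$model[1]),
                 metric = m, t = tt$t, p = tt$p,
                 significant = tt$significant, meanDiff = tt$meanDiff)
    }))
  }))
  anova <- do.call(rbind, lapply(metrics, function(m) {
    groups <- lapply(reports, `[[`, m)
    av <- anovaOneway(groups, alpha = alpha)
    data.frame(metric = m, F = av$F, p = av$p, significant = av$significant)
  }))
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(outputDir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tTests, file.path(outputDir, "t_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(anova, file.path(outputDir, "anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(report = report, summary = summarizeReport(report), tTests = tTests,
       anova = anova)
}
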