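#' Cross-validated evaluation of the fused model or a baseline
#'
#' For every fold: train on the remaining folds, predict class
#' probabilities on the held-out records, and score accuracy, macro and
#' micro F1, micro AUC, micro AUPR.  The same fold assignment can be
#' shared across models, which keeps model comparisons paired.
#'
#' @param dataset a [PairDataset-class] with folds assigned
#'   (see [assignFolds()]).
#' @param config a [modelConfig()] or a [baselineConfig()].
#' @param modalities modality subset to use (default: all in the dataset).
#' @param label report label (default from the config).
#' @param foldsToRun optional subset of fold indices (default all).
#' @param symmetrize average held-out predictions over both pair
#'   orientations (default TRUE); the event of an unordered pair should
#'   not depend on which drug is listed first.
#' @param verbose report per-fold progress.
#' @return an `evalReport` data.frame: one row per fold with columns
#'   model, features, fold, accuracy, f1Macro, f1Micro, aucMicro,
#'   auprMicro, plus attribute `probabilities` (held-out score matrices).
#' @export
evaluateCV <- function(dataset, config, modalities = NULL, label = NULL,
                       foldsToRun = NULL, symmetrize = TRUE,
                       verbose = FALSE) {
  folds <- foldAssignment(dataset)
  if (!length(folds)) stop("dataset has no fold assignment; call assignFolds()",
                           call. = FALSE)
  if (is.null(modalities)) modalities <- names(pairMatrices(dataset))
  miss <- setdiff(modalities, names(pairMatrices(dataset)))
  if (length(miss))
    stop(sprintf("modalities not in dataset: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  Xs <- pairMatrices(dataset)[modalities]
  y <- interactionRecords(dataset)$event
  E <- nEvents(dataset)
  if (is.null(foldsToRun)) foldsToRun <- sort(unique(folds))
  isBaseline <- inherits(config, "baselineConfig")
  if (is.null(label))
    label <- if (isBaseline) config$kind else "fusedConv"

  rows <- list(); probs <- list()
  for (f in foldsToRun) {
    test <- folds == f
    XsTest <- lapply(Xs, function(X) X[test, , drop = FALSE])
    if (isBaseline) {
      fit <- fitBaseline(config, Xs, y, E, train = !test)
      P <- predictBaseline(fit, XsTest)
      if (symmetrize)
        P <- (P + predictBaseline(fit, lapply(XsTest, swapPairHalves))) / 2
    } else {
      cfg <- config
      if (!identical(cfg$modalities, modalities)) {
        lens <- vapply(Xs, ncol, 1L)
        cfg <- rebuildConfigForModalities(cfg, lens)
      }
      model <- trainModel(buildModel(cfg),
                          lapply(Xs, function(X) X[!test, , drop = FALSE]),
                          y[!test])
      P <- predictProba(model, XsTest, symmetrize = symmetrize)
    }
    yPred <- max.col(P, ties.method = "first") - 1L
    yTest <- y[test]
    rows[[length(rows) + 1L]] <- data.frame(
      model = label, features = paste(modalities, collapse = "+"), fold = f,
      accuracy = accuracyScore(yTest, yPred),
      f1Macro = f1Multiclass(yTest, yPred, labels = 0:(E - 1L)),
      f1Micro = f1Multiclass(yTest, yPred, labels = 0:(E - 1L),
                             averaging = "micro"),
      aucMicro = aucMicro(oneHot(yTest, E), P),
      auprMicro = auprMicro(oneHot(yTest, E), P))
    probs[[as.character(f)]] <- P
    if (verbose)
      message(sprintf("[%s] fold %d: acc %.4f", label, f,
                      rows[[length(rows)]]$accuracy))
  }
  report <- do.call(rbind, rows)
  attr(report, "probabilities") <- probs
  class(report) <- c("evalReport", class(report))
  report
}

# rebuild a model config for a modality subset / new input lengths while
# keeping the training hyperparameters and per-branch architecture
rebuildConfigForModalities <- function(config, inputLengths) {
  proto <- config$submodels[[1]]
  submodels <- lapply(inputLengths, function(L) {
    s <- proto; s$inputLength <- as.integer(L); s
  })
  modelConfig(inputLengths, config$nEvents, fusion = config$fusion,
              epochs = config$epochs, batchSize = config$batchSize,
              learningRate = config$learningRate, seed = config$seed,
              patience = config$patience,
              validationFraction = config$validationFraction,
              submodels = submodels)
}

#' Aggregate an evalReport over folds
#'
#' @param report an `evalReport` from [evaluateCV()] (possibly several
#'   rbind-ed together).
#' @return data.frame with the fold-mean of every metric per
#'   (model, features) pair, in the column order ACC, F1, AUC, AUPR.
#' @export
summarizeReport <- function(report) {
  agg <- stats::aggregate(
    report[, c("accuracy", "f1Macro", "f1Micro", "aucMicro", "auprMicro")],
    by = list(model = report$model, features = report$features), mean)
  agg[order(agg$model, agg$features), , drop = FALSE]
}

#' Render a report as a fixed-width text table
#'
#' Mirrors the ACC / F1 / AUC / AUPR column order of the experiment
#' tables.
#'
#' @param report an `evalReport` or its [summarizeReport()] aggregate.
#' @param file optional path; when given the table is also written there.
#' @return the formatted lines, invisibly printed.
#' @export
formatReport <- function(report, file = NULL) {
  if ("fold" %in% names(report)) report <- summarizeReport(report)
  lines <- c(
    sprintf("%-12s %-14s %7s %7s %7s %7s", "Model", "Features",
            "ACC", "F1", "AUC", "AUPR"),
    sprintf("%-12s %-14s %7.4f %7.4f %7.4f %7.4f",
            report$model, report$features, report$accuracy,
            report$f1Macro, report$aucMicro, report$auprMicro))
  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}
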