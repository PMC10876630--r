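#' Baseline model configuration
#'
#' The comparison lineup operating on the same pair vectors as the fused
#' model: random forest (100 trees), k-nearest neighbours (k = 4),
#' multinomial logistic regression (library defaults), and the dense-only
#' network ablation (the fused model with its convolutional front
#' removed).  All modalities' pair vectors are concatenated into one flat
#' feature vector for the classical methods.
#'
#' @param kind one of "random_forest", "knn", "logistic_regression",
#'   "dnn_ablation".
#' @param rfTrees random-forest tree count (default 100).
#' @param knnNeighbors neighbour count (default 4).
#' @param seed RNG seed.
#' @param epochs,batchSize,learningRate training settings for the
#'   dense-only network ablation.
#' @return a `baselineConfig` list.
#' @export
baselineConfig <- function(kind = c("random_forest", "knn",
                                    "logistic_regression", "dnn_ablation"),
                           rfTrees = 100L, knnNeighbors = 4L, seed = 1L,
                           epochs = 50L, batchSize = 256L,
                           learningRate = 1e-3) {
  kind <- match.arg(kind)
  if (rfTrees < 1L || knnNeighbors < 1L)
    stop("tree and neighbour counts must be positive", call. = FALSE)
  structure(list(kind = kind, rfTrees = as.integer(rfTrees),
                 knnNeighbors = as.integer(knnNeighbors),
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate),
            class = "baselineConfig")
}

#' Fit a baseline on training rows
#'
#' @param config a [baselineConfig()].
#' @param Xs named list of per-modality pair-vector matrices.
#' @param y integer event labels.
#' @param nEvents number of event classes.
#' @param train logical vector selecting training rows (default all).
#' @return a fitted `baselineFit` exposing class probabilities through
#'   [predictBaseline()].
#' @export
fitBaseline <- function(config, Xs, y, nEvents, train = NULL) {
  stopifnot(inherits(config, "baselineConfig"))
  if (is.null(train)) train <- rep(TRUE, length(y))
  labels <- droplevels(factor(y[train], levels = 0:(nEvents - 1L)))
  fit <- switch(config$kind,
    random_forest = {
      X <- do.call(cbind, lapply(Xs, function(X) X[train, , drop = FALSE]))
      colnames(X) <- paste0("f", seq_len(ncol(X)))
      withSeed(config$seed,
               randomForest::randomForest(X, labels, ntree = config$rfTrees))
    },
    knn = {
      X <- do.call(cbind, lapply(Xs, function(X) X[train, , drop = FALSE]))
      caret::knn3(X, labels, k = config$knnNeighbors)
    },
    logistic_regression = {
      X <- do.call(cbind, lapply(Xs, function(X) X[train, , drop = FALSE]))
      df <- data.frame(.y = labels, X)
      withSeed(config$seed,
               nnet::multinom(.y ~ ., data = df,
                              MaxNWts = (ncol(X) + 2L) * nEvents + 100L,
                              trace = FALSE))
    },
    dnn_ablation = {
      lens <- vapply(Xs, ncol, 1L)
      cfg <- modelConfig(lens, nEvents, epochs = config$epochs,
                         batchSize = config$batchSize,
                         learningRate = config$learningRate,
                         seed = config$seed, useConv = FALSE)
      trainModel(buildModel(cfg),
                 lapply(Xs, function(X) X[train, , drop = FALSE]), y[train])
    })
  structure(list(kind = config$kind, fit = fit, nEvents = nEvents),
            class = "baselineFit")
}

#' Class probabilities from a fitted baseline
#'
#' @param fit a `baselineFit`.
#' @param Xs named list of per-modality matrices for the rows to score.
#' @return numeric (n, E) probability matrix.
#' @export
predictBaseline <- function(fit, Xs) {
  E <- fit$nEvents
  n <- nrow(Xs[[1]])
  if (n == 0L) return(matrix(0, 0L, E))
  if (fit$kind == "dnn_ablation") return(predictProba(fit$fit, Xs))
  X <- do.call(cbind, Xs)
  P <- switch(fit$kind,
    random_forest = {
      colnames(X) <- paste0("f", seq_len(ncol(X)))
      stats::predict(fit$fit, X, type = "prob")
    },
    knn = stats::predict(fit$fit, X, type = "prob"),
    logistic_regression = {
      p <- stats::predict(fit$fit, newdata = data.frame(X), type = "probs")
      if (is.null(dim(p))) {                    # 2-level multinom: P(level 2)
        lv <- fit$fit$lev
        p <- matrix(c(1 - p, p), nrow = n, dimnames = list(NULL, lv))
      }
      p
    })
  P <- as.matrix(P)
  # align columns to the full 0..E-1 label universe
  out <- matrix(0, n, E)
  cols <- suppressWarnings(as.integer(colnames(P)))
  if (length(cols) == E && !anyNA(cols)) out[, cols + 1L] <- P
  else if (ncol(P) == E) out <- P
  else if (!anyNA(cols)) out[, cols + 1L] <- P
  else stop("cannot align baseline probability columns", call. = FALSE)
  unname(out)
}
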