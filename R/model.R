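#' Per-modality submodel specification
#'
#' Describes one branch of the fused classifier: a 1-D valid convolution
#' (default one filter of kernel width 5, tanh), a flatten, then a stack
#' of dense blocks, each affine -> batch normalization -> activation ->
#' dropout (default sizes 1024/512/256, ELU, dropout 0.3).  The branch's
#' output width is the last dense size.  Setting `useConv = FALSE` removes
#' the convolutional front, yielding the dense-only ablation.
#'
#' @param inputLength length of the branch input vector (2N for pair
#'   vectors over N drugs).
#' @param convFilters number of convolution filters (default 1).
#' @param convKernel convolution kernel width (default 5).
#' @param convActivation activation after the convolution (default "tanh").
#' @param denseSizes integer vector of dense-layer widths
#'   (default `c(1024, 512, 256)`).
#' @param denseActivation activation inside dense blocks (default "elu").
#' @param dropout dropout rate in \[0, 1) (default 0.3).
#' @param batchNorm apply batch normalization in each dense block
#'   (default TRUE).
#' @param useConv keep the conv+flatten front (default TRUE).
#' @return a `submodelSpec` list.
#' @export
submodelSpec <- function(inputLength, convFilters = 1L, convKernel = 5L,
                         convActivation = "tanh",
                         denseSizes = c(1024L, 512L, 256L),
                         denseActivation = "elu", dropout = 0.3,
                         batchNorm = TRUE, useConv = TRUE) {
  inputLength <- as.integer(inputLength)
  if (useConv && convKernel > inputLength)
    stop(sprintf("kernel width %d exceeds input length %d",
                 convKernel, inputLength), call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  if (!length(denseSizes))
    stop("denseSizes must be non-empty", call. = FALSE)
  activationFun(convActivation); activationFun(denseActivation)
  structure(list(
    inputLength = inputLength, convFilters = as.integer(convFilters),
    convKernel = as.integer(convKernel), convActivation = convActivation,
    denseSizes = as.integer(denseSizes), denseActivation = denseActivation,
    dropout = dropout, batchNorm = batchNorm, useConv = useConv
  ), class = "submodelSpec")
}

#' Branch dimensions implied by a submodel specification
#'
#' @param spec a [submodelSpec()].
#' @return list with `convLength` (positions of the valid convolution, or
#'   NA without a conv front), `flatSize` (width entering the first dense
#'   layer) and `outputWidth` (the branch representation width).
#' @export
submodelDims <- function(spec) {
  if (spec$useConv) {
    convLength <- spec$inputLength - spec$convKernel + 1L
    flat <- convLength * spec$convFilters
  } else {
    convLength <- NA_integer_
    flat <- spec$inputLength
  }
  list(convLength = convLength, flatSize = flat,
       outputWidth = spec$denseSizes[length(spec$denseSizes)])
}

#' Fused multimodal model configuration
#'
#' One submodel per modality; their representations are fused and mapped
#' to an E-way softmax over interaction-event classes.  With
#' `fusion = "concat"` the branch outputs are concatenated and a single
#' affine layer produces the E logits; with `fusion = "average"` each
#' branch gets its own E-way softmax head and the class probabilities are
#' the arithmetic mean of the heads.  Training minimizes categorical
#' cross-entropy with Adam.
#'
#' @param inputLengths named integer vector: branch input length per
#'   modality.
#' @param nEvents number of event classes E (>= 2).
#' @param fusion "concat" (default) or "average".
#' @param epochs training epochs (default 100).
#' @param batchSize minibatch size (default 256).
#' @param learningRate Adam step size (default 1e-3).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param patience early-stopping patience in epochs; 0 disables early
#'   stopping (default 10).
#' @param validationFraction fraction of training rows held out to drive
#'   early stopping (default 0.1; ignored when patience is 0).
#' @param submodels optional named list of [submodelSpec()]s overriding
#'   the defaults built from `inputLengths`.
#' @param ... default arguments forwarded to [submodelSpec()] for every
#'   modality (e.g. `denseSizes`, `useConv = FALSE`).
#' @return a `modelConfig` list.
#' @export
modelConfig <- function(inputLengths, nEvents, fusion = c("concat", "average"),
                        epochs = 100L, batchSize = 256L, learningRate = 1e-3,
                        seed = 1L, patience = 10L, validationFraction = 0.1,
                        submodels = NULL, ...) {
  fusion <- match.arg(fusion)
  if (is.null(names(inputLengths)) || !length(inputLengths))
    stop("inputLengths must be a non-empty named vector (one per modality)",
         call. = FALSE)
  if (nEvents < 2L) stop("nEvents must be at least 2", call. = FALSE)
  if (is.null(submodels))
    submodels <- lapply(inputLengths, function(L) submodelSpec(L, ...))
  structure(list(
    modalities = names(inputLengths), nEvents = as.integer(nEvents),
    fusion = fusion, epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), learningRate = learningRate,
    seed = as.integer(seed), patience = as.integer(patience),
    validationFraction = validationFraction, submodels = submodels
  ), class = "modelConfig")
}

#' Build the fused model (untrained)
#'
#' Initializes all parameters (Glorot-uniform weights, zero biases, unit
#' batch-norm scale) deterministically from the configuration seed.
#'
#' @param config a [modelConfig()].
#' @return a `trainedModel` object with empty training history.
#' @export
buildModel <- function(config) {
  stopifnot(inherits(config, "modelConfig"))
  if (!length(config$modalities)) stop("at least one modality is required")
  params <- withSeed(config$seed, {
    p <- list(branches = lapply(config$submodels, initBranch))
    widths <- vapply(config$submodels,
                     function(s) submodelDims(s)$outputWidth, 1L)
    if (config$fusion == "concat") {
      p$head <- list(W = glorotInit(sum(widths), config$nEvents),
                     b = numeric(config$nEvents))
    } else {
      p$heads <- lapply(widths, function(w)
        list(W = glorotInit(w, config$nEvents), b = numeric(config$nEvents)))
    }
    p
  })
  structure(list(config = config, params = params,
                 history = data.frame(), trained = FALSE),
            class = "trainedModel")
}

# forward pass through all branches and the fusion head(s)
modelForward <- function(params, config, Xs, training = FALSE) {
  branches <- lapply(seq_along(config$modalities), function(i)
    forwardBranch(params$branches[[i]], config$submodels[[i]],
                  Xs[[i]], training = training))
  if (config$fusion == "concat") {
    Fmat <- do.call(cbind, lapply(branches, `[[`, "out"))
    P <- softmaxRows(addRow(Fmat %*% params$head$W, params$head$b))
    list(P = P, branches = branches, Fmat = Fmat)
  } else {
    Ps <- lapply(seq_along(branches), function(i)
      softmaxRows(addRow(branches[[i]]$out %*% params$heads[[i]]$W,
                         params$heads[[i]]$b)))
    P <- Reduce(`+`, Ps) / length(Ps)
    list(P = P, branches = branches, Ps = Ps)
  }
}

# gradients of mean categorical cross-entropy wrt all parameters
modelBackward <- function(params, config, fwd, Yhot) {
  n <- nrow(Yhot)
  grads <- list(branches = vector("list", length(config$modalities)))
  if (config$fusion == "concat") {
    dLogits <- (fwd$P - Yhot) / n
    grads$head <- list(W = crossprod(fwd$Fmat, dLogits),
                       b = colSums(dLogits))
    dF <- tcrossprod(dLogits, params$head$W)
    offset <- 0L
    for (i in seq_along(config$modalities)) {
      w <- submodelDims(config$submodels[[i]])$outputWidth
      dOut <- dF[, (offset + 1L):(offset + w), drop = FALSE]
      offset <- offset + w
      grads$branches[[i]] <- backwardBranch(params$branches[[i]],
                                            config$submodels[[i]],
                                            fwd$branches[[i]]$cache, dOut)
    }
  } else {
    M <- length(config$modalities)
    Pbar <- pmax(fwd$P, 1e-12)
    dPm <- -(Yhot / Pbar) / (n * M)            # same for every head
    grads$heads <- vector("list", M)
    for (i in seq_len(M)) {
      Pm <- fwd$Ps[[i]]
      inner <- rowSums(Pm * dPm)
      dZ <- Pm * (dPm - inner)                 # softmax Jacobian product
      grads$heads[[i]] <- list(W = crossprod(fwd$branches[[i]]$out, dZ),
                               b = colSums(dZ))
      dOut <- tcrossprod(dZ, params$heads[[i]]$W)
      grads$branches[[i]] <- backwardBranch(params$branches[[i]],
                                            config$submodels[[i]],
                                            fwd$branches[[i]]$cache, dOut)
    }
  }
  grads
}

#' Train the fused model
#'
#' Minimizes categorical cross-entropy over one-hot event targets with
#' Adam.  Rows outside the held-out fold (if `folds`/`holdout` are given)
#' form the training set.  When the configuration enables early stopping
#' (`patience > 0` and `validationFraction > 0`) a random slice of the
#' training rows is reserved to monitor validation accuracy, and the
#' parameters of the best epoch are restored.  Training is deterministic given the
#' configuration seed.  A non-finite training loss aborts with a
#' diagnostic.
#'
#' @param model a `trainedModel` from [buildModel()], or a [modelConfig()].
#' @param Xs named list of per-modality input matrices (rows aligned).
#' @param y integer event labels in `[0, nEvents)`.
#' @param folds optional integer fold assignment per row.
#' @param holdout optional fold index to exclude from training.
#' @param verbose print per-epoch losses.
#' @return the model with fitted parameters and a `history` data.frame
#'   (epoch, trainLoss, valLoss, valAccuracy).
#' @export
trainModel <- function(model, Xs, y, folds = NULL, holdout = NULL,
                       verbose = FALSE) {
  if (inherits(model, "modelConfig")) model <- buildModel(model)
  config <- model$config
  stopifnot(length(Xs) == length(config$modalities))
  keep <- if (!is.null(holdout) && !is.null(folds)) folds != holdout
          else rep(TRUE, length(y))
  Xs <- lapply(Xs, function(X) X[keep, , drop = FALSE])
  y <- y[keep]
  n <- length(y)
  if (!n) stop("no training rows", call. = FALSE)
  if (config$epochs == 0L) return(model)
  E <- config$nEvents

  fitted <- withSeed(config$seed + 1L, {
    params <- model$params
    useVal <- config$patience > 0L && config$validationFraction > 0 &&
      n >= 20L
    if (useVal) {
      nVal <- max(1L, floor(n * config$validationFraction))
      vIdx <- sample.int(n, nVal)
      XsVal <- lapply(Xs, function(X) X[vIdx, , drop = FALSE])
      yVal <- y[vIdx]
      tIdx <- setdiff(seq_len(n), vIdx)
    } else {
      tIdx <- seq_len(n)
    }
    XsTr <- lapply(Xs, function(X) X[tIdx, , drop = FALSE])
    yTr <- y[tIdx]
    nTr <- length(yTr)

    if (config$fusion == "concat") {
      # compiled fast path (identical architecture and update rule;
      # randomness still flows from R's RNG)
      res <- .cnnTrainConcat(
        unname(XsTr), as.integer(yTr), unname(config$submodels), params,
        if (useVal) unname(XsVal) else list(),
        if (useVal) as.integer(yVal) else integer(),
        E, config$epochs, config$batchSize, config$learningRate,
        config$patience, useVal)
      h <- res$history
      fitted <- list(params = res$params,
                     history = data.frame(epoch = as.integer(h[, 1]),
                                          trainLoss = h[, 2],
                                          valLoss = h[, 3],
                                          valAccuracy = h[, 4]))
    } else {
      fitted <- trainLoopR(params, config, XsTr, yTr, E,
                           if (useVal) XsVal else NULL,
                           if (useVal) yVal else NULL, useVal, verbose)
    }
    fitted
  })
  model$params <- fitted$params
  model$history <- fitted$history
  model$trained <- TRUE
  model
}

# reference training loop in plain R (used for average fusion; also the
# semantics the compiled concat path mirrors)
trainLoopR <- function(params, config, XsTr, yTr, E, XsVal, yVal, useVal,
                       verbose) {
    nTr <- length(yTr)
    Yhot <- matrix(0, nTr, E)
    Yhot[cbind(seq_len(nTr), yTr + 1L)] <- 1

    state <- NULL
    tStep <- 0L
    best <- list(acc = -Inf, params = NULL, epoch = 0L)
    hist <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nTr)
      batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
      lossSum <- 0
      for (b in batches) {
        Xb <- lapply(XsTr, function(X) X[b, , drop = FALSE])
        Yb <- Yhot[b, , drop = FALSE]
        fwd <- modelForward(params, config, Xb, training = TRUE)
        loss <- -mean(log(pmax(rowSums(fwd$P * Yb), 1e-12)))
        if (!is.finite(loss))
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d; lower the learning rate",
            epoch), call. = FALSE)
        lossSum <- lossSum + loss * length(b)
        grads <- modelBackward(params, config, fwd, Yb)
        for (i in seq_along(params$branches))
          params$branches[[i]] <- updateRunningStats(
            params$branches[[i]], config$submodels[[i]],
            fwd$branches[[i]]$cache)
        if (is.null(state)) state <- adamInit(grads)
        tStep <- tStep + 1L
        upd <- adamUpdate(params, grads, state, config$learningRate, tStep)
        params <- upd$p; state <- upd$s
      }
      trainLoss <- lossSum / nTr
      valLoss <- NA_real_; valAcc <- NA_real_
      if (useVal) {
        Pv <- modelForward(params, config, XsVal, training = FALSE)$P
        valLoss <- -mean(log(pmax(Pv[cbind(seq_along(yVal), yVal + 1L)], 1e-12)))
        valAcc <- mean(max.col(Pv) - 1L == yVal)
        if (valAcc > best$acc + 1e-9) {      # stop on validation accuracy
          best <- list(acc = valAcc, params = params, epoch = epoch)
        } else if (epoch - best$epoch >= config$patience) {
          hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                      valLoss = valLoss, valAccuracy = valAcc)
          break
        }
      }
      hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                  valLoss = valLoss, valAccuracy = valAcc)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %s", epoch, trainLoss,
                        ifelse(is.na(valLoss), "-", sprintf("%.4f", valLoss))))
    }
    history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
    if (useVal && !is.null(best$params)) params <- best$params
    list(params = params, history = history)
}

#' Class-probability predictions
#'
#' Deterministic inference: dropout off, batch normalization on running
#' statistics.  An empty batch returns a (0, E) matrix.
#'
#' With `symmetrize = TRUE` each input row is assumed to be the
#' concatenation of two drugs' similarity rows (as built by
#' [pairVectors()]); the probabilities of the (a, b) and (b, a)
#' orientations are averaged, so predictions respect the symmetry of the
#' unordered drug pair.
#'
#' @param model a fitted `trainedModel`.
#' @param Xs named list of per-modality input matrices.
#' @param symmetrize average the two pair orientations (default FALSE).
#' @return numeric (n, E) matrix of event probabilities; rows sum to 1.
#' @export
predictProba <- function(model, Xs, symmetrize = FALSE) {
  if (symmetrize) {
    P1 <- predictProba(model, Xs, symmetrize = FALSE)
    P2 <- predictProba(model, lapply(Xs, swapPairHalves),
                       symmetrize = FALSE)
    return((P1 + P2) / 2)
  }
  config <- model$config
  if (length(Xs) != length(config$modalities))
    stop(sprintf("expected %d input matrices, got %d",
                 length(config$modalities), length(Xs)), call. = FALSE)
  for (i in seq_along(Xs)) {
    want <- config$submodels[[i]]$inputLength
    if (ncol(Xs[[i]]) != want)
      stop(sprintf("modality '%s' expects input length %d, got %d",
                   config$modalities[i], want, ncol(Xs[[i]])), call. = FALSE)
  }
  if (nrow(Xs[[1]]) == 0L) return(matrix(0, 0L, config$nEvents))
  modelForward(model$params, config, Xs, training = FALSE)$P
}

#' Predicted event labels (argmax of class probabilities)
#' @inheritParams predictProba
#' @return integer labels in `[0, nEvents)`.
#' @export
predictEvents <- function(model, Xs, symmetrize = FALSE) {
  max.col(predictProba(model, Xs, symmetrize = symmetrize),
          ties.method = "first") - 1L
}

# swap the two drug halves of a pair-vector matrix
swapPairHalves <- function(X) {
  N <- ncol(X) %/% 2L
  cbind(X[, (N + 1L):(2L * N), drop = FALSE], X[, 1:N, drop = FALSE])
}

#' Count trainable parameters
#'
#' Counts weights, biases and batch-norm scale/shift; running statistics
#' are buffers, not parameters.
#'
#' @param model a `trainedModel`.
#' @return integer parameter count.
#' @export
countParameters <- function(model) {
  count <- function(p) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      keys <- setdiff(as.list(keys), list("runMean", "runVar"))
      sum(vapply(keys, function(k) count(p[[k]]), 0))
    } else length(p)
  }
  as.integer(count(model$params))
}

#' @export
print.trainedModel <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Multimodal conv classifier: %d modalities (%s), %d events, fusion=%s\n",
              length(cfg$modalities), paste(cfg$modalities, collapse = ", "),
              cfg$nEvents, cfg$fusion))
  cat(sprintf("  %s, %d parameters\n",
              if (x$trained) "trained" else "untrained", countParameters(x)))
  invisible(x)
}

#' Save / load a trained model
#'
#' The parameters are serialized with R's native serialization next to a
#' YAML sidecar describing the configuration; the training history is
#' written as tab-separated text.
#'
#' @param model a `trainedModel`.
#' @param path basename; writes `<path>.bin`, `<path>.yaml`,
#'   `<path>.history.tsv`.
#' @export
saveModel <- function(model, path) {
  saveRDS(model[c("params", "trained")], paste0(path, ".bin"))
  cfg <- model$config
  cfg$submodels <- lapply(cfg$submodels, unclass)
  yaml::write_yaml(unclass(cfg), paste0(path, ".yaml"))
  if (is.data.frame(model$history) && nrow(model$history))
    utils::write.table(model$history, paste0(path, ".history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  cfg <- yaml::read_yaml(paste0(path, ".yaml"))
  cfg$submodels <- lapply(cfg$submodels, function(s) {
    s$denseSizes <- as.integer(unlist(s$denseSizes))
    structure(s, class = "submodelSpec")
  })
  cfg$modalities <- unlist(cfg$modalities)
  config <- structure(cfg, class = "modelConfig")
  bits <- readRDS(paste0(path, ".bin"))
  hp <- paste0(path, ".history.tsv")
  hist <- if (file.exists(hp))
    utils::read.table(hp, header = TRUE, sep = "\t") else data.frame()
  structure(list(config = config, params = bits$params, history = hist,
                 trained = bits$trained), class = "trainedModel")
}
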