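#' Multi-class accuracy
#'
#' Fraction of records whose predicted event matches the true event.
#'
#' @param yTrue,yPred integer label vectors of equal length.
#' @return value in \[0, 1\].
#' @export
accuracyScore <- function(yTrue, yPred) {
  if (!length(yTrue)) stop("empty input", call. = FALSE)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length", call. = FALSE)
  mean(yTrue == yPred)
}

#' Multi-class F1 score
#'
#' Per-class F1 from one-vs-rest confusion counts.  Macro averaging
#' (default) gives each class equal weight; classes absent from both the
#' truth and the prediction contribute 0 to the macro mean (reported via a
#' message).  Micro averaging pools the confusion counts, which for
#' single-label classification equals accuracy.
#'
#' @param yTrue,yPred integer label vectors.
#' @param labels class universe; defaults to labels observed in either
#'   vector.
#' @param averaging "macro" (default) or "micro".
#' @return value in \[0, 1\].
#' @export
f1Multiclass <- function(yTrue, yPred, labels = NULL,
                         averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  if (!length(yTrue)) stop("empty input", call. = FALSE)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length", call. = FALSE)
  if (is.null(labels)) labels <- sort(unique(c(yTrue, yPred)))
  tp <- fp <- fn <- numeric(length(labels))
  for (i in seq_along(labels)) {
    cl <- labels[i]
    tp[i] <- sum(yTrue == cl & yPred == cl)
    fp[i] <- sum(yTrue != cl & yPred == cl)
    fn[i] <- sum(yTrue == cl & yPred != cl)
  }
  if (averaging == "micro") {
    denom <- 2 * sum(tp) + sum(fp) + sum(fn)
    return(if (denom == 0) 0 else 2 * sum(tp) / denom)
  }
  absent <- tp + fp + fn == 0
  if (any(absent))
    message(sprintf("%d class(es) absent from truth and prediction scored F1 = 0",
                    sum(absent)))
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom == 0, 0, 2 * tp / denom)
  mean(f1)
}

# micro flattening: (n, E) one-hot truth + score matrix -> long vectors
flattenMicro <- function(yTrueOnehot, scores) {
  if (!all(dim(yTrueOnehot) == dim(scores)))
    stop("truth and score matrices must share dimensions", call. = FALSE)
  lab <- as.vector(yTrueOnehot)
  if (all(lab == 1) || all(lab == 0))
    stop("flattened truth has a single class; AUC/AUPR undefined", call. = FALSE)
  list(lab = lab, score = as.vector(scores))
}

#' Micro-averaged area under the ROC curve
#'
#' The (n, E) one-hot truth and score matrices are flattened to n*E
#' binary decisions and the ROC area is computed in the rank
#' (Mann-Whitney) form, with the mid-rank convention for tied scores —
#' identical to the step-integration area over all thresholds.
#'
#' @param yTrueOnehot (n, E) 0/1 matrix.
#' @param scores (n, E) numeric score matrix.
#' @return value in \[0, 1\].
#' @export
aucMicro <- function(yTrueOnehot, scores) {
  fl <- flattenMicro(yTrueOnehot, scores)
  pos <- fl$lab == 1
  r <- rank(fl$score)                       # mid-ranks on ties
  nPos <- sum(pos); nNeg <- sum(!pos)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Micro-averaged area under the precision-recall curve
#'
#' Average-precision form: scores are swept from the highest down, and
#' precision is accumulated at every threshold where recall increases
#' (step integration, no trapezoid interpolation).  Tied scores are
#' handled as a single threshold.
#'
#' @inheritParams aucMicro
#' @return value in \[0, 1\].
#' @export
auprMicro <- function(yTrueOnehot, scores) {
  fl <- flattenMicro(yTrueOnehot, scores)
  averagePrecision(fl$lab, fl$score)
}

# average precision for a binary problem, tie-aware
averagePrecision <- function(lab, score) {
  ord <- order(score, decreasing = TRUE)
  lab <- lab[ord]; score <- score[ord]
  nPos <- sum(lab == 1)
  # group tied scores: all members of a tie group enter at one threshold
  grp <- cumsum(!duplicated(score))
  tpGrp <- tapply(lab == 1, grp, sum)
  nGrp <- tapply(lab, grp, length)
  cumTp <- cumsum(tpGrp)
  cumN <- cumsum(nGrp)
  prec <- cumTp / cumN
  dRecall <- tpGrp / nPos
  sum(prec * dRecall)
}

#' Precision among the top-k ranked predictions
#'
#' Records are ranked by their maximum class score, descending, ties
#' broken by record index (determinism); the value is the fraction of the
#' top k whose argmax class equals the true event.  At k = n this equals
#' accuracy.
#'
#' @param yTrue integer labels.
#' @param scores (n, E) score matrix.
#' @param k ranking depth (1 <= k <= n).
#' @return value in \[0, 1\].
#' @export
precisionAtK <- function(yTrue, scores, k) {
  n <- length(yTrue)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds n = %d", k, n), call. = FALSE)
  top <- apply(scores, 1L, max)
  pred <- max.col(scores, ties.method = "first") - 1L
  ord <- order(-top, seq_len(n))            # ties by record index
  sel <- ord[seq_len(k)]
  mean(yTrue[sel] == pred[sel])
}

#' Paired t-test between two per-fold metric vectors
#'
#' Two-sided paired t-test via [stats::t.test()], with the degenerate
#' zero-variance cases resolved before delegation: identical vectors give
#' t = 0, p = 1; a constant non-zero difference gives p -> 0 with a
#' warning (the test statistic is unbounded).
#'
#' @param a,b equal-length numeric vectors (>= 2 paired values).
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `p`, `significant`, `meanDiff`.
#' @export
pairedTTest <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired samples must have equal length",
                                   call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  stderr <- stats::sd(d) / sqrt(length(d))
  # same degeneracy rule as stats::t.test ("data are essentially constant")
  if (stderr < 10 * .Machine$double.eps * max(abs(mean(d)), 1e-100)) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, significant = FALSE, meanDiff = 0))
    warning("zero variance with non-zero mean difference; p -> 0",
            call. = FALSE)
    return(list(t = sign(mean(d)) * Inf, p = 0, significant = TRUE,
                meanDiff = mean(d)))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha, meanDiff = mean(d))
}

#' One-way ANOVA across per-fold metric groups
#'
#' Classical equal-variance one-way F test via
#' [stats::oneway.test()] (`var.equal = TRUE`).  If every value in every
#' group is identical the F statistic is undefined (0/0) and 0 is
#' returned with a warning.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `p`, `significant`, `dfBetween`, `dfWithin`.
#' @export
anovaOneway <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 values",
                                      call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::sd(values) == 0) {
    warning("all values identical across groups; F undefined, returning 0",
            call. = FALSE)
    return(list(F = 0, p = 1, significant = FALSE,
                dfBetween = length(groups) - 1L,
                dfWithin = length(values) - length(groups)))
  }
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = ht$p.value,
       significant = is.finite(ht$p.value) && ht$p.value < alpha,
       dfBetween = unname(ht$parameter[1]), dfWithin = unname(ht$parameter[2]))
}

# one-hot encode integer labels over E classes
oneHot <- function(y, E) {
  Y <- matrix(0, length(y), E)
  if (length(y)) Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}
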