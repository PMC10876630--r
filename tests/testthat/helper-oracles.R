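# Independent brute-force oracles used to pin down the vectorized
# implementations.  These deliberately use naive set arithmetic and
# exhaustive sweeps, never the code paths they check.

oracleJaccard <- function(bits) {
  n <- nrow(bits)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- which(bits[i, ] == 1)
    b <- which(bits[j, ] == 1)
    uni <- length(union(a, b))
    out[i, j] <- if (uni == 0) 0 else length(intersect(a, b)) / uni
  }
  out
}

oracleCosine <- function(bits) {
  n <- nrow(bits)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    na <- sqrt(sum(bits[i, ]^2)); nb <- sqrt(sum(bits[j, ]^2))
    out[i, j] <- if (na == 0 || nb == 0) 0 else sum(bits[i, ] * bits[j, ]) / (na * nb)
  }
  out
}

# ROC area by exhaustive threshold sweep (trapezoid over the ROC steps,
# which on ties matches the mid-rank convention)
oracleAucSweep <- function(lab, score) {
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(score[lab == 1] >= t), 0), 1)
  fpr <- c(0, vapply(th, function(t) mean(score[lab == 0] >= t), 0), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# precision-recall area in average-precision form by exhaustive sweep
oracleAprSweep <- function(lab, score) {
  th <- sort(unique(score), decreasing = TRUE)
  nPos <- sum(lab == 1)
  prevTp <- 0
  ap <- 0
  for (t in th) {
    sel <- score >= t
    tp <- sum(lab[sel] == 1)
    prec <- tp / sum(sel)
    ap <- ap + prec * (tp - prevTp) / nPos
    prevTp <- tp
  }
  ap
}

oracleF1Macro <- function(yTrue, yPred, labels) {
  f1 <- vapply(labels, function(cl) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1)
}

oraclePrecisionAtK <- function(yTrue, scores, k) {
  top <- apply(scores, 1, max)
  pred <- apply(scores, 1, which.max) - 1L
  ord <- order(-top, seq_along(top))
  sel <- ord[1:k]
  mean(yTrue[sel] == pred[sel])
}

oneHotLocal <- function(y, E) {
  Y <- matrix(0, length(y), E)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

randomBitMatrix <- function(n, v, p = 0.3) {
  matrix(rbinom(n * v, 1, p), n, v)
}

tinyFeatureTable <- function() {
  drugFeatureTable(c("d1", "d2", "d3"), list(
    target = list(d1 = c("a", "b"), d2 = c("b", "c"), d3 = character()),
    enzyme = list(d1 = "e1", d2 = character(), d3 = c("e1", "e2"))))
}
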