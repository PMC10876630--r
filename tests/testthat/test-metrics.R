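test_that("accuracy is the exact-match fraction", {
  expect_equal(accuracyScore(c(0, 1, 1), c(0, 1, 0)), 2 / 3)
  expect_equal(accuracyScore(0:4, 0:4), 1)
  expect_error(accuracyScore(integer(), integer()), "empty")
  set.seed(21)
  yt <- sample(0:4, 200, replace = TRUE)
  yp <- sample(0:4, 200, replace = TRUE)
  expect_equal(accuracyScore(yt, yp), sum(yt == yp) / 200)
})

test_that("multi-class F1 matches the confusion-table oracle", {
  expect_equal(f1Multiclass(0:3, 0:3), 1)
  expect_equal(f1Multiclass(rep(2L, 5), rep(2L, 5)), 1)
  set.seed(22)
  for (rep in 1:20) {
    yt <- sample(0:2, 30, replace = TRUE)
    yp <- sample(0:2, 30, replace = TRUE)
    expect_equal(suppressMessages(f1Multiclass(yt, yp, labels = 0:2)),
                 oracleF1Macro(yt, yp, 0:2), tolerance = 1e-12)
    # micro F1 with a single label per record equals accuracy
    expect_equal(f1Multiclass(yt, yp, labels = 0:2, averaging = "micro"),
                 mean(yt == yp), tolerance = 1e-12)
  }
  # class absent from truth and prediction scores 0 under macro
  expect_message(f1 <- f1Multiclass(c(0L, 1L), c(0L, 1L), labels = 0:2),
                 "absent")
  expect_equal(f1, 2 / 3)
})

test_that("micro AUC / AUPR have the right anchors and degenerate errors", {
  y <- oneHotLocal(c(0L, 1L, 2L, 1L), 3)
  expect_equal(aucMicro(y, y), 1)
  expect_equal(auprMicro(y, y), 1)
  expect_error(aucMicro(matrix(1, 2, 1), matrix(0.5, 2, 1)), "single class")
  # uninformative scores: AUPR ~ positive prevalence 1/E
  set.seed(23)
  E <- 4L; n <- 4000L
  yt <- oneHotLocal(sample(0:(E - 1L), n, replace = TRUE), E)
  sc <- matrix(runif(n * E), n, E)
  expect_lt(abs(auprMicro(yt, sc) - 1 / E), 0.02)
  expect_lt(abs(aucMicro(yt, sc) - 0.5), 0.02)
})

test_that("micro AUC / AUPR equal exhaustive threshold sweeps on random instances", {
  set.seed(24)
  for (rep in 1:40) {
    n <- sample(4:50, 1); E <- sample(2:5, 1)
    yt <- oneHotLocal(sample(0:(E - 1L), n, replace = TRUE), E)
    sc <- matrix(round(runif(n * E), sample(1:3, 1)), n, E)  # forces ties
    lab <- as.vector(yt); s <- as.vector(sc)
    expect_equal(aucMicro(yt, sc), oracleAucSweep(lab, s), tolerance = 1e-9)
    expect_equal(auprMicro(yt, sc), oracleAprSweep(lab, s), tolerance = 1e-9)
  }
})

test_that("micro AUC agrees with an independent ROC implementation", {
  set.seed(27)
  n <- 60L; E <- 3L
  yt <- sample(0:(E - 1L), n, replace = TRUE)
  sc <- matrix(runif(n * E), n, E)
  Y <- oneHotLocal(yt, E)
  ref <- as.numeric(pROC::auc(as.vector(Y), as.vector(sc), quiet = TRUE,
                              direction = "<", levels = c(0, 1)))
  expect_equal(aucMicro(Y, sc), ref, tolerance = 1e-12)
})

test_that("precision@k ranks by top score with index tie-break and hits accuracy at k = n", {
  yt <- c(0L, 1L, 0L)
  sc <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4))
  expect_equal(precisionAtK(yt, sc, 2), 1)      # two most confident correct
  expect_equal(precisionAtK(yt, sc, 3), 1)
  expect_error(precisionAtK(yt, sc, 0), "positive")
  expect_error(precisionAtK(yt, sc, 4), "exceeds")
  set.seed(25)
  for (rep in 1:20) {
    n <- sample(5:40, 1); E <- sample(2:5, 1)
    yt <- sample(0:(E - 1L), n, replace = TRUE)
    sc <- matrix(round(runif(n * E), 2), n, E)
    k <- sample(n, 1)
    expect_equal(precisionAtK(yt, sc, k), oraclePrecisionAtK(yt, sc, k))
    expect_equal(precisionAtK(yt, sc, n), accuracyScore(yt, max.col(sc, "first") - 1L))
  }
})

test_that("metrics are invariant to simultaneous record permutation", {
  set.seed(26)
  n <- 40; E <- 4L
  yt <- sample(0:(E - 1L), n, replace = TRUE)
  sc <- matrix(runif(n * E), n, E)
  yp <- max.col(sc) - 1L
  perm <- sample(n)
  expect_equal(accuracyScore(yt, yp), accuracyScore(yt[perm], yp[perm]))
  expect_equal(f1Multiclass(yt, yp, labels = 0:(E - 1L)),
               f1Multiclass(yt[perm], yp[perm], labels = 0:(E - 1L)))
  expect_equal(aucMicro(oneHotLocal(yt, E), sc),
               aucMicro(oneHotLocal(yt[perm], E), sc[perm, ]))
  expect_equal(auprMicro(oneHotLocal(yt, E), sc),
               auprMicro(oneHotLocal(yt[perm], E), sc[perm, ]))
})

test_that("paired t-test matches the closed form and honours degenerate contracts", {
  # textbook 5-pair sample against the closed form t = mean(d)/(sd(d)/sqrt(n))
  a <- c(0.90, 0.88, 0.91, 0.87, 0.89)
  b <- c(0.85, 0.86, 0.88, 0.84, 0.88)
  d <- a - b
  tt <- pairedTTest(a, b)
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(-abs(tt$t), df = 4), tolerance = 1e-12)

  ident <- pairedTTest(a, a)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_false(ident$significant)

  expect_warning(deg <- pairedTTest(b + 1, b), "zero variance")
  expect_equal(deg$p, 0)
  expect_true(deg$significant)

  expect_error(pairedTTest(1, 1), "at least 2")
})

test_that("one-way ANOVA matches the sum-of-squares formula", {
  g <- list(c(1, 2, 3, 4), c(2, 3, 4, 5), c(5, 6, 7, 9))
  av <- anovaOneway(g)
  allv <- unlist(g)
  grand <- mean(allv)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2, 0))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  Fref <- (ssb / 2) / (ssw / (length(allv) - 3))
  expect_equal(av$F, Fref, tolerance = 1e-12)
  expect_equal(av$p, pf(Fref, 2, length(allv) - 3, lower.tail = FALSE),
               tolerance = 1e-12)

  # equal means, unequal spread -> F exactly per formula (small here)
  g2 <- list(c(-1, 0, 1), c(-3, 0, 3))
  av2 <- anovaOneway(g2)
  expect_equal(av2$F, 0, tolerance = 1e-12)

  expect_warning(avDeg <- anovaOneway(list(c(1, 1), c(1, 1))), "identical")
  expect_equal(avDeg$F, 0)
  expect_error(anovaOneway(list(1:3)), "2 groups")
})
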