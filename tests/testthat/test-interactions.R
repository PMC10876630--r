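makeRecords <- function(a, b, e) {
  r <- data.frame(drugA = a, drugB = b, event = as.integer(e),
                  stringsAsFactors = FALSE)
  attr(r, "nEvents") <- max(e) + 1L
  r
}

test_that("interaction loading validates drugs, labels and malformed rows", {
  tab <- tinyFeatureTable()
  f <- tempfile(fileext = ".tsv")
  writeLines(c("drug_a\tdrug_b\tevent", "d1\td2\t0", "d2\td3\t1", "d1\td3\t2"), f)
  rec <- loadInteractions(f, tab)
  expect_equal(nrow(rec), 3L)
  expect_identical(attr(rec, "nEvents"), 3L)

  # unknown drug dropped with a message, not an error
  writeLines(c("drug_a\tdrug_b\tevent", "d1\td2\t0", "dX\td3\t1"), f)
  expect_message(rec2 <- loadInteractions(f, tab), "unknown")
  expect_equal(nrow(rec2), 1L)

  writeLines(c("drug_a\tdrug_b\tevent", "d1\td2\tfoo"), f)
  expect_error(loadInteractions(f, tab), "line 2")

  writeLines(c("drug_a\tdrug_b\tevent", "d1\td2\t7"), f)
  expect_error(loadInteractions(f, tab, nEvents = 3), "outside")
})

test_that("deduplication keeps one record per unordered pair, first wins", {
  rec <- makeRecords(c("A", "B", "A", "C"), c("B", "A", "B", "A"),
                     c(1, 1, 1, 0))
  out <- deduplicatePairs(rec)
  expect_equal(nrow(out), 2L)
  expect_identical(out$drugA, c("A", "C"))

  # conflicting labels: first kept, conflict reported
  rec2 <- makeRecords(c("A", "B"), c("B", "A"), c(1, 2))
  expect_message(out2 <- deduplicatePairs(rec2), "conflicting")
  expect_equal(out2$event, 1L)
})

test_that("dedup count matches a hash-set oracle on random lists and is idempotent", {
  set.seed(11)
  drugs <- sprintf("d%02d", 1:15)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    a <- sample(drugs, n, replace = TRUE)
    b <- sample(drugs, n, replace = TRUE)
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    rec <- makeRecords(a, b, sample(0:3, length(a), replace = TRUE))
    out <- suppressMessages(deduplicatePairs(rec))
    oracle <- length(unique(paste(pmin(a, b), pmax(a, b))))
    expect_equal(nrow(out), oracle)
    expect_identical(suppressMessages(deduplicatePairs(out)), out)
  }
})

test_that("pair vectors concatenate the two similarity rows", {
  v <- matrix(seq(0.01, 0.16, length.out = 16), 4, 4)
  v <- (v + t(v)) / 2; diag(v) <- 1
  drugs <- c("d0", "d1", "d2", "d3")
  dimnames(v) <- list(drugs, drugs)
  sim <- new("SimilarityMatrix", drugs = drugs, modality = "m",
             metric = "jaccard", values = v)
  rec <- makeRecords("d0", "d2", 0)
  pv <- pairVectors(rec, sim)
  expect_equal(dim(pv), c(1L, 8L))
  expect_equal(unname(pv[1, ]), unname(c(v["d0", ], v["d2", ])))

  # identity similarity -> one-hot at positions of the two drugs
  id <- diag(4); dimnames(id) <- list(drugs, drugs)
  simId <- new("SimilarityMatrix", drugs = drugs, modality = "m",
               metric = "jaccard", values = id)
  rec01 <- makeRecords("d0", "d1", 0)
  pvId <- pairVectors(rec01, simId)
  expect_equal(unname(which(pvId[1, ] == 1)), c(1L, 4L + 2L))

  # augmentation doubles rows with mirrored orientation
  aug <- pairVectors(rec, sim, augment = TRUE)
  expect_equal(nrow(aug), 2L)
  expect_equal(unname(aug[2, ]), unname(c(v["d2", ], v["d0", ])))

  expect_error(pairVectors(makeRecords("d0", "zz", 0), sim), "not indexed")
})

test_that("pair-vector construction commutes with drug permutation", {
  set.seed(12)
  bits <- randomBitMatrix(10, 12)
  drugs <- sprintf("d%02d", 1:10)
  sim <- similarityMatrix(new("BitMatrix", drugs = drugs, modality = "m",
                              values = bits))
  perm <- sample(10)
  simP <- similarityMatrix(new("BitMatrix", drugs = drugs[perm],
                               modality = "m", values = bits[perm, ]))
  rec <- makeRecords(c("d01", "d04"), c("d07", "d09"), c(0, 1))
  # column j of the permuted-matrix pair vectors is column perm[j] of the
  # original ones (per half)
  expect_equal(pairVectors(rec, simP),
               pairVectors(rec, sim)[, c(perm, 10L + perm)],
               ignore_attr = TRUE)
})

test_that("stratified folds partition records and balance classes within one", {
  # exact stratification: 2 classes, 50/50, k = 5 -> 10 + 10 per fold
  y <- rep(c(0L, 1L), each = 50)
  f <- stratifiedKFold(y, k = 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  for (i in 1:5) {
    expect_equal(sum(f == i & y == 0), 10)
    expect_equal(sum(f == i & y == 1), 10)
  }

  # rare class spread round-robin with a warning
  y2 <- c(rep(0L, 20), rep(1L, 3))
  expect_warning(f2 <- stratifiedKFold(y2, k = 5, seed = 3), "fewer than")
  expect_equal(max(table(f2[y2 == 1])), 1)

  expect_error(stratifiedKFold(1:3, k = 5, seed = 1), "exceeds")

  # proportional allocation within +-1 for random labels
  set.seed(13)
  for (rep in 1:5) {
    y3 <- sample(0:4, 200, replace = TRUE)
    f3 <- suppressWarnings(stratifiedKFold(y3, k = 5, seed = rep))
    expect_equal(sort(unique(f3)), 1:5)
    for (cl in unique(y3)) {
      counts <- tabulate(f3[y3 == cl], 5)
      expect_lte(max(counts) - min(counts), 1)
    }
  }

  # determinism per seed
  expect_identical(stratifiedKFold(y, 5, seed = 9),
                   stratifiedKFold(y, 5, seed = 9))
})

test_that("pairDataset assembles matrices aligned with deduplicated records", {
  set.seed(14)
  fx <- makeFixture("tiny", seed = 5)
  enc <- runEncode(fx$paths$features, fx$paths$interactions)
  ds <- pairDataset(enc$records, enc$similarities)
  expect_s4_class(ds, "PairDataset")
  expect_equal(nrow(interactionRecords(ds)), nrow(enc$records))
  for (m in names(pairMatrices(ds)))
    expect_equal(nrow(pairMatrices(ds)[[m]]), nrow(interactionRecords(ds)))
  ds <- assignFolds(ds, k = 3, seed = 2)
  f <- foldAssignment(ds)
  expect_equal(length(f), nrow(interactionRecords(ds)))
  expect_true(all(f %in% 1:3))
})
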