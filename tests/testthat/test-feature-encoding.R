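test_that("vocabulary is the sorted token union and errors on unknown modalities", {
  tab <- drugFeatureTable(c("d1", "d2"),
                          list(m = list(d1 = c("b", "a"), d2 = c("c", "b"))))
  v <- buildVocabulary(tab, "m")
  expect_identical(v@tokens, c("a", "b", "c"))
  expect_identical(vocabularySize(v), 3L)
  expect_error(buildVocabulary(tab, "nope"), "valid modalities")

  empty <- drugFeatureTable(c("d1", "d2"),
                            list(m = list(d1 = character(), d2 = character())))
  ve <- buildVocabulary(empty, "m")
  expect_identical(vocabularySize(ve), 0L)
  bm <- encodeBitMatrix(empty, ve)
  expect_identical(dim(bitValues(bm)), c(2L, 0L))
})

test_that("bit encoding reflects set membership; unknown tokens warn", {
  tab <- drugFeatureTable(c("d1", "d2"),
                          list(m = list(d1 = c("a", "b"), d2 = c("b", "c"))))
  bm <- encodeBitMatrix(tab, buildVocabulary(tab, "m"))
  expect_equal(unname(bitValues(bm)), rbind(c(1, 1, 0), c(0, 1, 1)))

  # drug with empty set -> all-zero row
  tab2 <- drugFeatureTable(c("d1", "d2"),
                           list(m = list(d1 = c("a", "b"), d2 = character())))
  bm2 <- encodeBitMatrix(tab2, buildVocabulary(tab2, "m"))
  expect_equal(unname(bitValues(bm2)[2, ]), c(0, 0))

  # vocabulary from a narrower table: foreign tokens warn, never fail
  narrow <- new("FeatureVocabulary", modality = "m", tokens = c("a"))
  expect_warning(bm3 <- encodeBitMatrix(tab, narrow), "ignored")
  expect_equal(unname(bitValues(bm3)), rbind(1, 0))
})

test_that("row sums of a random encoding equal token-set cardinalities", {
  set.seed(42)
  drugs <- sprintf("d%02d", 1:50)
  pool <- sprintf("t%03d", 1:120)
  sets <- lapply(drugs, function(d) sample(pool, rpois(1, 8)))
  names(sets) <- drugs
  tab <- drugFeatureTable(drugs, list(m = sets))
  bm <- encodeBitMatrix(tab, buildVocabulary(tab, "m"))
  expect_equal(unname(rowSums(bitValues(bm))),
               unname(vapply(sets, function(s) length(unique(s)), 0)))
})

test_that("Jaccard and cosine match hand values on toy rows", {
  tab <- drugFeatureTable(c("d1", "d2", "d3", "d4"), list(
    m = list(d1 = c("a", "b"), d2 = c("b", "c"), d3 = c("a", "b"),
             d4 = "z")))
  sim <- similarityMatrix(encodeBitMatrix(tab, buildVocabulary(tab, "m")))
  v <- similarityValues(sim)
  expect_equal(v["d1", "d2"], 1 / 3)        # one shared of three tokens
  expect_equal(v["d1", "d3"], 1)            # identical sets
  expect_equal(v["d1", "d4"], 0)            # disjoint sets
  expect_equal(unname(diag(v)), rep(1, 4))
})

test_that("vectorized similarity equals brute-force set arithmetic", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:30, 1); v <- sample(5:20, 1)
    bits <- randomBitMatrix(n, v, runif(1, 0.1, 0.5))
    bm <- new("BitMatrix", drugs = sprintf("d%d", 1:n), modality = "m",
              values = bits)
    expect_equal(unname(similarityValues(similarityMatrix(bm, "jaccard"))),
                 oracleJaccard(bits), tolerance = 1e-12)
    expect_equal(unname(similarityValues(similarityMatrix(bm, "cosine"))),
                 oracleCosine(bits), tolerance = 1e-12)
  }
})

test_that("similarity output is symmetric, bounded, unit-diagonal, and empty-vs-empty is 0", {
  set.seed(8)
  for (metric in c("jaccard", "cosine")) {
    for (rep in 1:5) {
      bits <- randomBitMatrix(15, 10, 0.2)
      bits[1, ] <- 0; bits[2, ] <- 0           # plant two empty drugs
      bm <- new("BitMatrix", drugs = sprintf("d%d", 1:15), modality = "m",
                values = bits)
      v <- similarityValues(similarityMatrix(bm, metric))
      expect_equal(v, t(v))
      expect_true(all(v >= 0 & v <= 1 + 1e-12))
      nonEmpty <- rowSums(bits) > 0
      expect_equal(unname(diag(v)[nonEmpty]), rep(1, sum(nonEmpty)))
      expect_equal(v[1, 2], 0)                 # empty vs empty convention
    }
  }
})

test_that("permuting drug order permutes the similarity matrix consistently", {
  set.seed(9)
  bits <- randomBitMatrix(12, 8)
  drugs <- sprintf("d%02d", 1:12)
  bm <- new("BitMatrix", drugs = drugs, modality = "m", values = bits)
  v1 <- similarityValues(similarityMatrix(bm))
  perm <- sample(12)
  bm2 <- new("BitMatrix", drugs = drugs[perm], modality = "m",
             values = bits[perm, ])
  v2 <- similarityValues(similarityMatrix(bm2))
  expect_equal(unname(v2), unname(v1[perm, perm]))
})

test_that("drug-feature and bit-matrix files round-trip", {
  tab <- tinyFeatureTable()
  f <- tempfile(fileext = ".tsv")
  writeDrugFeatures(tab, f)
  tab2 <- readDrugFeatures(f)
  expect_identical(drugNames(tab2), drugNames(tab))
  expect_identical(modalityNames(tab2), modalityNames(tab))
  for (m in modalityNames(tab))
    expect_identical(lapply(tokenSets(tab2, m), sort),
                     lapply(tokenSets(tab, m), sort))

  bm <- encodeBitMatrix(tab, buildVocabulary(tab, "target"))
  g <- tempfile(fileext = ".tsv.gz")
  writeBitMatrix(bm, g)
  bm2 <- readBitMatrix(g, "target")
  expect_equal(bitValues(bm2), bitValues(bm))
})
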