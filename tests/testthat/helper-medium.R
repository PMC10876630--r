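# Desk-scale study fixture shared by the learnability and multimodality
# tests: 400 drugs, 20 events, 3 informative modalities, noise 0.1
# (the package's "medium" preset).  Built once per test session.

.mediumCache <- new.env(parent = emptyenv())

mediumStudy <- function() {
  if (is.null(.mediumCache$study)) {
    fx <- makeFixture("medium", seed = 20260901)
    enc <- runEncode(fx$paths$features, fx$paths$interactions)
    ds <- buildPairDataset(enc, k = 5, seed = 1)
    .mediumCache$study <- list(fixture = fx, dataset = ds,
                               oracle = fx$data$oracle)
  }
  .mediumCache$study
}

# reduced-epoch training settings used throughout the desk-scale tests
mediumModelConfig <- function(dataset, seed = 1L, epochs = 15L) {
  lens <- vapply(pairMatrices(dataset), ncol, 1L)
  modelConfig(lens, nEvents(dataset), epochs = epochs, seed = seed,
              patience = 6L)
}

# single stratified 80/20 holdout accuracy for a modality subset; short
# fixed-epoch training (the ordering of modality subsets, not peak
# accuracy, is what these runs measure)
holdoutAccuracy <- function(study, modalities, seed, epochs = 8L) {
  ds <- study$dataset
  rec <- interactionRecords(ds)
  split <- stratifiedKFold(rec$event, k = 5L, seed = seed + 1000L)
  test <- split == 1L
  Xs <- lapply(pairMatrices(ds)[modalities],
               function(X) X[!test, , drop = FALSE])
  cfg <- modelConfig(vapply(Xs, ncol, 1L), nEvents(ds), epochs = epochs,
                     seed = seed, patience = 0L)
  model <- trainModel(buildModel(cfg), Xs, rec$event[!test])
  XsTest <- lapply(pairMatrices(ds)[modalities],
                   function(X) X[test, , drop = FALSE])
  accuracyScore(rec$event[test],
                predictEvents(model, XsTest, symmetrize = TRUE))
}
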