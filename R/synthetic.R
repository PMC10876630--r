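#' Synthetic dataset configuration
#'
#' Emulates the statistical shape of the real drug-interaction data at
#' reduced scale: sparse per-modality token sets and a multi-class event
#' label planted on a subset of "informative" modalities.  For each event
#' class a prototype weight vector over the informative modalities'
#' vocabularies is drawn; a pair's true event is the argmax over classes
#' of the prototype score on the pair's combined token counts, and the
#' observed label flips to a uniformly drawn other class with the noise
#' probability.  Models trained on non-informative modalities alone can
#' therefore do no better than chance, while informative ones support
#' near-ceiling accuracy.
#'
#' @param nDrugs number of drugs.
#' @param vocabSizes named integer vector of per-modality vocabulary
#'   sizes.
#' @param tokenProb per-token presence probability (sparse sets).
#' @param nEvents number of event classes (>= 2).
#' @param nPairs number of distinct unordered interacting pairs to draw.
#' @param noise label-flip probability in \[0, 1).
#' @param informative modality names carrying the label signal
#'   (non-empty subset of `names(vocabSizes)`).
#' @param seed RNG seed; everything is reproducible from it.
#' @return a `synthConfig` list.
#' @export
synthConfig <- function(nDrugs = 120L,
                        vocabSizes = c(substructure = 24L, target = 30L,
                                       enzyme = 10L, pathway = 24L),
                        tokenProb = 0.25, nEvents = 8L, nPairs = 600L,
                        noise = 0.1,
                        informative = c("substructure", "target", "pathway"),
                        seed = 1L) {
  if (nEvents < 2L) stop("nEvents must be at least 2", call. = FALSE)
  if (noise < 0 || noise >= 1) stop("noise must lie in [0, 1)", call. = FALSE)
  if (!length(informative) || !all(informative %in% names(vocabSizes)))
    stop("informative must be a non-empty subset of the modalities",
         call. = FALSE)
  capacity <- nDrugs * (nDrugs - 1L) / 2
  if (nPairs > capacity)
    stop(sprintf("nPairs = %d exceeds the %d unordered pairs of %d drugs",
                 nPairs, capacity, nDrugs), call. = FALSE)
  structure(list(nDrugs = as.integer(nDrugs), vocabSizes = vocabSizes,
                 tokenProb = tokenProb, nEvents = as.integer(nEvents),
                 nPairs = as.integer(nPairs), noise = noise,
                 informative = informative, seed = as.integer(seed)),
            class = "synthConfig")
}

#' Generate a synthetic drug-feature table and interaction records
#'
#' @param config a [synthConfig()].
#' @return list with `featureTable` (a [DrugFeatureTable-class]),
#'   `records` (data.frame drugA/drugB/event with attribute `nEvents`),
#'   and `oracle`, a function `(drugA, drugB) -> true event` closing over
#'   the planted prototypes (the noise-free label, usable as a ceiling
#'   reference).
#' @export
generateSynthetic <- function(config) {
  stopifnot(inherits(config, "synthConfig"))
  withSeed(config$seed, {
    drugs <- sprintf("D%04d", seq_len(config$nDrugs))
    modalities <- names(config$vocabSizes)
    # per-modality binary token incidence
    bits <- lapply(modalities, function(m) {
      V <- config$vocabSizes[[m]]
      B <- matrix(stats::rbinom(config$nDrugs * V, 1L, config$tokenProb),
                  config$nDrugs, V)
      # every drug carries at least one token per modality
      empty <- rowSums(B) == 0L
      if (any(empty))
        B[cbind(which(empty), sample.int(V, sum(empty), replace = TRUE))] <- 1L
      dimnames(B) <- list(drugs, sprintf("%s_t%04d", substr(m, 1, 3),
                                         seq_len(V)))
      B
    })
    names(bits) <- modalities
    tokens <- lapply(modalities, function(m) {
      sets <- apply(bits[[m]], 1L, function(r) colnames(bits[[m]])[r == 1L],
                    simplify = FALSE)
      names(sets) <- drugs
      sets
    })
    names(tokens) <- modalities
    featureTable <- drugFeatureTable(drugs, tokens)

    # planted linear prototypes over the informative modalities
    infoBits <- do.call(cbind, bits[config$informative])
    prototypes <- matrix(stats::rnorm(config$nEvents * ncol(infoBits)),
                         config$nEvents, ncol(infoBits))
    scoreDrug <- infoBits %*% t(prototypes)      # per-drug class scores
    # standardize class scores across drugs so no class dominates the
    # argmax and the event histogram stays roughly uniform
    scoreDrug <- scale(scoreDrug)
    rownames(scoreDrug) <- drugs

    # sample distinct unordered pairs
    capacity <- config$nDrugs * (config$nDrugs - 1L) / 2
    pairIdx <- sample(capacity, config$nPairs)
    # invert linear index over the upper triangle (column-major)
    b <- ceiling((1 + sqrt(1 + 8 * pairIdx)) / 2)
    a <- pairIdx - (b - 1) * (b - 2) / 2

    # per-class offsets balance the event catalogue: iterative logit
    # adjustment until no class dominates the argmax over sampled pairs
    pairScores <- scoreDrug[a, , drop = FALSE] + scoreDrug[b, , drop = FALSE]
    offsets <- numeric(config$nEvents)
    target <- config$nPairs / config$nEvents
    for (it in seq_len(200L)) {
      wins <- max.col(pairScores + rep(offsets, each = config$nPairs),
                      ties.method = "first")
      cnt <- tabulate(wins, config$nEvents)
      if (max(cnt) / max(min(cnt), 1) < 1.5) break
      offsets <- offsets - 0.2 * log((cnt + 1) / (target + 1))
    }
    oracle <- function(drugA, drugB) {
      s <- scoreDrug[drugA, , drop = FALSE] + scoreDrug[drugB, , drop = FALSE]
      max.col(s + rep(offsets, each = nrow(s)), ties.method = "first") - 1L
    }
    trueEvent <- oracle(drugs[a], drugs[b])
    flip <- stats::runif(config$nPairs) < config$noise
    shift <- sample(config$nEvents - 1L, config$nPairs, replace = TRUE)
    event <- ifelse(flip, (trueEvent + shift) %% config$nEvents, trueEvent)
    records <- data.frame(drugA = drugs[a], drugB = drugs[b],
                          event = as.integer(event),
                          stringsAsFactors = FALSE)
    attr(records, "nEvents") <- config$nEvents
    list(featureTable = featureTable, records = records, oracle = oracle)
  })
}

#' Preset synthetic fixtures on disk
#'
#' Writes the canonical delimited files (drug features, interactions) for
#' one of three scales: `tiny` (20 drugs, 3 events; unit tests), `small`
#' (120 drugs, 8 events; integration), `medium` (400 drugs, 20 events, 3
#' informative modalities, noise 0.1; desk-scale training).
#'
#' @param scale "tiny", "small" or "medium".
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return list with the file `paths`, the generating `config`, and the
#'   in-memory `data` from [generateSynthetic()].
#' @export
makeFixture <- function(scale = c("tiny", "small", "medium"),
                        dir = tempfile("fixture"), seed = 1L) {
  scale <- match.arg(scale)
  config <- switch(scale,
    tiny = synthConfig(
      nDrugs = 20L,
      vocabSizes = c(substructure = 24L, target = 30L, enzyme = 10L,
                     pathway = 26L),
      tokenProb = 0.2, nEvents = 3L, nPairs = 60L, noise = 0,
      informative = c("substructure", "target", "pathway"), seed = seed),
    small = synthConfig(seed = seed),
    medium = synthConfig(
      nDrugs = 400L,
      vocabSizes = c(substructure = 2L, target = 3L, enzyme = 8L,
                     pathway = 2L),
      tokenProb = 0.5, nEvents = 20L, nPairs = 10000L, noise = 0.1,
      informative = c("substructure", "target", "pathway"), seed = seed))
  data <- generateSynthetic(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(features = file.path(dir, "drug_features.tsv"),
                interactions = file.path(dir, "interactions.tsv"))
  writeDrugFeatures(data$featureTable, paths$features)
  writeInteractions(data$records, paths$interactions)
  list(paths = paths, config = config, data = data)
}
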