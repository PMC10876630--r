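#' @import methods
NULL

MODALITIES <- c("substructure", "target", "enzyme", "pathway")

#' DrugFeatureTable: token-set drug descriptions per modality
#'
#' Maps every drug to a finite set of feature tokens in each of up to four
#' modalities (chemical substructure keys, targets, enzymes, pathways).
#' Tokens are opaque strings: the substructure modality arrives
#' pre-tokenized, no SMILES parsing is performed.
#'
#' @slot drugs character vector of unique drug identifiers (ordered).
#' @slot modalities character vector of modality names (ordered, non-empty).
#' @slot tokens named list (per modality) of named lists (per drug) of
#'   character vectors; token sets may be empty.
#' @export
setClass("DrugFeatureTable", representation(
  drugs = "character",
  modalities = "character",
  tokens = "list"
))

setValidity("DrugFeatureTable", function(object) {
  msg <- character()
  if (anyDuplicated(object@drugs))
    msg <- c(msg, "drug identifiers must be unique")
  if (length(object@modalities) == 0L)
    msg <- c(msg, "modality list must be non-empty")
  if (anyDuplicated(object@modalities))
    msg <- c(msg, "modality names must be unique")
  if (!setequal(names(object@tokens), object@modalities))
    msg <- c(msg, "token list must have one entry per modality")
  for (m in object@modalities) {
    if (!identical(names(object@tokens[[m]]), object@drugs))
      msg <- c(msg, sprintf("tokens[['%s']] must be named by drugs, in order", m))
  }
  if (length(msg)) msg else TRUE
})

#' FeatureVocabulary: the ordered token universe of one modality
#'
#' The vocabulary fixes the bit order of the binary encoding.  Ordering is
#' lexicographic so encodings are reproducible across runs and platforms.
#'
#' @slot modality modality name.
#' @slot tokens character vector, unique, sorted.
#' @export
setClass("FeatureVocabulary", representation(
  modality = "character",
  tokens = "character"
))

setValidity("FeatureVocabulary", function(object) {
  msg <- character()
  if (length(object@modality) != 1L)
    msg <- c(msg, "modality must be a single name")
  if (anyDuplicated(object@tokens))
    msg <- c(msg, "vocabulary tokens must be unique")
  if (is.unsorted(object@tokens, strictly = TRUE) && length(object@tokens) > 1L)
    msg <- c(msg, "vocabulary tokens must be sorted")
  if (length(msg)) msg else TRUE
})

#' BitMatrix: drugs x vocabulary binary indicator matrix
#'
#' Entry (i, j) is 1 iff vocabulary token j is present in drug i's token
#' set for the modality.
#'
#' @slot drugs character, row order (matches the source DrugFeatureTable).
#' @slot modality modality name.
#' @slot values numeric N x V matrix with entries in {0, 1}.
#' @export
setClass("BitMatrix", representation(
  drugs = "character",
  modality = "character",
  values = "matrix"
))

setValidity("BitMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@drugs))
    msg <- c(msg, "row count must equal number of drugs")
  if (length(object@values) && !all(object@values %in% c(0, 1)))
    msg <- c(msg, "entries must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: N x N drug-drug similarity for one modality
#'
#' Symmetric, entries in [0, 1], unit diagonal for drugs with at least one
#' token.  The Jaccard metric on bit vectors x, y is |x AND y| / |x OR y|;
#' two all-zero vectors get similarity 0 (0/0 is undefined; no shared
#' evidence means no similarity and keeps the range [0, 1]).
#'
#' @slot drugs character, row/column order.
#' @slot modality modality name.
#' @slot metric "jaccard" or "cosine".
#' @slot values numeric N x N matrix.
#' @export
setClass("SimilarityMatrix", representation(
  drugs = "character",
  modality = "character",
  metric = "character",
  values = "matrix"
))

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v) || nrow(v) != length(object@drugs))
    msg <- c(msg, "values must be square with one row per drug")
  if (!object@metric %in% c("jaccard", "cosine"))
    msg <- c(msg, "metric must be 'jaccard' or 'cosine'")
  if (length(v)) {
    if (max(abs(v - t(v))) > 1e-12)
      msg <- c(msg, "similarity matrix must be symmetric")
    if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
      msg <- c(msg, "entries must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' PairDataset: interaction records with per-modality pair vectors
#'
#' Holds the deduplicated (drug A, drug B, event) records, the number of
#' event classes E, one pair-vector matrix per modality (each row is the
#' concatenation of the two drugs' similarity rows, length 2N), and an
#' optional cross-validation fold assignment.
#'
#' @slot records data.frame with columns drugA, drugB (character) and
#'   event (integer in [0, E)).
#' @slot nEvents integer, number of event classes E.
#' @slot pairMatrices named list of numeric matrices, one per modality;
#'   row count equals record count.
#' @slot folds integer vector, fold index per record (length 0 until
#'   assigned).
#' @export
setClass("PairDataset", representation(
  records = "data.frame",
  nEvents = "integer",
  pairMatrices = "list",
  folds = "integer"
))

setValidity("PairDataset", function(object) {
  msg <- character()
  r <- object@records
  if (!all(c("drugA", "drugB", "event") %in% names(r)))
    msg <- c(msg, "records needs columns drugA, drugB, event")
  if (nrow(r)) {
    if (any(r$drugA == r$drugB))
      msg <- c(msg, "self-pairs are not allowed")
    if (any(r$event < 0L | r$event >= object@nEvents))
      msg <- c(msg, "event labels must lie in [0, nEvents)")
    # mirrored-orientation augmentation may add the (B, A) row of an
    # (A, B) record, so uniqueness is enforced on ordered pairs
    key <- paste(r$drugA, r$drugB, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "ordered pairs must be unique")
  }
  for (m in names(object@pairMatrices)) {
    if (nrow(object@pairMatrices[[m]]) != nrow(r))
      msg <- c(msg, sprintf("pair matrix '%s' row count must equal record count", m))
  }
  if (length(object@folds) && length(object@folds) != nrow(r))
    msg <- c(msg, "fold assignment length must equal record count")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DrugFeatureTable", function(object) {
  cat(sprintf("DrugFeatureTable: %d drugs, modalities: %s\n",
              length(object@drugs), paste(object@modalities, collapse = ", ")))
  for (m in object@modalities) {
    sizes <- lengths(object@tokens[[m]])
    cat(sprintf("  %-13s tokens/drug: min %d, median %s, max %d\n",
                m, min(sizes), format(stats::median(sizes)), max(sizes)))
  }
})

setMethod("show", "FeatureVocabulary", function(object) {
  cat(sprintf("FeatureVocabulary '%s': %d tokens\n",
              object@modality, length(object@tokens)))
})

setMethod("show", "BitMatrix", function(object) {
  cat(sprintf("BitMatrix '%s': %d drugs x %d tokens, density %.3f\n",
              object@modality, nrow(object@values), ncol(object@values),
              if (length(object@values)) mean(object@values) else 0))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix '%s' (%s): %d x %d\n",
              object@modality, object@metric,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "PairDataset", function(object) {
  cat(sprintf("PairDataset: %d records, %d event classes, modalities: %s\n",
              nrow(object@records), object@nEvents,
              paste(names(object@pairMatrices), collapse = ", ")))
  if (length(object@folds))
    cat(sprintf("  folds: %d\n", length(unique(object@folds))))
})
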