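#' Accessors for ddiFusion data classes
#'
#' `drugNames()` returns the ordered drug identifiers; `modalityNames()`
#' the modality names; `tokenSets()` the per-drug token sets of one
#' modality; `similarityValues()` / `bitValues()` the underlying numeric
#' matrices; `interactionRecords()` the record table; `nEvents()` the
#' number of event classes; `foldAssignment()` the cross-validation fold
#' index per record.
#'
#' @param x a ddiFusion object.
#' @param modality modality name.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("drugNames", function(x) standardGeneric("drugNames"))
#' @rdname accessors
#' @export
setGeneric("modalityNames", function(x) standardGeneric("modalityNames"))
#' @rdname accessors
#' @export
setGeneric("tokenSets", function(x, modality) standardGeneric("tokenSets"))
#' @rdname accessors
#' @export
setGeneric("bitValues", function(x) standardGeneric("bitValues"))
#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @rdname accessors
#' @export
setGeneric("interactionRecords", function(x) standardGeneric("interactionRecords"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("foldAssignment", function(x) standardGeneric("foldAssignment"))
#' @rdname accessors
#' @export
setGeneric("pairMatrices", function(x) standardGeneric("pairMatrices"))

#' @rdname accessors
#' @export
setMethod("drugNames", "DrugFeatureTable", function(x) x@drugs)
#' @rdname accessors
#' @export
setMethod("drugNames", "BitMatrix", function(x) x@drugs)
#' @rdname accessors
#' @export
setMethod("drugNames", "SimilarityMatrix", function(x) x@drugs)
#' @rdname accessors
#' @export
setMethod("modalityNames", "DrugFeatureTable", function(x) x@modalities)
#' @rdname accessors
#' @export
setMethod("tokenSets", "DrugFeatureTable", function(x, modality) {
  checkModality(x, modality)
  x@tokens[[modality]]
})
#' @rdname accessors
#' @export
setMethod("bitValues", "BitMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("interactionRecords", "PairDataset", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("nEvents", "PairDataset", function(x) x@nEvents)
#' @rdname accessors
#' @export
setMethod("foldAssignment", "PairDataset", function(x) x@folds)
#' @rdname accessors
#' @export
setMethod("pairMatrices", "PairDataset", function(x) x@pairMatrices)

checkModality <- function(table, modality) {
  if (!modality %in% table@modalities)
    stop(sprintf("unknown modality '%s'; valid modalities: %s",
                 modality, paste(table@modalities, collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

# canonical key for an unordered drug pair
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
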