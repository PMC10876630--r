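#' Load drug-pair interaction records
#'
#' Reads a delimited file with columns `drug_a`, `drug_b`, `event` (integer
#' class label).  Records naming drugs absent from the feature table are
#' dropped with a message reporting the count; malformed rows and
#' out-of-range event labels are errors naming the offending line.
#'
#' @param path interactions file path.
#' @param featureTable a [DrugFeatureTable-class] used to validate drugs.
#' @param nEvents number of event classes E; defaults to
#'   `max(event) + 1` observed in the file.
#' @param sep field separator.
#' @return data.frame with columns drugA, drugB, event and attribute
#'   `nEvents`.
#' @export
loadInteractions <- function(path, featureTable, nEvents = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("drug_a", "drug_b", "event")
  if (!all(need %in% names(df)))
    stop("interactions file needs columns drug_a, drug_b, event", call. = FALSE)
  ev <- suppressWarnings(as.integer(df$event))
  bad <- which(is.na(ev) | df$drug_a == "" | df$drug_b == "")
  if (length(bad))
    stop(sprintf("malformed interaction row at line %d", bad[1] + 1L),
         call. = FALSE)
  if (is.null(nEvents)) nEvents <- max(ev) + 1L
  out <- which(ev < 0L | ev >= nEvents)
  if (length(out))
    stop(sprintf("event label %d outside [0, %d) at line %d",
                 ev[out[1]], nEvents, out[1] + 1L), call. = FALSE)
  rec <- data.frame(drugA = df$drug_a, drugB = df$drug_b, event = ev,
                    stringsAsFactors = FALSE)
  self <- rec$drugA == rec$drugB
  if (any(self)) {
    message(sprintf("dropped %d self-pair record(s)", sum(self)))
    rec <- rec[!self, , drop = FALSE]
  }
  known <- rec$drugA %in% featureTable@drugs & rec$drugB %in% featureTable@drugs
  if (any(!known)) {
    message(sprintf("dropped %d record(s) referencing unknown drugs", sum(!known)))
    rec <- rec[known, , drop = FALSE]
  }
  rownames(rec) <- NULL
  attr(rec, "nEvents") <- as.integer(nEvents)
  rec
}

#' Write interaction records as delimited text
#' @param records data.frame with columns drugA, drugB, event.
#' @param path output path.
#' @param sep field separator.
#' @export
writeInteractions <- function(records, path, sep = "\t") {
  utils::write.table(
    data.frame(drug_a = records$drugA, drug_b = records$drugB,
               event = records$event),
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove repeated interactions of drug pairs
#'
#' Keeps one record per unordered drug pair: both exact repeats and
#' mirror-orientation repeats (B, A) of an earlier (A, B) are removed, the
#' first occurrence winning.  If repeats of the same pair disagree on the
#' event label the first label is kept and the conflict is reported.
#'
#' @param records data.frame with columns drugA, drugB, event.
#' @return the deduplicated data.frame (attributes preserved).
#' @export
deduplicatePairs <- function(records) {
  if (!nrow(records)) return(records)
  key <- pairKey(records$drugA, records$drugB)
  keep <- !duplicated(key)
  first <- records$event[keep][match(key, key[keep])]
  conflicts <- sum(!keep & records$event != first)
  if (conflicts > 0L)
    message(sprintf(
      "%d repeated pair(s) carried a conflicting event label; kept first", conflicts))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nEvents") <- attr(records, "nEvents")
  out
}

#' Pair-level input vectors from a similarity matrix
#'
#' Row r is the concatenation of drug A's and drug B's similarity rows
#' (length 2N).  With `augment = TRUE` every record also contributes the
#' mirrored (B, A) orientation as an extra row with the same label,
#' doubling the row count.
#'
#' @param records data.frame with columns drugA, drugB.
#' @param sim a [SimilarityMatrix-class] indexing every record drug.
#' @param augment append mirrored orientations (default FALSE).
#' @return numeric matrix, `nrow(records)` (or twice that) x 2N.
#' @export
pairVectors <- function(records, sim, augment = FALSE) {
  ia <- match(records$drugA, sim@drugs)
  ib <- match(records$drugB, sim@drugs)
  if (anyNA(ia) || anyNA(ib)) {
    missing <- unique(c(records$drugA[is.na(ia)], records$drugB[is.na(ib)]))
    stop(sprintf("drug(s) not indexed in similarity matrix: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  v <- sim@values
  out <- cbind(v[ia, , drop = FALSE], v[ib, , drop = FALSE])
  if (augment)
    out <- rbind(out, cbind(v[ib, , drop = FALSE], v[ia, , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Assemble a PairDataset
#'
#' Deduplicates the records and builds one pair-vector matrix per
#' similarity matrix supplied.
#'
#' @param records data.frame with columns drugA, drugB, event.
#' @param sims named list of [SimilarityMatrix-class], one per modality.
#' @param nEvents number of event classes; default from the records'
#'   `nEvents` attribute or `max(event) + 1`.
#' @param augment include mirrored pair orientations (doubles rows and
#'   duplicates labels; default FALSE).
#' @return a [PairDataset-class].
#' @export
pairDataset <- function(records, sims, nEvents = NULL, augment = FALSE) {
  records <- deduplicatePairs(records)
  if (is.null(nEvents))
    nEvents <- attr(records, "nEvents") %||% (max(records$event) + 1L)
  mats <- lapply(sims, function(s) pairVectors(records, s, augment = augment))
  if (augment) {
    mirrored <- data.frame(drugA = records$drugB, drugB = records$drugA,
                           event = records$event, stringsAsFactors = FALSE)
    records <- rbind(records, mirrored)   # same labels, swapped orientation
  }
  rownames(records) <- NULL
  new("PairDataset", records = records, nEvents = as.integer(nEvents),
      pairMatrices = mats, folds = integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified k-fold assignment over interaction records
#'
#' Event-stratified partition: within each event class, records are
#' shuffled (deterministically from `seed`) and dealt to folds so per-class
#' counts differ by at most one.  Classes with fewer than k members are
#' spread round-robin across folds, with a warning.  Splits are pair-level:
#' the same drug may appear in several folds.
#'
#' @param events integer vector of event labels (or a data.frame with an
#'   `event` column).
#' @param k number of folds (>= 2).
#' @param seed integer seed making the assignment reproducible.
#' @return integer vector of fold indices in 1..k.
#' @export
stratifiedKFold <- function(events, k = 5L, seed = 1L) {
  if (is.data.frame(events)) events <- events$event
  n <- length(events)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds record count %d", k, n), call. = FALSE)
  rng <- withSeed(seed, sample.int(n))          # one global shuffle
  folds <- integer(n)
  offset <- 0L                                  # staggers rare-class round-robin
  rare <- character()
  for (cl in sort(unique(events))) {
    idx <- rng[events[rng] == cl]
    if (length(idx) < k) rare <- c(rare, as.character(cl))
    assign_ <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    folds[idx] <- assign_
    offset <- (offset + length(idx)) %% k
  }
  if (length(rare))
    warning(sprintf("event class(es) with fewer than %d records spread round-robin: %s",
                    k, paste(rare, collapse = ", ")), call. = FALSE)
  as.integer(folds)
}

#' Attach a fold assignment to a PairDataset
#' @param dataset a [PairDataset-class].
#' @param k folds.
#' @param seed RNG seed.
#' @return the dataset with `foldAssignment()` populated.
#' @export
assignFolds <- function(dataset, k = 5L, seed = 1L) {
  dataset@folds <- stratifiedKFold(dataset@records$event, k = k, seed = seed)
  validObject(dataset)
  dataset
}

# run expr under a local RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
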