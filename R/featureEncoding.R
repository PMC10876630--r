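#' Build a DrugFeatureTable from per-drug token sets
#'
#' @param drugs character vector of unique drug identifiers.
#' @param tokens named list, one entry per modality; each entry is a list
#'   of character vectors named by drug (missing drugs get empty sets).
#' @return a [DrugFeatureTable-class].
#' @examples
#' tab <- drugFeatureTable(c("d1", "d2"),
#'   list(target = list(d1 = c("a", "b"), d2 = c("b", "c"))))
#' @export
drugFeatureTable <- function(drugs, tokens) {
  drugs <- as.character(drugs)
  modalities <- names(tokens)
  tok <- lapply(modalities, function(m) {
    sets <- lapply(drugs, function(d) {
      s <- tokens[[m]][[d]]
      if (is.null(s)) character() else unique(as.character(s))
    })
    names(sets) <- drugs
    sets
  })
  names(tok) <- modalities
  new("DrugFeatureTable", drugs = drugs, modalities = modalities, tokens = tok)
}

#' Build the feature vocabulary of one modality
#'
#' The vocabulary is the sorted union of all drugs' token sets; its order
#' fixes the bit positions of the binary encoding (lexicographic, so
#' encodings are deterministic).
#'
#' @param table a [DrugFeatureTable-class].
#' @param modality modality name present in `table`.
#' @return a [FeatureVocabulary-class].
#' @export
buildVocabulary <- function(table, modality) {
  checkModality(table, modality)
  tokens <- sort(unique(unlist(table@tokens[[modality]], use.names = FALSE)))
  if (is.null(tokens)) tokens <- character()
  new("FeatureVocabulary", modality = modality, tokens = tokens)
}

#' Vocabulary size
#' @param vocab a [FeatureVocabulary-class].
#' @export
vocabularySize <- function(vocab) length(vocab@tokens)

#' Encode drugs as a binary bit matrix over a vocabulary
#'
#' Entry (i, j) is 1 iff vocabulary token j occurs in drug i's token set.
#' Tokens absent from the vocabulary are ignored with a warning (they
#' cannot be represented), never an error.
#'
#' @param table a [DrugFeatureTable-class].
#' @param vocab a [FeatureVocabulary-class] for one of `table`'s modalities.
#' @return a [BitMatrix-class] (N drugs x V tokens).
#' @export
encodeBitMatrix <- function(table, vocab) {
  checkModality(table, vocab@modality)
  sets <- table@tokens[[vocab@modality]]
  n <- length(table@drugs)
  v <- length(vocab@tokens)
  values <- matrix(0, n, v, dimnames = list(table@drugs, vocab@tokens))
  unknown <- 0L
  for (i in seq_len(n)) {
    idx <- match(sets[[i]], vocab@tokens)
    unknown <- unknown + sum(is.na(idx))
    idx <- idx[!is.na(idx)]
    values[i, idx] <- 1
  }
  if (unknown > 0L)
    warning(sprintf("%d token(s) not in the '%s' vocabulary were ignored",
                    unknown, vocab@modality), call. = FALSE)
  new("BitMatrix", drugs = table@drugs, modality = vocab@modality,
      values = values)
}

#' Drug-drug similarity matrix from a bit matrix
#'
#' Jaccard similarity of two bit rows x, y is |x AND y| / |x OR y| (shared
#' tokens over tokens in either drug); cosine is the normalized dot
#' product.  Pairs where both rows are all-zero get similarity 0 under
#' either metric (the ratio is 0/0; absent evidence is scored as no
#' similarity, keeping the range [0, 1]).  The result is symmetric with
#' unit diagonal for drugs holding at least one token.
#'
#' @param bits a [BitMatrix-class].
#' @param metric "jaccard" (default) or "cosine".
#' @return a [SimilarityMatrix-class].
#' @examples
#' tab <- drugFeatureTable(c("d1", "d2"),
#'   list(target = list(d1 = c("a", "b"), d2 = c("b", "c"))))
#' bm <- encodeBitMatrix(tab, buildVocabulary(tab, "target"))
#' similarityValues(similarityMatrix(bm))["d1", "d2"]  # 1/3
#' @export
similarityMatrix <- function(bits, metric = c("jaccard", "cosine")) {
  metric <- match.arg(metric)
  x <- bits@values
  n <- nrow(x)
  if (ncol(x) == 0L) {
    values <- matrix(0, n, n, dimnames = list(bits@drugs, bits@drugs))
  } else {
    inter <- tcrossprod(x)                     # |x AND y|
    sizes <- rowSums(x)
    if (metric == "jaccard") {
      union <- outer(sizes, sizes, "+") - inter  # |x OR y|
      values <- ifelse(union > 0, inter / pmax(union, 1), 0)
    } else {
      norms <- sqrt(sizes)                       # ||x|| for binary rows
      denom <- outer(norms, norms)
      values <- ifelse(denom > 0, inter / pmax(denom, .Machine$double.eps), 0)
    }
    values <- (values + t(values)) / 2           # exact symmetry
    dimnames(values) <- list(bits@drugs, bits@drugs)
  }
  new("SimilarityMatrix", drugs = bits@drugs, modality = bits@modality,
      metric = metric, values = values)
}

#' Read a drug-feature file
#'
#' Expects delimited text with columns `drug_id`, `modality`, `token`, one
#' token per row.  Drugs keep first-appearance order; modalities are
#' ordered substructure, target, enzyme, pathway where present, then any
#' others in appearance order.
#'
#' @param path file path.
#' @param sep field separator (default tab; `","` for CSV).
#' @return a [DrugFeatureTable-class].
#' @export
readDrugFeatures <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("drug_id", "modality", "token")
  if (!all(need %in% names(df)))
    stop("drug-feature file needs columns drug_id, modality, token", call. = FALSE)
  drugs <- unique(df$drug_id)
  seen <- unique(df$modality)
  modalities <- c(intersect(MODALITIES, seen), setdiff(seen, MODALITIES))
  tokens <- lapply(modalities, function(m) {
    sub <- df[df$modality == m, , drop = FALSE]
    split(sub$token, factor(sub$drug_id, levels = drugs))
  })
  names(tokens) <- modalities
  drugFeatureTable(drugs, tokens)
}

#' Write a drug-feature file
#'
#' Long format: one row per (drug, modality, token), tab separated.
#'
#' @param table a [DrugFeatureTable-class].
#' @param path output file path.
#' @param sep field separator.
#' @export
writeDrugFeatures <- function(table, path, sep = "\t") {
  rows <- do.call(rbind, lapply(table@modalities, function(m) {
    sets <- table@tokens[[m]]
    nn <- lengths(sets)
    data.frame(drug_id = rep(names(sets), nn), modality = m,
               token = unlist(sets, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a bit matrix as delimited text
#'
#' Round-trips a [BitMatrix-class] through gzip-compressed tab-separated
#' text with a header row of vocabulary tokens and drug identifiers in the
#' first column.
#'
#' @param bits a [BitMatrix-class].
#' @param path output path (a `.gz` suffix triggers compression).
#' @export
writeBitMatrix <- function(bits, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  df <- data.frame(drug_id = bits@drugs, bits@values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBitMatrix
#' @param modality modality name to stamp on the restored object.
#' @export
readBitMatrix <- function(path, modality) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$drug_id
  new("BitMatrix", drugs = as.character(df$drug_id), modality = modality,
      values = values)
}
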