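# Concept-frequency summarizer core: concept-count vectors and the CF score.

#' Concept-count vector of a sentence
#'
#' Counts the multiplicity of each concept id among the sentence's
#' annotations. Annotations are expected to be semantic-type-filtered
#' already (see [filter_document_annotations()]); the counting itself is
#' agnostic.
#'
#' @param sentence A `sentence`, or a list of `concept_annotation`.
#' @return Named integer vector: concept id -> occurrence count. Concepts
#'   absent from the sentence are simply absent (count 0 implicitly).
#' @export
sentence_vector <- function(sentence) {
  anns <- if (inherits(sentence, "sentence")) sentence$annotations
          else sentence
  if (!length(anns)) return(stats::setNames(integer(), character()))
  ids <- vapply(anns, `[[`, character(1), "concept_id")
  tab <- table(ids)
  v <- stats::setNames(as.integer(tab), names(tab))
  v[order(names(v))]
}

#' Document concept-count vector
#'
#' Per-concept sum of the sentence counts: the count of concept C_i in the
#' document is the number of times C_i occurs across all sentences.
#'
#' @param sentence_vectors Non-empty list of vectors from
#'   [sentence_vector()].
#' @return Named integer vector of document-level counts.
#' @export
document_vector <- function(sentence_vectors) {
  if (!length(sentence_vectors)) {
    stop("cannot build a document vector from zero sentence vectors",
         call. = FALSE)
  }
  all_ids <- sort(unique(unlist(lapply(sentence_vectors, names))))
  out <- stats::setNames(integer(length(all_ids)), all_ids)
  for (v in sentence_vectors) {
    if (length(v)) out[names(v)] <- out[names(v)] + v
  }
  out
}

#' Concept-frequency (CF) score of a sentence
#'
#' The sum over the sentence's concepts of the concept's frequency in the
#' sentence multiplied by its frequency in the whole document — the inner
#' product of the sentence and document concept vectors.
#'
#' @param sentence_vec Sentence concept vector.
#' @param doc_vec Document concept vector (aggregating the sentence's
#'   document).
#' @return Non-negative score.
#' @export
cf_score <- function(sentence_vec, doc_vec) {
  if (!length(sentence_vec)) return(0)
  common <- intersect(names(sentence_vec), names(doc_vec))
  sum(as.numeric(sentence_vec[common]) * as.numeric(doc_vec[common]))
}

#' Normalize scores into [0, 1] by the maximum
#'
#' Division by the per-document maximum preserves the ranking, which is all
#' sentence selection uses. An all-zero input maps to all zeros.
#'
#' @param scores Non-empty numeric vector of non-negative scores.
#' @return Scores scaled into \[0, 1\].
#' @export
normalize_cf <- function(scores) {
  stopifnot(length(scores) >= 1)
  m <- max(scores)
  if (m == 0) return(scores)
  scores / m
}

#' Export a concept vector as TSV
#'
#' @param vec A concept vector (named counts).
#' @param path Output path (columns `concept_id`, `count`).
#' @return `path`, invisibly.
#' @export
write_concept_vector <- function(vec, path) {
  utils::write.table(data.frame(concept_id = names(vec),
                                count = as.integer(vec)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
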