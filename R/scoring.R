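# Linear combination of base-summarizer and positional scores, top-N
# sentence selection, and the end-to-end summarize pipeline.

#' Mixing weights for base vs positional score
#'
#' @param alpha Weight of the base (semantic-similarity or
#'   concept-frequency) score, in \[0, 1\].
#' @param beta Weight of the positional score, in \[0, 1\].
#' @return An object of class `mixing_weights`.
#' @export
mixing_weights <- function(alpha = 0.8, beta = 0.2) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  structure(list(alpha = alpha, beta = beta), class = "mixing_weights")
}

#' Combine a base score with a positional score
#'
#' The combined sentence score is alpha * base + beta * positional, with
#' both inputs already normalized into \[0, 1\]. With beta = 0 the ranking
#' is exactly the base summarizer's ranking.
#'
#' @param base Normalized base score(s) in \[0, 1\].
#' @param positional Positional score(s) in \[0, 1\].
#' @param w A [mixing_weights()] object.
#' @return Combined score(s).
#' @export
combine_scores <- function(base, positional, w = mixing_weights()) {
  stopifnot(inherits(w, "mixing_weights"))
  w$alpha * base + w$beta * positional
}

#' Select the top-N sentences
#'
#' The N highest-scoring sentence positions, ties broken toward the earlier
#' position; the selection is returned in document order for readability.
#' When N exceeds the number of sentences, all sentences are selected.
#'
#' @param scores Named numeric vector: sentence position -> score (names
#'   coercible to integer), or an unnamed vector indexed by position.
#' @param n Number of sentences to select (>= 1).
#' @return Integer vector of selected positions, in increasing order.
#' @export
select_sentences <- function(scores, n) {
  if (!length(scores)) stop("no sentence scores to select from",
                            call. = FALSE)
  stopifnot(n >= 1)
  pos <- if (is.null(names(scores))) seq_along(scores)
         else as.integer(names(scores))
  ord <- order(-scores, pos)
  sort(pos[ord[seq_len(min(n, length(scores)))]])
}

#' Summarize a structured document
#'
#' Runs the full extractive pipeline: semantic-type filtering, base
#' sentence scoring with the chosen engine (concept graph with hub-vertex
#' clustering, or concept frequency), max-normalization of the base scores,
#' positional scoring with the chosen strategy, linear combination, and
#' top-N selection. With `strategy = "none"` the positional weight beta is
#' forced to 0 and the result is the plain base summarizer.
#'
#' @param document An annotated `structured_document`.
#' @param engine `"graph"` or `"frequency"`.
#' @param strategy `"none"`, `"begin"`, `"begin_end"` or `"section"`.
#' @param n Summary length in sentences; default is the abstract length,
#'   the evaluation protocol's summary size.
#' @param weights A [mixing_weights()] object (alpha, beta).
#' @param section_w A [section_weights()] object (used by
#'   `strategy = "section"`).
#' @param hierarchy A `concept_hierarchy`; required for the graph engine.
#' @param hub_fraction Hub fraction for the graph engine's clustering.
#' @param pruning_levels Hierarchy pruning depth for the graph engine.
#' @param filter_types Apply the default semantic-type exclusion before
#'   scoring (default TRUE).
#' @return An object of class `summary_result`: selected positions, the
#'   selected sentence texts, and a per-sentence score breakdown data
#'   frame (`position`, `base`, `positional`, `combined`).
#' @export
summarize_document <- function(document,
                               engine = c("frequency", "graph"),
                               strategy = c("none", "begin", "begin_end",
                                            "section"),
                               n = NULL,
                               weights = mixing_weights(),
                               section_w = section_weights(),
                               hierarchy = NULL,
                               hub_fraction = 0.2,
                               pruning_levels = 2L,
                               filter_types = TRUE) {
  engine <- match.arg(engine)
  strategy <- match.arg(strategy)
  if (is.null(n)) n <- abstract_length(document)
  if (filter_types) document <- filter_document_annotations(document)
  M <- doc_length(document)

  if (engine == "frequency") {
    svecs <- lapply(document$sentences, sentence_vector)
    dvec <- document_vector(svecs)
    base <- vapply(svecs, cf_score, numeric(1), doc_vec = dvec)
  } else {
    if (is.null(hierarchy)) {
      stop("the graph engine requires a concept hierarchy", call. = FALSE)
    }
    sgraphs <- lapply(document$sentences, build_sentence_graph,
                      hierarchy = hierarchy,
                      pruning_levels = pruning_levels)
    dgraph <- build_document_graph(sgraphs, hierarchy)
    partition <- cluster_hvs(dgraph, hub_fraction = hub_fraction)
    base <- vapply(sgraphs, function(g) {
      if (igraph::vcount(g) == 0) 0 else sem_sim(g, partition)
    }, numeric(1))
  }
  base_norm <- normalize_cf(base)
  posit <- positional_scores(document, strategy, section_w)
  w <- if (strategy == "none") mixing_weights(weights$alpha, 0) else weights
  combined <- combine_scores(base_norm, posit, w)
  names(combined) <- seq_len(M)
  selected <- select_sentences(combined, n)
  structure(
    list(selected = selected,
         sentences = vapply(document$sentences[selected], `[[`,
                            character(1), "text"),
         scores = data.frame(position = seq_len(M), base = base_norm,
                             positional = posit, combined = unname(combined)),
         engine = engine, strategy = strategy),
    class = "summary_result")
}

#' @export
print.summary_result <- function(x, ...) {
  cat(sprintf("<summary_result: engine=%s strategy=%s, %d sentences>\n",
              x$engine, x$strategy, length(x$selected)))
  for (i in seq_along(x$selected)) {
    cat(sprintf("  [%d] %s\n", x$selected[i], x$sentences[i]))
  }
  invisible(x)
}
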