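# The three positional sentence-weighting strategies.

#' Section weights for the Section-Pos strategy
#'
#' One weight per section class: `gamma` (Introduction), `delta`
#' (Background), `theta` (Methods/Materials), `sigma` (Results/Discussion)
#' and `pi` (Conclusions/Future Work), each in \[0, 1\]. Sentences whose
#' header matched no class (`OTHER`) receive `other_weight`, which defaults
#' to 0 because the section-weight formula defines no term for them.
#'
#' The defaults are the best-performing configuration found empirically for
#' biomedical articles: methods/materials and results/discussion sections
#' carry full weight, the introduction a small weight, background none and
#' conclusions almost none.
#'
#' @param gamma,delta,theta,sigma,pi Class weights in \[0, 1\].
#' @param other_weight Weight for unclassified sections, in \[0, 1\].
#' @return An object of class `section_weights`.
#' @export
section_weights <- function(gamma = 0.2, delta = 0.0, theta = 1.0,
                            sigma = 1.0, pi = 0.1, other_weight = 0.0) {
  w <- c(INTRODUCTION = gamma, BACKGROUND = delta,
         METHODS_MATERIALS = theta, RESULTS_DISCUSSION = sigma,
         CONCLUSIONS_FUTURE = pi, OTHER = other_weight)
  if (any(w < 0 | w > 1)) stop("all section weights must lie in [0, 1]",
                               call. = FALSE)
  structure(as.list(w), class = "section_weights")
}

#' Begin-Pos: reciprocal-position score
#'
#' Sentences near the beginning of the document score highest: the score of
#' the sentence at position m is 1/m, so the first sentence scores 1, the
#' second 0.5, and so on.
#'
#' @param position Sentence position m (integer >= 1); vectorized.
#' @return Score(s) in (0, 1].
#' @export
begin_pos <- function(position) {
  if (any(position < 1 | position != floor(position))) {
    stop("`position` must be an integer >= 1", call. = FALSE)
  }
  1 / position
}

#' Begin-End-Pos: distance to either document end
#'
#' The score of the sentence at position m in an M-sentence document is
#' max(1/m, 1/(M - m + 1)) — the larger of the reciprocal distances to the
#' beginning and the end, so both the first and the last sentence score 1.
#'
#' @param position Sentence position m (1 <= m <= M); vectorized.
#' @param doc_length Document length M in sentences.
#' @return Score(s) in (0, 1].
#' @export
begin_end_pos <- function(position, doc_length) {
  if (any(doc_length < 1) || any(position < 1) ||
      any(position > doc_length) || any(position != floor(position))) {
    stop("need 1 <= position <= doc_length", call. = FALSE)
  }
  pmax(1 / position, 1 / (doc_length - position + 1))
}

#' Section-Pos: per-section-class weight
#'
#' Each sentence belongs to exactly one section class, so the weighted sum
#' over class-indicator functions collapses to the single weight of the
#' sentence's class.
#'
#' @param section_class Section class label(s) (see
#'   [classify_section_header()]); vectorized.
#' @param weights A [section_weights()] object.
#' @return Score(s) in \[0, 1\].
#' @export
section_pos <- function(section_class, weights = section_weights()) {
  stopifnot(inherits(weights, "section_weights"))
  bad <- setdiff(unique(section_class), SECTION_CLASSES)
  if (length(bad)) stop("unknown section class: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  vapply(section_class, function(cls) weights[[cls]], numeric(1),
         USE.NAMES = FALSE)
}

#' Positional scores for every sentence of a document
#'
#' @param document A `structured_document`.
#' @param strategy `"none"` (all zeros), `"begin"`, `"begin_end"` or
#'   `"section"`.
#' @param weights A [section_weights()] object (used by `"section"` only).
#' @return Numeric vector of length M, one score per sentence in position
#'   order.
#' @export
positional_scores <- function(document,
                              strategy = c("none", "begin", "begin_end",
                                           "section"),
                              weights = section_weights()) {
  strategy <- match.arg(strategy)
  M <- doc_length(document)
  pos <- seq_len(M)
  switch(strategy,
         none = rep(0, M),
         begin = begin_pos(pos),
         begin_end = begin_end_pos(pos, M),
         section = section_pos(
           vapply(document$sentences, `[[`, character(1), "section_class"),
           weights))
}
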