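# Worked-example fixture (the five-sentence LRF-1 liver-regeneration
# passage with its concept annotations) and a synthetic-document generator
# for controlled experiments.

#' Load the worked-example document
#'
#' A five-sentence molecular-biology passage about the LRF-1/JunB/c-Jun/
#' c-Fos regulatory program in liver regeneration, shipped with its
#' per-sentence concept annotations (17 distinct concepts) and a small toy
#' concept hierarchy. The one-sentence abstract and the hierarchy are
#' illustrative additions so the fixture satisfies the full structured
#' format; the sentence texts and concept multisets are the substantive
#' part.
#'
#' @return An annotated `structured_document` with 5 sentences.
#' @export
load_worked_example <- function() {
  doc <- parse_structured_document(
    system.file("extdata", "lrf1_document.json", package = "sectsum"),
    dialect = "json")
  anns <- parse_annotation_file(
    system.file("extdata", "lrf1_annotations.tsv", package = "sectsum"),
    document = doc)
  attach_annotations(doc, anns)
}

#' Toy concept hierarchy of the worked example
#'
#' Synthetic and illustrative: depths and relations are chosen to be
#' consistent with the worked example's concepts, not a reproduction of
#' any controlled vocabulary.
#'
#' @return A `concept_hierarchy`.
#' @export
worked_example_hierarchy <- function() {
  read_concept_hierarchy(
    system.file("extdata", "lrf1_hierarchy.tsv", package = "sectsum"))
}

#' Dictionary lexicon for the worked example
#'
#' Maps surface forms of the worked-example passage to concept annotations,
#' for exercising the UMLS-free dictionary annotation path. Longest-match
#' resolution makes "c-Fos-containing complexes" annotate as the C-Complex
#' concept rather than as c-fos plus Complexes.
#'
#' @return Named list: surface form -> `concept_annotation`.
#' @export
worked_example_lexicon <- function() {
  mk <- function(id, types) concept_annotation(id, semantic_types = types)
  list(
    "LRF-1" = mk("LRF", "Gene or Genome"),
    "c-Jun" = mk("c-Jun", "Gene or Genome"),
    "c-Fos" = mk("c-fos", "Gene or Genome"),
    "liver" = mk("Liver", "Body Part, Organ, or Organ Component"),
    "cell" = mk("Cell", "Cell"),
    "cells" = mk("Cell", "Cell"),
    "growth" = mk("growth", "Biologic Function"),
    "regeneration" = mk("Regeneration", "Biologic Function"),
    "program" = mk("Program", "Biologic Function"),
    "transition" = mk("Transition", "Biologic Function"),
    "complexes" = mk("Complexes", "Amino Acid, Peptide, or Protein"),
    "c-Fos-containing complexes" =
      mk("C-Complex", "Amino Acid, Peptide, or Protein"),
    "promoter" = mk("Promoter", "Nucleotide Sequence"),
    "combination" = mk("Combination", "Activity"),
    "Jun protein" = mk("JUNProtein", "Amino Acid, Peptide, or Protein"),
    "protein" = mk("Protein", "Amino Acid, Peptide, or Protein"),
    "element" = mk("Element", "Nucleotide Sequence")
  )
}

#' Specification for a synthetic structured document
#'
#' The generator emulates the structural features the summarizers exploit:
#' a five-class section skeleton, heavy-tailed (Zipf-like) concept counts,
#' topical concepts concentrated in designated "salient" section classes,
#' and an abstract built by copying the most topical sentences of those
#' classes (so selection quality against the abstract is measurable). The
#' seed fully determines the output.
#'
#' @param sections_per_class Named integer vector: section class ->
#'   number of sections. Default: one section for each of the five named
#'   classes.
#' @param sentences_per_section Sentences in each section (default 8).
#' @param vocab_size Concept vocabulary size (default 60).
#' @param n_topical Number of topical concepts planted in the salient
#'   classes (default 8).
#' @param n_distractor Size of the per-class distractor concept pool: each
#'   non-salient section class gets its own `n_distractor` concepts
#'   (default 8).
#' @param salient_classes Classes holding the abstract-worthy content;
#'   default methods/materials and results/discussion.
#' @param p_topical Probability that a concept slot in a salient-class
#'   sentence draws a topical concept (default 0.7).
#' @param distractor_strength Concentration of non-salient classes on
#'   their own distractor pool, relative to `p_topical` (default 0.6):
#'   distractor topics are prominent but less focused than the article's
#'   main topic, as in real article sections.
#' @param concepts_per_sentence Integer range (min, max) of concept
#'   occurrences per sentence (default c(4, 8)).
#' @param abstract_length Abstract length in sentences (default 6).
#' @param zipf_exponent Exponent of the Zipf-like concept distribution
#'   (default 1).
#' @param seed Random seed (integer).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(sections_per_class = c(INTRODUCTION = 1L,
                                                  BACKGROUND = 1L,
                                                  METHODS_MATERIALS = 1L,
                                                  RESULTS_DISCUSSION = 1L,
                                                  CONCLUSIONS_FUTURE = 1L),
                           sentences_per_section = 8L,
                           vocab_size = 60L,
                           n_topical = 8L,
                           n_distractor = 8L,
                           salient_classes = c("METHODS_MATERIALS",
                                               "RESULTS_DISCUSSION"),
                           p_topical = 0.7,
                           distractor_strength = 0.6,
                           concepts_per_sentence = c(4L, 8L),
                           abstract_length = 6L,
                           zipf_exponent = 1,
                           seed = 1L) {
  stopifnot(all(sections_per_class >= 0),
            sum(sections_per_class) > 0,
            sentences_per_section >= 1,
            vocab_size >= n_topical + n_distractor,
            abstract_length >= 1,
            length(concepts_per_sentence) == 2,
            all(salient_classes %in% SECTION_CLASSES))
  bad <- setdiff(names(sections_per_class), SECTION_CLASSES)
  if (length(bad)) stop("unknown section class: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(sections_per_class = sections_per_class,
                 sentences_per_section = sentences_per_section,
                 vocab_size = vocab_size, n_topical = n_topical,
                 n_distractor = n_distractor,
                 salient_classes = salient_classes, p_topical = p_topical,
                 distractor_strength = distractor_strength,
                 concepts_per_sentence = concepts_per_sentence,
                 abstract_length = abstract_length,
                 zipf_exponent = zipf_exponent, seed = seed),
            class = "synthetic_spec")
}

class_headers <- c(INTRODUCTION = "Introduction",
                   BACKGROUND = "Background",
                   METHODS_MATERIALS = "Methods",
                   RESULTS_DISCUSSION = "Results and Discussion",
                   CONCLUSIONS_FUTURE = "Conclusions",
                   OTHER = "Appendix")

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed",
                                envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

filler_words <- c("the", "of", "in", "and", "with", "for", "was", "were",
                  "observed", "measured", "analysis", "showed", "using",
                  "between", "levels", "samples", "data", "results")

#' Generate a synthetic annotated document
#'
#' See [synthetic_spec()] for what is emulated. Each sentence draws a
#' number of concept occurrences; salient-class sentences draw mostly from
#' the topical pool, other sentences mostly from the distractor pool (with
#' Zipf-like background concepts mixed into both). Sentence text is built
#' from concept surface words interleaved with filler words, so ROUGE
#' overlap against the abstract tracks concept overlap. The abstract
#' copies the `abstract_length` salient-class sentences richest in topical
#' concepts.
#'
#' @param spec A `synthetic_spec`.
#' @return An annotated `structured_document` (bit-identical for a given
#'   spec, including the seed).
#' @export
generate_synthetic_document <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    vocab <- sprintf("C%03d", seq_len(spec$vocab_size))
    surface <- sprintf("concept%03d", seq_len(spec$vocab_size))
    topical <- seq_len(spec$n_topical)
    # every non-salient class gets its own distractor sub-vocabulary, so
    # no single distractor topic accumulates document frequency across
    # sections the way the shared topical pool does
    active <- names(spec$sections_per_class)[spec$sections_per_class > 0]
    nonsal <- setdiff(active, spec$salient_classes)
    pool_of <- list()
    for (k in seq_along(nonsal)) {
      start <- spec$n_topical + (k - 1L) * spec$n_distractor
      if (start + spec$n_distractor > spec$vocab_size) {
        stop("vocab_size too small for ", length(nonsal),
             " per-class distractor pools", call. = FALSE)
      }
      pool_of[[nonsal[k]]] <- (start + 1L):(start + spec$n_distractor)
    }
    background <- setdiff(seq_len(spec$vocab_size),
                          c(topical, unlist(pool_of)))
    if (!length(background)) background <- topical
    zipf <- function(idx) {
      p <- seq_along(idx)^(-spec$zipf_exponent); p / sum(p)
    }
    # Zipf-like prominence within a topic pool; the background tail is
    # flat so no incidental concept outweighs the planted topics
    draw_concepts <- function(k, pool, p) {
      vapply(seq_len(k), function(i) {
        if (stats::runif(1) < p) {
          sample(pool, 1, prob = zipf(pool))
        } else sample(background, 1)
      }, integer(1))
    }
    sentences <- list(); pos <- 0L
    topical_hits <- integer(); is_salient_sent <- logical()
    for (cls in names(spec$sections_per_class)) {
      n_sec <- spec$sections_per_class[[cls]]
      if (n_sec == 0L) next
      salient <- cls %in% spec$salient_classes
      class_pool <- if (salient) topical else pool_of[[cls]]
      class_p <- if (salient) spec$p_topical else
        spec$p_topical * spec$distractor_strength
      for (sec in seq_len(n_sec)) {
        header <- if (n_sec == 1L) class_headers[[cls]] else
          paste(class_headers[[cls]], sec)
        for (sj in seq_len(spec$sentences_per_section)) {
          pos <- pos + 1L
          k <- sample(spec$concepts_per_sentence[1]:
                        spec$concepts_per_sentence[2], 1)
          ids <- draw_concepts(k, class_pool, class_p)
          words <- character(0)
          for (cid in ids) {
            words <- c(words, sample(filler_words, 1), surface[cid])
          }
          text <- paste0(toupper(substring(paste(words, collapse = " "),
                                           1, 1)),
                         substring(paste(words, collapse = " "), 2), ".")
          anns <- lapply(ids, function(cid) {
            concept_annotation(vocab[cid], preferred_name = surface[cid],
                               semantic_types = "Synthetic concept")
          })
          sentences[[pos]] <- new_sentence(pos, text, header, cls, anns)
          topical_hits[pos] <- sum(ids %in% topical)
          is_salient_sent[pos] <- salient
        }
      }
    }
    cand <- which(is_salient_sent)
    if (!length(cand)) cand <- seq_along(sentences)
    ord <- cand[order(-topical_hits[cand], cand)]
    chosen <- sort(ord[seq_len(min(spec$abstract_length, length(ord)))])
    abstract <- vapply(sentences[chosen], `[[`, character(1), "text")
    doc <- new_structured_document(
      sprintf("synthetic-seed%d", spec$seed), sentences, abstract)
    attr(doc, "planted_positions") <- chosen
    doc
  })
}

#' Toy hierarchy for synthetic documents
#'
#' Assigns every synthetic concept a depth-3 hypernym path
#' (ROOT > group > concept, groups of ten concepts) and relates
#' consecutive topical concepts, so the graph engine can run on generated
#' documents.
#'
#' @param spec A `synthetic_spec`.
#' @return A `concept_hierarchy`.
#' @export
synthetic_hierarchy <- function(spec = synthetic_spec()) {
  vocab <- sprintf("C%03d", seq_len(spec$vocab_size))
  grp <- sprintf("GROUP%02d", ((seq_len(spec$vocab_size) - 1L) %/% 10L) + 1L)
  is_a <- rbind(
    data.frame(a = unique(grp), b = "ROOT", stringsAsFactors = FALSE),
    data.frame(a = vocab, b = grp, stringsAsFactors = FALSE))
  topical <- vocab[seq_len(spec$n_topical)]
  related <- if (length(topical) > 1) {
    data.frame(a = topical[-length(topical)], b = topical[-1],
               kind = "metathesaurus_related", stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(), b = character(), kind = character())
  }
  concept_hierarchy(is_a = is_a, related = related)
}

#' Generate a synthetic corpus
#'
#' @param n_docs Number of documents.
#' @param spec Base `synthetic_spec`; document i uses seed
#'   `spec$seed + i - 1`.
#' @return List of annotated `structured_document`s.
#' @export
generate_synthetic_corpus <- function(n_docs, spec = synthetic_spec()) {
  stopifnot(n_docs >= 1)
  lapply(seq_len(n_docs), function(i) {
    s <- spec; s$seed <- spec$seed + i - 1L
    generate_synthetic_document(s)
  })
}
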