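# Recall-oriented ROUGE-2 / ROUGE-SU4, the abstract-length summary
# protocol, paired Wilcoxon significance testing, and the benchmark runner.

#' Tokenize text for ROUGE
#'
#' Lowercases and splits on runs of non-alphanumeric characters. No
#' stemming and no stopword removal by default; Porter-less light stemming
#' (plural/suffix stripping) can be enabled for experimentation.
#'
#' @param text Character vector (one element per sentence).
#' @param stem Apply light suffix stripping (default FALSE).
#' @return List of character vectors, one token vector per sentence.
#' @export
rouge_tokenize <- function(text, stem = FALSE) {
  lapply(text, function(s) {
    toks <- strsplit(tolower(s), "[^a-z0-9]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (stem) toks <- sub("(ing|edly|ed|ly|es|s)$", "", toks)
    toks
  })
}

count_units <- function(units) {
  if (!length(units)) return(stats::setNames(integer(), character()))
  tab <- table(units)
  stats::setNames(as.integer(tab), names(tab))
}

sentence_bigrams <- function(tokens) {
  unlist(lapply(tokens, function(t) {
    if (length(t) < 2L) return(character())
    paste(t[-length(t)], t[-1])
  }))
}

# skip-bigrams with at most `gap` intervening tokens, plus unigrams (the
# "U" in SU); units never cross sentence boundaries
sentence_skip_units <- function(tokens, gap = 4L) {
  unlist(lapply(tokens, function(t) {
    n <- length(t)
    units <- t  # unigram credit
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        jmax <- min(n, i + gap + 1L)
        units <- c(units, paste(t[i], t[(i + 1L):jmax]))
      }
    }
    units
  }))
}

clipped_recall <- function(metric, peer_counts, ref_count_list) {
  overlap <- 0L; total <- 0L
  for (rc in ref_count_list) {
    total <- total + sum(rc)
    common <- intersect(names(rc), names(peer_counts))
    if (length(common)) {
      overlap <- overlap + sum(pmin(rc[common], peer_counts[common]))
    }
  }
  structure(list(metric = metric,
                 recall = if (total > 0) overlap / total else 0,
                 overlap_count = as.integer(overlap),
                 reference_count = as.integer(total)),
            class = "rouge_score")
}

#' @export
print.rouge_score <- function(x, ...) {
  cat(sprintf("%s recall = %.4f (%d / %d)\n", x$metric, x$recall,
              x$overlap_count, x$reference_count))
  invisible(x)
}

as_reference_list <- function(references) {
  if (is.character(references)) list(references) else references
}

#' ROUGE-2 recall
#'
#' Clipped bigram-overlap recall of a peer summary against one or more
#' reference summaries: sum over references of min(peer count, reference
#' count) per bigram, divided by the total reference bigram count
#' (micro-averaging across references). Bigrams do not cross sentence
#' boundaries. A reference with fewer than two tokens contributes no
#' bigrams; if the total reference count is zero the recall is defined as 0.
#'
#' @param peer Character vector of peer-summary sentences.
#' @param references A character vector (one reference, one element per
#'   sentence) or a list of such vectors.
#' @param stem Light stemming option passed to [rouge_tokenize()].
#' @return A `rouge_score` (metric, recall, overlap_count,
#'   reference_count).
#' @export
rouge2 <- function(peer, references, stem = FALSE) {
  refs <- as_reference_list(references)
  stopifnot(length(refs) >= 1)
  pc <- count_units(sentence_bigrams(rouge_tokenize(peer, stem)))
  rcs <- lapply(refs, function(r) {
    count_units(sentence_bigrams(rouge_tokenize(r, stem)))
  })
  clipped_recall("ROUGE-2", pc, rcs)
}

#' ROUGE-SU4 recall
#'
#' Clipped overlap recall over skip-bigrams with a skip distance of 4 (at
#' most four intervening tokens, in sentence order, within a sentence)
#' together with unigrams — the "U" extension that grants credit for
#' single-word matches.
#'
#' @inheritParams rouge2
#' @return A `rouge_score`.
#' @export
rouge_su4 <- function(peer, references, stem = FALSE) {
  refs <- as_reference_list(references)
  stopifnot(length(refs) >= 1)
  pc <- count_units(sentence_skip_units(rouge_tokenize(peer, stem)))
  rcs <- lapply(refs, function(r) {
    count_units(sentence_skip_units(rouge_tokenize(r, stem)))
  })
  clipped_recall("ROUGE-SU4", pc, rcs)
}

#' Summary length dictated by the reference abstract
#'
#' Automatic summaries are generated with the same number of sentences as
#' the article's abstract, the reference (model) summary.
#'
#' @param document A `structured_document`.
#' @return Integer number of abstract sentences.
#' @export
abstract_length <- function(document) {
  if (!length(document$abstract)) {
    stop("document '", document$doc_id, "' has no abstract", call. = FALSE)
  }
  length(document$abstract)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of the paired differences a - b. For small samples
#' (n <= 25) with no zero differences and no tied magnitudes the exact
#' distribution is used (via [stats::wilcox.test()]); otherwise a normal
#' approximation with Pratt handling of zeros (zeros are ranked, then their
#' ranks dropped from the statistic) and a tie correction is applied.
#'
#' @param a,b Equal-length numeric vectors of paired scores (length >= 6).
#' @param confidence Confidence level (default 0.95; informational —
#'   the returned p-value is what callers compare to 1 - confidence).
#' @return List with `statistic` (W+, the positive-rank sum), `p_value`,
#'   and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, confidence = 0.95) {
  if (length(a) != length(b)) stop("paired score vectors differ in length",
                                   call. = FALSE)
  n <- length(a)
  if (n < 6) stop("need at least 6 pairs for the signed-rank test",
                  call. = FALSE)
  d <- a - b
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, method = "degenerate"))
  }
  zeros <- sum(d == 0)
  ties <- anyDuplicated(abs(d[d != 0])) > 0
  if (n <= 25 && zeros == 0 && !ties) {
    wt <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE,
                             alternative = "two.sided")
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                method = "exact"))
  }
  # Pratt: rank |d| including zeros, drop zero ranks from the statistic
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  n0 <- zeros
  mu <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
  tie_tab <- table(r[d != 0])
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sig2 <= 0) {
    return(list(statistic = w_pos, p_value = 1, method = "pratt-degenerate"))
  }
  z <- (w_pos - mu) / sqrt(sig2)
  list(statistic = w_pos, p_value = 2 * stats::pnorm(-abs(z)),
       method = "pratt-normal")
}

#' Benchmark summarizer configurations over a corpus
#'
#' For every configuration, summarizes every document at abstract length,
#' scores the summary with ROUGE-2 and ROUGE-SU4 against the abstract, and
#' reports per-configuration mean recalls. Each configuration with a
#' positional component is compared against the beta = 0 baseline of the
#' same engine with a paired Wilcoxon signed-rank test (when the corpus has
#' at least 6 documents).
#'
#' @param corpus Non-empty list of annotated `structured_document`s.
#' @param configurations List of configuration lists; each may carry
#'   `label`, `engine`, `strategy`, `weights` ([mixing_weights()]),
#'   `section_w` ([section_weights()]), `hub_fraction`, `pruning_levels`.
#' @param hierarchy Optional `concept_hierarchy` for graph-engine
#'   configurations.
#' @param confidence Confidence level for significance flags.
#' @return Data frame with one row per configuration: label, engine,
#'   strategy, alpha, beta, mean_rouge2, mean_rouge_su4, p_rouge2,
#'   significant. Per-document recalls are attached as attribute
#'   `"per_document"`.
#' @export
run_benchmark <- function(corpus, configurations, hierarchy = NULL,
                          confidence = 0.95) {
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  if (!length(configurations)) stop("no configurations", call. = FALSE)
  per_doc <- list()
  rows <- list()
  for (ci in seq_along(configurations)) {
    cfg <- configurations[[ci]]
    engine <- cfg$engine %||% "frequency"
    strategy <- cfg$strategy %||% "none"
    w <- cfg$weights %||% mixing_weights()
    sw <- cfg$section_w %||% section_weights()
    label <- cfg$label %||% sprintf("%s/%s a=%.2f b=%.2f", engine, strategy,
                                    w$alpha, w$beta)
    r2 <- su4 <- numeric(length(corpus))
    for (di in seq_along(corpus)) {
      doc <- corpus[[di]]
      res <- summarize_document(doc, engine = engine, strategy = strategy,
                                weights = w, section_w = sw,
                                hierarchy = hierarchy %||% cfg$hierarchy,
                                hub_fraction = cfg$hub_fraction %||% 0.2,
                                pruning_levels = cfg$pruning_levels %||% 2L)
      r2[di] <- rouge2(res$sentences, doc$abstract)$recall
      su4[di] <- rouge_su4(res$sentences, doc$abstract)$recall
    }
    per_doc[[ci]] <- list(label = label, engine = engine,
                          strategy = strategy, beta = w$beta,
                          rouge2 = r2, rouge_su4 = su4)
    rows[[ci]] <- data.frame(label = label, engine = engine,
                             strategy = strategy, alpha = w$alpha,
                             beta = w$beta, mean_rouge2 = mean(r2),
                             mean_rouge_su4 = mean(su4),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_rouge2 <- NA_real_
  out$significant <- FALSE
  for (ci in seq_along(per_doc)) {
    pd <- per_doc[[ci]]
    if (pd$beta == 0 || pd$strategy == "none") next
    base_i <- which(vapply(per_doc, function(x) {
      x$engine == pd$engine && (x$beta == 0 || x$strategy == "none")
    }, logical(1)))
    if (!length(base_i) || length(corpus) < 6) next
    wt <- wilcoxon_signed_rank(pd$rouge2, per_doc[[base_i[1]]]$rouge2)
    out$p_rouge2[ci] <- wt$p_value
    out$significant[ci] <- wt$p_value < (1 - confidence)
  }
  attr(out, "per_document") <- per_doc
  out
}
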