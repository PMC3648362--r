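# Structured-document parsing, section-header classification, concept
# annotation ingestion, and the dictionary-based fallback annotator.

SECTION_CLASSES <- c("INTRODUCTION", "BACKGROUND", "METHODS_MATERIALS",
                     "RESULTS_DISCUSSION", "CONCLUSIONS_FUTURE", "OTHER")

#' Create a concept annotation
#'
#' A concept annotation records one occurrence of a controlled-vocabulary
#' concept (a UMLS Metathesaurus concept, or a dictionary entry standing in
#' for one) in a sentence. Repeated occurrences of the same concept are
#' represented by repeated annotations, so annotation lists encode frequency.
#'
#' @param concept_id Non-empty concept identifier (e.g. a CUI or a mnemonic).
#' @param preferred_name Human-readable concept name; defaults to the id.
#' @param semantic_types Character vector of semantic-type names (possibly
#'   empty). Used by [filter_semantic_types()].
#' @param hypernym_path Character vector giving the root-to-concept path of
#'   `is_a` hypernyms in a concept hierarchy; must end with `concept_id` when
#'   non-empty. Empty when no hierarchy is available.
#' @return An object of class `concept_annotation`.
#' @export
concept_annotation <- function(concept_id, preferred_name = concept_id,
                               semantic_types = character(),
                               hypernym_path = character()) {
  if (!is.character(concept_id) || length(concept_id) != 1L ||
      is.na(concept_id) || !nzchar(concept_id)) {
    stop("`concept_id` must be a single non-empty string", call. = FALSE)
  }
  if (length(hypernym_path) > 0L &&
      hypernym_path[length(hypernym_path)] != concept_id) {
    stop("`hypernym_path` must end with `concept_id` (got path ending in '",
         hypernym_path[length(hypernym_path)], "' for concept '",
         concept_id, "')", call. = FALSE)
  }
  structure(
    list(concept_id = concept_id,
         preferred_name = preferred_name,
         semantic_types = as.character(semantic_types),
         hypernym_path = as.character(hypernym_path)),
    class = "concept_annotation"
  )
}

new_sentence <- function(position, text, section_header, section_class,
                         annotations = list()) {
  structure(
    list(position = as.integer(position), text = text,
         section_header = section_header, section_class = section_class,
         annotations = annotations),
    class = "sentence"
  )
}

new_structured_document <- function(doc_id, sentences, abstract) {
  pos <- vapply(sentences, `[[`, integer(1), "position")
  stopifnot(identical(pos, seq_along(sentences)))
  structure(
    list(doc_id = doc_id, sentences = sentences, abstract = abstract),
    class = "structured_document"
  )
}

#' @export
print.structured_document <- function(x, ...) {
  cat(sprintf("<structured_document '%s': %d sentences, %d abstract sentences>\n",
              x$doc_id, length(x$sentences), length(x$abstract)))
  tab <- table(vapply(x$sentences, `[[`, character(1), "section_class"))
  cat("  sections:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of sentences in a document
#' @param document A `structured_document`.
#' @return Integer count of body sentences (the document length M).
#' @export
doc_length <- function(document) length(document$sentences)

normalize_header <- function(header) {
  h <- tolower(trimws(header))
  h <- gsub("[^a-z0-9 ]+", " ", h)
  gsub(" +", " ", trimws(h))
}

section_mapping_env <- new.env(parent = emptyenv())

#' Load a section-header mapping table
#'
#' The table maps normalized header strings to one of the five named section
#' classes. The shipped table is a best-effort reconstruction of the
#' conventional groupings of biomedical article headers (IMRaD and common
#' variants) and is user-extensible: supply your own TSV with columns
#' `pattern` and `class`.
#'
#' @param path Path to a two-column TSV (pattern, class); default is the
#'   table shipped with the package.
#' @return A named character vector: normalized pattern -> section class.
#' @export
load_section_mapping <- function(path = system.file("extdata",
                                                    "section_classes.tsv",
                                                    package = "sectsum")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("pattern", "class") %in% names(tab)))
  bad <- setdiff(unique(tab$class), SECTION_CLASSES)
  if (length(bad)) stop("unknown section class in mapping table: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  stats::setNames(tab$class, normalize_header(tab$pattern))
}

default_section_mapping <- function() {
  if (is.null(section_mapping_env$map)) {
    section_mapping_env$map <- load_section_mapping()
  }
  section_mapping_env$map
}

#' Classify a section header into one of the five section classes
#'
#' Matching is case-insensitive and punctuation-normalized against a mapping
#' table of header variants; lexical variants collapse to one class
#' ("Method" and "Methods" are both methods/materials, as is "Experimental
#' Procedures"). A header matching no rule is classified `OTHER`.
#'
#' @param header Section header string (non-empty).
#' @param mapping Optional mapping from [load_section_mapping()].
#' @return One of `"INTRODUCTION"`, `"BACKGROUND"`, `"METHODS_MATERIALS"`,
#'   `"RESULTS_DISCUSSION"`, `"CONCLUSIONS_FUTURE"`, `"OTHER"`.
#' @export
classify_section_header <- function(header, mapping = NULL) {
  stopifnot(is.character(header), all(nzchar(header)))
  if (is.null(mapping)) mapping <- default_section_mapping()
  key <- normalize_header(header)
  out <- unname(mapping[key])
  out[is.na(out)] <- "OTHER"
  out
}

#' Parse a structured article
#'
#' Two dialects are supported. The JSON dialect has fields `doc_id`,
#' `abstract` (array of sentence strings) and `sections` (array of objects
#' with `header` and `sentences`). The plaintext dialect uses
#' `== header ==` section markers with one sentence per line; the first
#' section must be the abstract (any header containing "abstract").
#' Sentences are pre-split in both dialects: sentence segmentation is not
#' part of the summarization method, so the convenience splitter
#' [split_sentences()] is offered separately for raw text.
#'
#' @param path Path to the document file.
#' @param dialect `"json"` or `"plaintext"`.
#' @param mapping Optional section-header mapping table.
#' @return A `structured_document` with 1-based consecutive sentence
#'   positions and a section class on every sentence.
#' @export
parse_structured_document <- function(path, dialect = c("json", "plaintext"),
                                      mapping = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "json") {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e) stop("malformed JSON in '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
    doc_id <- doc$doc_id %||% tools::file_path_sans_ext(basename(path))
    abstract <- vapply(doc$abstract, as.character, character(1))
    sections <- lapply(doc$sections, function(s) {
      list(header = as.character(s$header),
           sentences = vapply(s$sentences, as.character, character(1)))
    })
  } else {
    lines <- readLines(path, warn = FALSE)
    sections <- list(); cur <- NULL
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln)) next
      m <- regmatches(ln, regexec("^==\\s*(.+?)\\s*==$", ln))[[1]]
      if (length(m) == 2L) {
        if (!is.null(cur)) sections[[length(sections) + 1L]] <- cur
        cur <- list(header = m[2], sentences = character())
      } else {
        if (is.null(cur)) stop("line ", i, " of '", path,
                               "' precedes the first '== header ==' marker",
                               call. = FALSE)
        cur$sentences <- c(cur$sentences, ln)
      }
    }
    if (!is.null(cur)) sections[[length(sections) + 1L]] <- cur
    if (!length(sections)) stop("no sections found in '", path, "'",
                                call. = FALSE)
    is_abs <- grepl("abstract", normalize_header(sections[[1]]$header))
    if (!is_abs) stop("plaintext dialect requires the first section to be ",
                      "the abstract; got header '", sections[[1]]$header, "'",
                      call. = FALSE)
    abstract <- sections[[1]]$sentences
    sections <- sections[-1]
    doc_id <- tools::file_path_sans_ext(basename(path))
  }
  if (!length(abstract)) {
    stop("document '", path, "' has no abstract; the abstract is required ",
         "as the reference summary", call. = FALSE)
  }
  sentences <- list(); pos <- 0L
  for (sec in sections) {
    cls <- classify_section_header(sec$header, mapping)
    for (txt in sec$sentences) {
      pos <- pos + 1L
      sentences[[pos]] <- new_sentence(pos, txt, sec$header, cls)
    }
  }
  if (!length(sentences)) stop("document '", path, "' has no body sentences",
                               call. = FALSE)
  new_structured_document(doc_id, sentences, abstract)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Naive rule-based sentence splitter
#'
#' Convenience only: splits raw text at sentence-final punctuation followed
#' by whitespace and an uppercase letter or digit. Structured input is
#' expected to arrive pre-split.
#'
#' @param text A character string of running text.
#' @return Character vector of sentences.
#' @export
split_sentences <- function(text) {
  out <- strsplit(text, "(?<=[.!?])\\s+(?=[A-Z0-9])", perl = TRUE)[[1]]
  trimws(out[nzchar(trimws(out))])
}

#' Parse a per-sentence concept annotation file
#'
#' One record per line, tab-separated: sentence index, concept id, preferred
#' name, semicolon-joined semantic types, pipe-joined hypernym path (both of
#' the last two may be empty). Duplicate identical records are kept — they
#' encode occurrence frequency. The format is intended as a trivial
#' post-processing target for MetaMap output, keeping the external annotator
#' external.
#'
#' @param path Path to the TSV annotation file.
#' @param document Optional `structured_document`; when supplied, records
#'   referencing a sentence position outside the document raise an error.
#' @return A list mapping sentence position (as list index) to a list of
#'   `concept_annotation` objects. When `document` is given the list has one
#'   element per sentence; otherwise it extends to the largest index seen.
#' @export
parse_annotation_file <- function(path, document = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  n <- if (!is.null(document)) doc_length(document) else 0L
  recs <- vector("list", n)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("annotation record on line ", i,
                             " has fewer than 2 fields", call. = FALSE)
    idx <- suppressWarnings(as.integer(f[1]))
    if (is.na(idx) || idx < 1L) stop("bad sentence index '", f[1],
                                     "' on line ", i, call. = FALSE)
    if (!is.null(document) && idx > n) {
      stop("annotation on line ", i, " references sentence ", idx,
           " but the document has only ", n, " sentences", call. = FALSE)
    }
    sty <- if (length(f) >= 4L && nzchar(f[4])) {
      strsplit(f[4], ";", fixed = TRUE)[[1]]
    } else character()
    hyp <- if (length(f) >= 5L && nzchar(f[5])) {
      strsplit(f[5], "|", fixed = TRUE)[[1]]
    } else character()
    ann <- concept_annotation(f[2],
                              preferred_name = if (length(f) >= 3L &&
                                                   nzchar(f[3])) f[3] else f[2],
                              semantic_types = sty, hypernym_path = hyp)
    if (idx > length(recs)) recs[idx] <- list(NULL)
    recs[[idx]] <- c(recs[[idx]], list(ann))
  }
  lapply(recs, function(x) if (is.null(x)) list() else x)
}

#' Serialize per-sentence annotations to the TSV annotation format
#'
#' Inverse of [parse_annotation_file()]; parse-serialize-parse is a fixed
#' point.
#'
#' @param annotations List (by sentence position) of lists of
#'   `concept_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_file <- function(annotations, path) {
  rows <- character()
  for (idx in seq_along(annotations)) {
    for (a in annotations[[idx]]) {
      rows <- c(rows, paste(idx, a$concept_id, a$preferred_name,
                            paste(a$semantic_types, collapse = ";"),
                            paste(a$hypernym_path, collapse = "|"),
                            sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Attach parsed annotations to a document
#'
#' @param document A `structured_document`.
#' @param annotations Result of [parse_annotation_file()] (or a compatible
#'   list, one element per sentence).
#' @return The document with each sentence's `annotations` field filled.
#' @export
attach_annotations <- function(document, annotations) {
  if (length(annotations) > doc_length(document)) {
    stop("annotation list is longer than the document (",
         length(annotations), " > ", doc_length(document), ")", call. = FALSE)
  }
  for (i in seq_along(annotations)) {
    document$sentences[[i]]$annotations <- annotations[[i]]
  }
  document
}

#' Dictionary-based concept annotator
#'
#' A UMLS-free annotation path for testing and self-contained use: each
#' lexicon surface form is matched case-insensitively in each sentence,
#' respecting token boundaries, and every matched span contributes one
#' annotation occurrence. Overlapping matches are resolved longest-first,
#' ties leftmost-first (so "liver regeneration" beats "liver" where both
#' apply).
#'
#' @param document A `structured_document`.
#' @param lexicon Named list: surface form -> `concept_annotation` template
#'   (the template is copied once per match).
#' @return The document with annotations filled from lexicon matches.
#' @export
dictionary_annotate <- function(document, lexicon) {
  stopifnot(length(lexicon) == 0L || all(nzchar(names(lexicon))))
  forms <- names(lexicon)[order(-nchar(names(lexicon)))]  # longest first
  for (i in seq_along(document$sentences)) {
    text <- document$sentences[[i]]$text
    taken <- rep(FALSE, nchar(text))
    hits <- list()
    for (form in forms) {
      pat <- paste0("(?<![A-Za-z0-9])", escape_regex(form), "(?![A-Za-z0-9])")
      m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1L) next
      len <- attr(m, "match.length")
      for (k in seq_along(m)) {
        span <- m[k]:(m[k] + len[k] - 1L)
        if (any(taken[span])) next
        taken[span] <- TRUE
        hits[[length(hits) + 1L]] <- list(start = m[k], ann = lexicon[[form]])
      }
    }
    ord <- order(vapply(hits, `[[`, numeric(1), "start"))
    document$sentences[[i]]$annotations <- lapply(hits[ord], `[[`, "ann")
  }
  document
}

escape_regex <- function(x) gsub("([^A-Za-z0-9 ])", "\\\\\\1", x)

#' Semantic types excluded by default
#'
#' Nine overly general UMLS semantic types whose concepts are discarded
#' before graph construction and concept counting, because they are too
#' broad to contribute to summarization.
#'
#' @return Character vector of the nine type names.
#' @export
excluded_semantic_types <- function() {
  c("Quantitative concept", "Qualitative concept", "Temporal concept",
    "Functional concept", "Idea or concept", "Intellectual product",
    "Mental process", "Spatial concept", "Language")
}

#' Filter annotations by semantic type
#'
#' Drops annotations any of whose semantic types appear in the exclusion
#' set; order of the survivors is preserved. With an empty exclusion set
#' this is the identity.
#'
#' @param annotations List of `concept_annotation`.
#' @param excluded Character vector of semantic-type names to exclude;
#'   defaults to [excluded_semantic_types()].
#' @return Filtered list of annotations.
#' @export
filter_semantic_types <- function(annotations,
                                  excluded = excluded_semantic_types()) {
  keep <- vapply(annotations, function(a) {
    !any(a$semantic_types %in% excluded)
  }, logical(1))
  annotations[keep]
}

#' Apply the semantic-type filter to every sentence of a document
#'
#' @param document An annotated `structured_document`.
#' @param excluded Semantic types to exclude.
#' @return The document with filtered annotations.
#' @export
filter_document_annotations <- function(document,
                                        excluded = excluded_semantic_types()) {
  for (i in seq_along(document$sentences)) {
    document$sentences[[i]]$annotations <-
      filter_semantic_types(document$sentences[[i]]$annotations, excluded)
  }
  document
}
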