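# Independent brute-force oracles. These deliberately share no code with
# the package: counting is done by explicit enumeration so that agreement
# is evidence, not tautology.

oracle_tokens <- function(sents) {
  lapply(sents, function(s) {
    t <- unlist(strsplit(tolower(s), "[^a-z0-9]+"))
    t[nzchar(t)]
  })
}

# multiset of units as a plain character vector (duplicates kept)
oracle_bigram_list <- function(sents) {
  out <- character()
  for (t in oracle_tokens(sents)) {
    if (length(t) >= 2) {
      for (i in 1:(length(t) - 1)) out <- c(out, paste(t[i], t[i + 1]))
    }
  }
  out
}

oracle_su4_list <- function(sents) {
  out <- character()
  for (t in oracle_tokens(sents)) {
    out <- c(out, t)  # unigrams
    n <- length(t)
    if (n >= 2) {
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          if (j - i - 1 <= 4) out <- c(out, paste(t[i], t[j]))
        }
      }
    }
  }
  out
}

# clipped recall by explicit per-unit matching
oracle_clipped_recall <- function(peer_units, ref_units) {
  if (!length(ref_units)) return(0)
  avail <- peer_units
  hit <- 0
  for (u in ref_units) {
    k <- match(u, avail)
    if (!is.na(k)) {
      hit <- hit + 1
      avail <- avail[-k]
    }
  }
  hit / length(ref_units)
}

oracle_rouge2 <- function(peer, ref) {
  oracle_clipped_recall(oracle_bigram_list(peer), oracle_bigram_list(ref))
}

oracle_rouge_su4 <- function(peer, ref) {
  oracle_clipped_recall(oracle_su4_list(peer), oracle_su4_list(ref))
}

# salience by scanning the edge list one edge at a time
oracle_salience <- function(graph) {
  es <- igraph::as_data_frame(graph, what = "edges")
  s <- stats::setNames(rep(0, igraph::vcount(graph)),
                       igraph::V(graph)$name)
  for (i in seq_len(nrow(es))) {
    s[es$from[i]] <- s[es$from[i]] + es$weight[i]
    s[es$to[i]] <- s[es$to[i]] + es$weight[i]
  }
  s
}

# votes by explicit per-vertex case analysis
oracle_votes <- function(verts, cluster) {
  total <- 0
  for (v in unique(verts)) {
    if (v %in% cluster$hvs) total <- total + 1
    else if (v %in% cluster$members) total <- total + 0.5
  }
  total
}

oracle_sem_sim <- function(verts, partition) {
  total <- 0
  for (cl in partition) total <- total + oracle_votes(verts, cl) /
      length(cl$members)
  total
}

# connection weight of v to a member set, by edge scan
oracle_connection <- function(graph, v, members) {
  es <- igraph::as_data_frame(graph, what = "edges")
  w <- 0
  for (i in seq_len(nrow(es))) {
    if ((es$from[i] == v && es$to[i] %in% members) ||
        (es$to[i] == v && es$from[i] %in% members)) w <- w + es$weight[i]
  }
  w
}

# a partition is a valid fixed point if every non-hub vertex sits in the
# lowest-index cluster whose connection weight is maximal, given everyone
# else's current seat
oracle_assignment_stable <- function(graph, partition) {
  hubs <- unlist(lapply(partition, `[[`, "hvs"))
  for (ci in seq_along(partition)) {
    for (v in setdiff(partition[[ci]]$members, hubs)) {
      w <- vapply(seq_along(partition), function(k) {
        oracle_connection(graph, v, setdiff(partition[[k]]$members, v))
      }, numeric(1))
      if (ci != which(w == max(w))[1]) return(FALSE)
    }
  }
  TRUE
}

# random weighted concept-style graph with named vertices
random_toy_graph <- function(n, p = 0.3) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g), 0.1, 1), 3)
    igraph::E(g)$kind <- "metathesaurus_related"
  }
  g
}

# random hierarchy: a forest of chains under a handful of roots
random_hierarchy_paths <- function(n_paths, max_depth = 5) {
  lapply(seq_len(n_paths), function(i) {
    d <- sample(2:max_depth, 1)
    root <- sprintf("R%d", sample(1:2, 1))
    c(root, sprintf("p%d_%d", i, seq_len(d - 1)))
  })
}

random_words <- function(n, vocab = 12) {
  sample(sprintf("w%d", seq_len(vocab)), n, replace = TRUE)
}

random_sentence_text <- function(n_tokens) {
  paste(random_words(n_tokens), collapse = " ")
}

tmp_json_doc <- function(sections, abstract = c("An abstract sentence."),
                         doc_id = "tmp") {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(doc_id = doc_id, abstract = abstract,
                            sections = sections),
                       path, auto_unbox = TRUE)
  path
}
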