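# Concept-hierarchy interface, weighted document concept graph, degree-based
# hub-vertex-set clustering, and vote-based sentence-cluster similarity.

#' Read a concept hierarchy from TSV
#'
#' The hierarchy stands in for a controlled vocabulary such as the UMLS: a
#' forest of `is_a` (hypernym) edges plus flat "related" edges of two kinds,
#' mirroring Metathesaurus concept-level relations and Semantic-Network
#' type-level relations. Format: three tab-separated columns `a`, `b`,
#' `kind`; for `kind == "is_a"`, `a` is the child and `b` the parent; the
#' other kinds (`metathesaurus_related`, `semantic_network_related`) are
#' symmetric.
#'
#' @param path Path to the TSV file (a header line is required).
#' @return An object of class `concept_hierarchy`.
#' @export
read_concept_hierarchy <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("a", "b", "kind") %in% names(tab)))
  concept_hierarchy(is_a = tab[tab$kind == "is_a", c("a", "b")],
                    related = tab[tab$kind != "is_a", ])
}

#' Construct a concept hierarchy in memory
#'
#' @param is_a Data frame with columns `a` (child) and `b` (parent).
#' @param related Data frame with columns `a`, `b`, `kind`; kinds other than
#'   `is_a`.
#' @return An object of class `concept_hierarchy`.
#' @export
concept_hierarchy <- function(is_a = data.frame(a = character(),
                                                b = character()),
                              related = data.frame(a = character(),
                                                   b = character(),
                                                   kind = character())) {
  is_a <- as.data.frame(is_a, stringsAsFactors = FALSE)
  related <- as.data.frame(related, stringsAsFactors = FALSE)
  allowed <- c("metathesaurus_related", "semantic_network_related")
  bad <- setdiff(unique(related$kind), allowed)
  if (length(bad)) stop("unknown relation kind: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(is_a$a)) {
    stop("a concept may have at most one is_a parent in this hierarchy",
         call. = FALSE)
  }
  parent <- stats::setNames(is_a$b, is_a$a)
  # cycle check: walking up from any child must terminate
  for (child in names(parent)) {
    seen <- child; v <- child
    while (v %in% names(parent)) {
      v <- unname(parent[v])
      if (v %in% seen) stop("is_a cycle involving '", v, "'", call. = FALSE)
      seen <- c(seen, v)
    }
  }
  roots <- setdiff(unique(c(is_a$b, is_a$a)), is_a$a)
  structure(list(is_a = is_a, related = related, parent = parent,
                 roots = roots),
            class = "concept_hierarchy")
}

#' Root-to-concept hypernym path
#'
#' @param hierarchy A `concept_hierarchy`.
#' @param concept_id Concept identifier known to the hierarchy.
#' @return Character vector from the hierarchy root down to `concept_id`.
#' @export
hypernym_path <- function(hierarchy, concept_id) {
  known <- unique(c(hierarchy$is_a$a, hierarchy$is_a$b))
  if (!concept_id %in% known) {
    stop("concept '", concept_id, "' is not in the hierarchy", call. = FALSE)
  }
  path <- concept_id; v <- concept_id
  while (v %in% names(hierarchy$parent)) {
    v <- unname(hierarchy$parent[v])
    path <- c(v, path)
  }
  path
}

empty_concept_graph <- function() {
  igraph::make_empty_graph(n = 0, directed = FALSE)
}

#' Build the concept graph of a single sentence
#'
#' The hypernym paths of all the sentence's concepts are merged (set union
#' of vertices and consecutive-pair `is_a` edges). The top `pruning_levels`
#' of each path are removed first, because the upper levels of a concept
#' hierarchy carry excessively broad meanings; a concept whose whole path
#' would be pruned away keeps at least itself. Vertex depth is measured
#' after pruning, starting at 1, and a vertex reachable at several depths
#' keeps the smallest.
#'
#' @param sentence A `sentence` (with annotations).
#' @param hierarchy A `concept_hierarchy`; used to resolve annotations that
#'   carry no hypernym path of their own.
#' @param pruning_levels Number of top hierarchy levels to remove
#'   (default 2).
#' @return An undirected `igraph` with vertex attribute `depth` and edge
#'   attributes `kind` and `weight` (is_a weight = depth(parent)/depth(child)).
#' @export
build_sentence_graph <- function(sentence, hierarchy, pruning_levels = 2L) {
  anns <- sentence$annotations
  if (!length(anns)) return(empty_concept_graph())
  depth <- c(); efrom <- c(); eto <- c()
  for (a in anns) {
    path <- a$hypernym_path
    if (!length(path)) {
      path <- tryCatch(hypernym_path(hierarchy, a$concept_id),
                       error = function(e) {
                         stop("concept '", a$concept_id,
                              "' has no hypernym path and is absent from ",
                              "the hierarchy", call. = FALSE)
                       })
    }
    keep <- max(1L, length(path) - pruning_levels)
    path <- path[(length(path) - keep + 1L):length(path)]
    for (d in seq_along(path)) {
      v <- path[d]
      if (is.null(depth[v]) || is.na(depth[v])) depth[v] <- d
      else depth[v] <- min(depth[v], d)
    }
    if (length(path) > 1L) {
      efrom <- c(efrom, path[-length(path)])
      eto <- c(eto, path[-1])
    }
  }
  vdf <- data.frame(name = names(depth), depth = as.numeric(depth),
                    stringsAsFactors = FALSE)
  if (length(efrom)) {
    edges <- unique(data.frame(from = efrom, to = eto,
                               stringsAsFactors = FALSE))
    edges$kind <- "is_a"
    edges$weight <- unname(depth[edges$from] / depth[edges$to])
  } else {
    edges <- data.frame(from = character(), to = character(),
                        kind = character(), weight = numeric())
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vdf)
}

#' Merge sentence graphs into the document concept graph
#'
#' Vertex and edge sets are unioned (set union: a duplicated edge keeps a
#' single copy with the maximum weight; a vertex reached at several depths
#' keeps the smallest). The merged graph is then extended with the
#' hierarchy's flat relations — Metathesaurus-style concept relations and
#' Semantic-Network-style type relations — between concept pairs that are
#' both present, each such edge carrying weight 1, while `is_a` edges keep
#' the depth-ratio weight depth(parent)/depth(child).
#'
#' @param sentence_graphs List of graphs from [build_sentence_graph()].
#' @param hierarchy A `concept_hierarchy` supplying the flat relations.
#' @return An undirected weighted `igraph` (the document graph).
#' @export
build_document_graph <- function(sentence_graphs, hierarchy = NULL) {
  sentence_graphs <- Filter(function(g) igraph::vcount(g) > 0,
                            sentence_graphs)
  if (!length(sentence_graphs)) {
    stop("document has no concepts: all sentence graphs are empty",
         call. = FALSE)
  }
  vs <- do.call(rbind, lapply(sentence_graphs, function(g) {
    igraph::as_data_frame(g, what = "vertices")
  }))
  vdf <- stats::aggregate(depth ~ name, data = vs, FUN = min)
  es <- do.call(rbind, lapply(sentence_graphs, function(g) {
    igraph::as_data_frame(g, what = "edges")
  }))
  if (!is.null(hierarchy) && nrow(hierarchy$related)) {
    rel <- hierarchy$related
    present <- rel$a %in% vdf$name & rel$b %in% vdf$name
    rel <- rel[present, , drop = FALSE]
    if (nrow(rel)) {
      es <- rbind(es, data.frame(from = rel$a, to = rel$b, kind = rel$kind,
                                 weight = 1, stringsAsFactors = FALSE))
    }
  }
  if (is.null(es) || !nrow(es)) {
    return(igraph::graph_from_data_frame(
      data.frame(from = character(), to = character(), kind = character(),
                 weight = numeric()), directed = FALSE, vertices = vdf))
  }
  es <- es[es$from != es$to, , drop = FALSE]  # no self-loops
  key <- paste(pmin(es$from, es$to), pmax(es$from, es$to), es$kind,
               sep = "\r")
  keep <- !duplicated(key)
  dedup <- es[keep, , drop = FALSE]
  dedup$weight <- vapply(key[keep], function(k) max(es$weight[key == k]),
                         numeric(1), USE.NAMES = FALSE)
  igraph::graph_from_data_frame(dedup, directed = FALSE, vertices = vdf)
}

#' Vertex salience
#'
#' The salience of a vertex is the sum of the weights of its incident
#' edges (weighted degree).
#'
#' @param graph A document or sentence concept graph.
#' @param v Optional vertex name(s); default all vertices.
#' @return Named numeric vector of saliences.
#' @export
vertex_salience <- function(graph, v = NULL) {
  if (igraph::ecount(graph) > 0) {
    s <- igraph::strength(graph, weights = igraph::E(graph)$weight)
  } else {
    s <- stats::setNames(rep(0, igraph::vcount(graph)),
                         igraph::V(graph)$name)
  }
  if (is.null(v)) return(s)
  if (!all(v %in% names(s))) {
    stop("unknown vertex: ", paste(setdiff(v, names(s)), collapse = ", "),
         call. = FALSE)
  }
  s[v]
}

#' Cluster the document graph around hub vertex sets
#'
#' Degree-based topic clustering: (1) vertices are ranked by salience, ties
#' broken lexicographically by concept id; (2) the top
#' `ceiling(hub_fraction * |V|)` vertices become hub vertices; (3) the
#' connected components of the hub-induced subgraph form the hub vertex
#' sets (HVS), the centroids of the clusters; (4) every remaining vertex is
#' iteratively assigned to the cluster to which its total edge weight is
#' greatest (sweeps in descending salience, ties to the lowest cluster
#' index) until the assignment is stable, with a cap of 100 sweeps.
#'
#' @param graph A non-empty document graph.
#' @param hub_fraction Fraction of vertices labelled hubs, in (0, 1];
#'   default 0.2.
#' @return An object of class `cluster_partition`: a list of clusters, each
#'   with `members` and `hvs` (character vectors of concept ids).
#' @export
cluster_hvs <- function(graph, hub_fraction = 0.2) {
  nv <- igraph::vcount(graph)
  if (nv == 0L) stop("cannot cluster an empty graph", call. = FALSE)
  stopifnot(hub_fraction > 0, hub_fraction <= 1)
  sal <- vertex_salience(graph)
  ranking <- names(sal)[order(-sal, names(sal))]
  n_hub <- min(nv, ceiling(hub_fraction * nv))
  hubs <- ranking[seq_len(n_hub)]
  sub <- igraph::induced_subgraph(graph, hubs)
  comp <- igraph::components(sub)
  hvs_list <- split(igraph::V(sub)$name, comp$membership)
  # deterministic cluster order: by rank of each HVS's most salient member
  first_rank <- vapply(hvs_list, function(m) min(match(m, ranking)),
                       numeric(1))
  hvs_list <- unname(hvs_list[order(first_rank)])

  non_hubs <- setdiff(ranking, hubs)  # already in descending salience
  assign <- stats::setNames(rep(NA_integer_, length(non_hubs)), non_hubs)
  adj <- igraph::as_data_frame(graph, what = "edges")
  conn_to <- function(v, members) {
    sum(adj$weight[(adj$from == v & adj$to %in% members) |
                   (adj$to == v & adj$from %in% members)])
  }
  for (sweep in seq_len(100L)) {
    changed <- FALSE
    for (v in non_hubs) {
      members <- lapply(seq_along(hvs_list), function(i) {
        c(hvs_list[[i]], names(assign)[!is.na(assign) & assign == i &
                                         names(assign) != v])
      })
      w <- vapply(members, function(m) conn_to(v, m), numeric(1))
      best <- which(w == max(w))[1]  # ties -> lowest cluster index
      if (is.na(assign[v]) || assign[v] != best) {
        assign[v] <- best; changed <- TRUE
      }
    }
    if (!changed) break
  }
  clusters <- lapply(seq_along(hvs_list), function(i) {
    list(members = c(hvs_list[[i]], names(assign)[assign == i]),
         hvs = hvs_list[[i]])
  })
  structure(clusters, class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition: %d clusters>\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("  C%d (|C|=%d): HVS {%s}\n", i, length(x[[i]]$members),
                paste(x[[i]]$hvs, collapse = ", ")))
  }
  invisible(x)
}

#' Vote-based sentence-to-cluster similarity
#'
#' Non-democratic voting: each distinct concept vertex of the sentence
#' casts one full vote for a cluster if it belongs to the cluster's HVS,
#' half a vote if it belongs to the cluster but not to its HVS, and no vote
#' otherwise. A concept occurring twice in a sentence is still one vertex
#' and one vote.
#'
#' @param sentence_graph The sentence's concept graph (or a character
#'   vector of concept ids).
#' @param cluster One element of a `cluster_partition`.
#' @return Total votes (non-negative real).
#' @export
sentence_cluster_similarity <- function(sentence_graph, cluster) {
  verts <- if (is.character(sentence_graph)) unique(sentence_graph)
           else igraph::V(sentence_graph)$name
  sum(ifelse(verts %in% cluster$hvs, 1,
             ifelse(verts %in% cluster$members, 0.5, 0)))
}

#' Semantic similarity score of a sentence
#'
#' The sum over clusters of the sentence's vote similarity to the cluster,
#' adjusted by cluster size: sum_i similarity(C_i, S_j) / |C_i|.
#'
#' @param sentence_graph The sentence's concept graph (or a character
#'   vector of concept ids).
#' @param partition A `cluster_partition`.
#' @return Non-negative real score.
#' @export
sem_sim <- function(sentence_graph, partition) {
  stopifnot(inherits(partition, "cluster_partition"), length(partition) > 0)
  sum(vapply(partition, function(cl) {
    sentence_cluster_similarity(sentence_graph, cl) / length(cl$members)
  }, numeric(1)))
}

#' Export a concept graph as a TSV edge list
#'
#' Debug-friendly plain-text export: columns `from`, `to`, `kind`,
#' `weight`.
#'
#' @param graph A concept graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  es <- igraph::as_data_frame(graph, what = "edges")
  utils::write.table(es, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
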