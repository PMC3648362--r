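toy_hier <- function() {
  concept_hierarchy(
    is_a = data.frame(
      a = c("B", "C", "D", "E", "F"),
      b = c("A", "B", "C", "B", "E")),
    related = data.frame(a = "D", b = "F", kind = "metathesaurus_related"))
}

sent_with <- function(ids, hier = toy_hier()) {
  anns <- lapply(ids, function(id) {
    concept_annotation(id, hypernym_path = hypernym_path(hier, id))
  })
  new_sentence(1L, "t", "Results", "RESULTS_DISCUSSION", anns)
}

test_that("hierarchies reject cycles and resolve hypernym paths", {
  expect_equal(hypernym_path(toy_hier(), "D"), c("A", "B", "C", "D"))
  expect_equal(hypernym_path(toy_hier(), "A"), "A")
  expect_error(hypernym_path(toy_hier(), "Z"), "not in the hierarchy")
  expect_error(concept_hierarchy(is_a = data.frame(a = c("X", "Y"),
                                                   b = c("Y", "X"))),
               "cycle")
  expect_error(concept_hierarchy(related = data.frame(a = "X", b = "Y",
                                                      kind = "sibling")),
               "unknown relation kind")
})

test_that("a single concept's sentence graph is its hypernym path", {
  g <- build_sentence_graph(sent_with("C"), toy_hier(), pruning_levels = 0)
  expect_equal(sort(igraph::V(g)$name), c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)
  expect_true(all(igraph::E(g)$kind == "is_a"))
  # depth is measured from the (unpruned) root: A=1, B=2, C=3
  expect_equal(igraph::V(g)$depth[match(c("A", "B", "C"),
                                        igraph::V(g)$name)], c(1, 2, 3))
})

test_that("concepts sharing ancestry merge into one path union", {
  g <- build_sentence_graph(sent_with(c("C", "E")), toy_hier(),
                            pruning_levels = 0)
  # brute-force union of the two root-to-concept paths
  want <- unique(unlist(list(hypernym_path(toy_hier(), "C"),
                             hypernym_path(toy_hier(), "E"))))
  expect_equal(sort(igraph::V(g)$name), sort(want))
  expect_equal(igraph::ecount(g), length(want) - 1)  # tree: shared B once
})

test_that("pruning removes upper levels and rebases depth", {
  g <- build_sentence_graph(sent_with("D"), toy_hier(), pruning_levels = 2)
  expect_equal(sort(igraph::V(g)$name), c("C", "D"))
  expect_equal(igraph::V(g)$depth[igraph::V(g)$name == "C"], 1)
  # a concept shallower than the pruning depth keeps itself
  g2 <- build_sentence_graph(sent_with("B"), toy_hier(), pruning_levels = 5)
  expect_equal(igraph::V(g2)$name, "B")
  # unresolvable concept names the culprit
  bad <- new_sentence(1L, "t", "Results", "RESULTS_DISCUSSION",
                      list(concept_annotation("ZZ")))
  expect_error(build_sentence_graph(bad, toy_hier()), "ZZ")
})

test_that("document graph merge is a set union with flat relations added", {
  h <- toy_hier()
  g1 <- build_sentence_graph(sent_with("D"), h, pruning_levels = 0)
  # merging two identical sentence graphs changes nothing
  m <- build_document_graph(list(g1, g1), h)
  expect_equal(sort(igraph::V(m)$name), sort(igraph::V(g1)$name))
  expect_equal(igraph::ecount(m), igraph::ecount(g1))

  # a related edge appears (weight 1) once both endpoints are present
  g2 <- build_sentence_graph(sent_with("F"), h, pruning_levels = 0)
  dg <- build_document_graph(list(g1, g2), h)
  es <- igraph::as_data_frame(dg, what = "edges")
  rel <- es[es$kind == "metathesaurus_related", ]
  expect_equal(nrow(rel), 1)
  expect_equal(rel$weight, 1)
  expect_error(build_document_graph(list(), h), "no concepts")
})

test_that("is_a edge weights are depth ratios, in (0, 1)", {
  h <- toy_hier()
  dg <- build_document_graph(
    list(build_sentence_graph(sent_with(c("D", "F")), h,
                              pruning_levels = 0)), h)
  es <- igraph::as_data_frame(dg, what = "edges")
  vdepth <- stats::setNames(igraph::V(dg)$depth, igraph::V(dg)$name)
  isa <- es[es$kind == "is_a", ]
  for (i in seq_len(nrow(isa))) {
    dpair <- sort(c(vdepth[isa$from[i]], vdepth[isa$to[i]]))
    expect_equal(isa$weight[i], unname(dpair[1] / dpair[2]))
    expect_true(isa$weight[i] > 0 && isa$weight[i] < 1)
  }
  # depth-2 parent over depth-4 child
  expect_equal(unname(vdepth["B"] / vdepth["D"]), 0.5)
})

test_that("salience is the incident weight sum (handshake identity)", {
  g <- igraph::make_graph(~ a - b, a - c)
  igraph::E(g)$weight <- c(0.5, 1.0)
  igraph::E(g)$kind <- "is_a"
  expect_equal(unname(vertex_salience(g, "a")), 1.5)
  expect_error(vertex_salience(g, "zz"), "unknown vertex")
  set.seed(42)
  for (i in 1:25) {
    rg <- random_toy_graph(sample(3:20, 1))
    s <- vertex_salience(rg)
    expect_equal(s, oracle_salience(rg))
    expect_equal(sum(s), 2 * sum(igraph::E(rg)$weight))
  }
  # isolated vertex has salience 0
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "solo"
  expect_equal(unname(vertex_salience(iso, "solo")), 0)
})

test_that("hub-vertex clustering finds components and assigns the rest", {
  # two disconnected triangles -> two clusters matching the components
  g <- igraph::make_graph(~ a - b, b - c, a - c, x - y, y - z, x - z)
  igraph::E(g)$weight <- 1
  part <- cluster_hvs(g, hub_fraction = 0.67)  # >= 2 hubs per triangle
  expect_length(part, 2)
  mem <- lapply(part, function(cl) sort(cl$members))
  expect_setequal(unlist(mem), c("a", "b", "c", "x", "y", "z"))
  expect_true(setequal(mem[[1]], c("a", "b", "c")) ||
              setequal(mem[[1]], c("x", "y", "z")))

  # single vertex graph: one cluster whose HVS is the vertex
  solo <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(solo)$name <- "only"
  p1 <- cluster_hvs(solo, 0.5)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$hvs, "only")
  expect_error(cluster_hvs(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("cluster partitions cover all vertices disjointly and stably", {
  set.seed(99)
  for (i in 1:30) {
    g <- random_toy_graph(sample(5:25, 1))
    part <- cluster_hvs(g, hub_fraction = 0.3)
    members <- unlist(lapply(part, `[[`, "members"))
    expect_equal(sort(members), sort(igraph::V(g)$name))  # cover, disjoint
    expect_true(all(lengths(lapply(part, `[[`, "hvs")) > 0))
    expect_true(oracle_assignment_stable(g, part))
  }
})

test_that("clustering is invariant under vertex relabeling up to tie-break", {
  set.seed(5)
  g <- random_toy_graph(12)
  part <- cluster_hvs(g, 0.25)
  # relabel vertices with a reversed alphabet prefix that preserves
  # lexicographic order, so the documented tie-break is unchanged
  g2 <- g
  igraph::V(g2)$name <- paste0("X", igraph::V(g)$name)
  part2 <- cluster_hvs(g2, 0.25)
  expect_equal(lapply(part2, function(cl) sort(sub("^X", "", cl$members))),
               lapply(part, function(cl) sort(cl$members)))
})

test_that("vote similarity follows the non-democratic scheme", {
  cl <- list(members = c("a", "b", "c", "d"), hvs = c("a", "b"))
  expect_equal(sentence_cluster_similarity(c("a", "b"), cl), 2.0)
  expect_equal(sentence_cluster_similarity(c("c", "d"), cl), 1.0)
  expect_equal(sentence_cluster_similarity(c("q", "r"), cl), 0.0)
  expect_equal(sentence_cluster_similarity(c("a", "c", "q"), cl), 1.5)
  # one vertex = one vote even when the concept repeats
  expect_equal(sentence_cluster_similarity(c("a", "a"), cl), 1.0)
})

test_that("semantic similarity sums size-adjusted votes over clusters", {
  part <- structure(list(
    list(members = c("a", "b", "c", "d"), hvs = c("a", "b")),
    list(members = c("e", "f"), hvs = "e"),
    list(members = c("g"), hvs = "g")), class = "cluster_partition")
  expect_equal(sem_sim(c("a", "e", "g"), part), 1 / 4 + 1 / 2 + 1 / 1)
  expect_equal(sem_sim(character(), part), 0)
  # one cluster of size 4 with similarity 2 contributes 0.5
  p2 <- structure(list(list(members = c("a", "b", "c", "d"),
                            hvs = c("a", "b"))),
                  class = "cluster_partition")
  expect_equal(sem_sim(c("a", "b"), p2), 0.5)
  # random instances agree with the enumeration oracle; votes are bounded
  set.seed(17)
  for (i in 1:30) {
    g <- random_toy_graph(sample(5:20, 1))
    part <- cluster_hvs(g, 0.3)
    verts <- sample(igraph::V(g)$name, sample(1:5, 1))
    expect_equal(sem_sim(verts, part), oracle_sem_sim(verts, part))
    per_cl <- vapply(part, function(cl) {
      sentence_cluster_similarity(verts, cl)
    }, numeric(1))
    expect_true(all(per_cl <= length(unique(verts))))
    expect_lte(sum(per_cl), length(unique(verts)))
  }
})

test_that("graph export writes a readable edge list", {
  h <- toy_hier()
  dg <- build_document_graph(
    list(build_sentence_graph(sent_with(c("D", "F")), h, 0)), h)
  path <- tempfile(fileext = ".tsv")
  write_graph_edges(dg, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), igraph::ecount(dg))
  expect_true(all(c("from", "to", "kind", "weight") %in% names(tab)))
})
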