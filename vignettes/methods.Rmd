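---
title: "Concept-based summarization with positional strategies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept-based summarization with positional strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectsum)
```

## The problem

Extractive summarization of a scientific article selects whole sentences
whose content best covers what the author abstract covers. In biomedical
text, sentence relevance is better captured at the level of *concepts*
(controlled-vocabulary entries such as UMLS Metathesaurus concepts) than
surface words, and the position of a sentence matters differently than in
news: the informative sentences sit in the methods and results sections,
not at the document's ends. `sectsum` implements both ingredients — two
concept-based sentence scorers and three positional weighting strategies —
together with the ROUGE evaluation harness needed to compare them.

The package assumes its input is already structured: sentences are
pre-split and grouped under section headers, and each sentence carries
concept annotations (parsed from a MetaMap-style TSV, or produced by the
built-in dictionary annotator). Sentence segmentation and word-sense
disambiguation are upstream concerns; a naive splitter is provided only
as a convenience.

## Base scorers

**Concept frequency.** A sentence's vector counts its concept
occurrences; the document vector is the per-concept sum over sentences.
The CF score is their inner product, so a sentence is rewarded both for
containing many concepts and for containing *frequent* ones. The score is
bilinear in the counts and bounded below by the sentence's own
concept-occurrence total. Before counting, annotations of nine overly
general semantic types (quantitative/qualitative/temporal/functional
concepts, ideas, intellectual products, mental processes, spatial
concepts, language) are discarded — they are too broad to discriminate
topics. The same exclusion applies to both engines.

**Concept graph.** Each sentence's concepts are expanded to their full
hypernym (is_a) paths; the paths are merged into a sentence graph, and
sentence graphs into a document graph, as *set* unions — a duplicated
edge keeps one copy (at the maximum weight seen), and a vertex reachable
at two depths keeps the smaller depth. The upper levels of each path are
pruned before merging (default: 2 levels below the root) because the top
of a concept hierarchy is uninformatively broad; a concept whose whole
path would vanish keeps at least itself. The document graph is extended
with two kinds of flat relations between concept pairs already present —
Metathesaurus-style concept relations and Semantic-Network-style type
relations — supplied by the same hierarchy file. Edge weights are:

* is_a edge between parent at depth $d_p$ and child at depth $d_c$
  (depths measured after pruning, root = 1): $d_p / d_c \in (0, 1)$;
* any flat relation: 1.

Clustering then identifies topics. Salience of a vertex is its incident
weight sum. The top $\lceil h \cdot |V| \rceil$ vertices by salience
(ties broken lexicographically by concept id) become hub vertices; the
connected components of the hub-induced subgraph are the hub vertex sets
(HVS), which seed the clusters; every other vertex joins the cluster to
which its total edge weight is largest, sweeping in descending salience
until the assignment stabilizes (cap: 100 sweeps; each strict move
increases total intra-cluster weight and tie moves only decrease cluster
index, so the sweep terminates). A sentence's similarity to a cluster is
a non-democratic vote — 1 per distinct sentence vertex in the HVS, ½ per
vertex merely in the cluster — and its semantic score sums the
size-adjusted similarities over clusters.

Two parameters here are genuinely open and are therefore exposed:

* `hub_fraction` (default 0.2): the clustering literature this follows
  says only "the n most salient vertices"; a fifth of the vertices is a
  conventional centroid budget that keeps several distinct HVS
  components on desk-scale graphs.
* `pruning_levels` (default 2): "remove the upper levels" fixes no
  count; two levels removes the near-root strata in typical biomedical
  hierarchies (entity / broad-category) while preserving the
  discriminative middle.

A further reading choice: HVS formation is taken as *connected
components* of the hub subgraph — the minimal faithful reading of
"groups of strongly connected hub vertices". Variants that re-merge HVS
components by inter- vs intra-connectivity exist in the degree-based
clustering family but are not implemented; users clustering very dense
graphs should know the partition here can be finer than under those
variants.

## Positional strategies and combination

* `begin`: $1/m_j$ — news-style lead bias.
* `begin_end`: $\max(1/m_j,\ 1/(M - m_j + 1))$ — both ends favored; the
  score is symmetric under reversing the document.
* `section`: the weight of the sentence's section class, out of five
  classes (introduction, background, methods/materials,
  results/discussion, conclusions/future work) assigned by normalizing
  the header and looking it up in a shipped, user-extensible mapping
  table. Headers matching no rule map to OTHER, which scores a
  configurable `other_weight` defaulting to 0 — the weighted-indicator
  formula defines no term for unmapped sections, and 0 is the
  conservative reading. The mapping table is a best-effort
  reconstruction of common biomedical header variants; it cannot be
  exhaustive and is shipped as data precisely so users can extend it.

The default section weights (γ=0.2, δ=0, θ=1, σ=1, Π=0.1) are the
configuration that performs best for biomedical articles in the
literature this package operationalizes: full weight on
methods/materials and results/discussion, token weight on introduction
and conclusions, none on background. They are defaults, not constants —
every weight is settable programmatically and via the CLI.

Base scores are normalized to [0, 1] by dividing by the per-document
maximum. Divide-by-max is chosen over sum- or z-normalization because
selection only consumes the *ranking*, which max-scaling preserves; the
all-zero degenerate case (a document with no surviving concepts) maps to
all zeros rather than NaN. The combined score is
$\alpha \cdot \text{base} + \beta \cdot \text{position}$; with
`strategy = "none"` β is forced to 0, which reduces the ranking exactly
to the base engine's. Selection takes the top N (N = abstract length in
the evaluation protocol), breaking ties toward the earlier position —
deterministic, and consistent with position-favoring intuition — and
emits sentences in document order for readability.

## Evaluation

ROUGE-2 is clipped bigram-overlap recall against the reference; ROUGE-SU4
adds skip-bigrams with skip distance 4 — at most four intervening tokens,
the metric's standard reading, under which distance 0 degenerates to
ordinary bigrams — plus unigrams (the "U"), which give a
minimally-overlapping summary nonzero credit. Tokenization lowercases
and splits on non-alphanumerics; no stemming or stopword removal is
applied by default (light suffix stripping is available as an option).
N-gram units never cross sentence boundaries. Multiple references are
micro-averaged (summed clipped overlaps over summed reference counts);
the package's own protocol has a single reference — the author abstract —
so that path matters only for general use.

Significance between paired per-document recalls uses the Wilcoxon
signed-rank test, two-sided: exact for n ≤ 25 with no zero differences
and no tied magnitudes, otherwise a normal approximation with Pratt
handling of zeros (zeros are ranked and then dropped from the statistic)
and a tie-corrected variance. The Pratt branch is hand-implemented
because base R's `wilcox.test` discards zeros before ranking
(Wilcoxon's reduction), which biases paired comparisons of recall
vectors where exact ties are common. Identical vectors return p = 1 by
definition. At least 6 pairs are required.

`run_benchmark()` ties this together: each configuration is run over a
corpus at abstract length, mean ROUGE-2/ROUGE-SU4 are reported, and each
positional configuration is tested against the β = 0 baseline of the
same engine.

## The synthetic generator

`generate_synthetic_document()` emulates the features the summarizers
exploit, not the surface of real articles:

* a five-class section skeleton (one section of 8 sentences per class by
  default, M = 40 — large enough for positional structure, small enough
  that a full test suite runs in seconds);
* a shared *topical* concept pool (8 concepts) concentrated in the
  designated salient classes (methods/materials and results/discussion
  by default, mixing probability 0.7);
* a private *distractor* pool per non-salient class (8 concepts each, at
  0.6 of the topical concentration) — distractor topics are prominent
  but less focused, as related-work or background discussions are, and
  keeping the pools per-class prevents any one distractor topic from
  accumulating document frequency that the planted topic cannot match;
* Zipf-distributed prominence *within* each pool (heavy-tailed concept
  counts, as in real annotated text) over a flat background tail;
* an abstract built by copying the salient-class sentences richest in
  topical concepts (6 by default, a typical structured-abstract length),
  so ROUGE against the abstract directly measures whether selection
  found the planted content.

The seed fully determines the output. What the generator does *not*
emulate: real lexical variation between abstract and body (abstract
sentences are verbatim copies, so absolute ROUGE values are far higher
than on real articles and are meaningful only comparatively), annotator
noise and coverage gaps, section-length imbalance, and discourse
structure within sections. Passing desk-scale tests therefore shows the
pipeline's mechanics and the *direction* of the positional effects, not
absolute performance on real corpora — which additionally requires a
real concept vocabulary (e.g. the UMLS) and annotator (e.g. MetaMap),
both deliberately outside this package.

## Numerical and degenerate-input choices

* All tie-breaks are documented and deterministic: salience ranking by
  lexicographic concept id, cluster assignment to the lowest index,
  selection to the earlier position.
* Duplicate annotations encode frequency in the CF engine but collapse
  to one vertex (one vote) in the graph engine — votes are cast by graph
  vertices, not occurrences.
* Empty sentences score 0 in both engines; a document whose sentences
  are all unannotated is an error for the graph engine (no graph to
  build) and scores uniformly 0 under CF.
* `normalize_cf` maps an all-zero vector to itself; `rouge2` against a
  sub-bigram reference defines recall 0.
* Worked-example fixtures are exact integer computations; floating-point
  tolerances appear only in oracle-equivalence tests (1e-9) and in the
  cross-checked Wilcoxon p-values (1e-10).

## Test problem sizes

The suite exercises: the 5-sentence worked example (exact integer
checks); exhaustive positional symmetry up to M = 50; 100 random
hierarchies for the edge-weight law; 200 random graphs of up to 30
vertices for clustering/salience/voting oracle equivalence and 200
random texts of up to ~50 tokens for ROUGE oracle equivalence; 50
synthetic documents for the β = 0 reduction; and a 20-document corpus
for the directional section-weighting comparison. These sizes were
chosen so the full suite completes in well under a minute while leaving
each property with substantial random coverage.

## Known limitations

* The section-header mapping table is heuristic; unusual headers fall to
  OTHER (weight 0 by default), which silently removes those sentences
  from positional consideration under `section`.
* The dictionary annotator is longest-match and boundary-aware but has
  no disambiguation; it is a testing and fallback path, not a MetaMap
  replacement.
* The concept hierarchy interface supports a single is_a parent per
  concept (a forest); true DAG vocabularies must be spanning-tree'd
  upstream.
* ROUGE here is recall-only (the protocol fixes summary length to the
  abstract's, making recall the comparable quantity); no precision/F
  variants, and no ROUGE-1/L/W.
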