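# sectsum

Section-aware extractive summarization of biomedical articles, in R.

Scientific articles do not put their key content first: the opening
sentences motivate, the closing sentences speculate, and the substance sits
in the middle, inside the methods and results sections. `sectsum`
implements two concept-based extractive summarizers and three positional
sentence-weighting strategies so that this structure can be exploited — and
measured — when building summaries of structured biomedical full texts. It
is aimed at text-mining researchers and practitioners who need a
self-contained, testable summarization pipeline that works from
MetaMap-style concept annotations (or a built-in dictionary annotator)
without requiring a UMLS installation.

## The model

Every sentence S<sub>j</sub> (position m<sub>j</sub> of M, section class
c<sub>j</sub>) receives a **base score** from one of two engines, both
operating on concept annotations after nine overly general semantic types
are discarded:

* **Concept frequency (CF).** With document concept counts
  f<sub>i</sub>(d) and sentence counts f<sub>i</sub>(S<sub>j</sub>),

  CF(S<sub>j</sub>) = Σ<sub>i</sub> f<sub>i</sub>(S<sub>j</sub>) · f<sub>i</sub>(d),

  the inner product of the sentence and document concept vectors.

* **Concept graph.** Concept hypernym paths are merged (upper levels
  pruned) into a weighted document graph — is_a edges weighted
  depth(parent)/depth(child), flat Metathesaurus/Semantic-Network
  relations weighted 1. Vertices are ranked by salience (incident weight
  sum); the top fraction become hub vertices, whose connected components
  form hub vertex sets (HVS), the cluster centroids; remaining vertices
  join their best-connected cluster iteratively. A sentence scores by
  non-democratic voting — each of its vertices gives a cluster 1 vote if
  in the HVS, ½ if merely in the cluster — size-adjusted and summed:
  Sem_Sim(S<sub>j</sub>) = Σ<sub>i</sub> sim(C<sub>i</sub>, S<sub>j</sub>)/|C<sub>i</sub>|.

The base score (max-normalized to [0,1]) is blended with a **positional
score**:

* Begin-Pos: 1/m<sub>j</sub>
* Begin-End-Pos: max(1/m<sub>j</sub>, 1/(M − m<sub>j</sub> + 1))
* Section-Pos: the weight of the sentence's section class
  (γ introduction, δ background, θ methods/materials,
  σ results/discussion, Π conclusions/future work)

as Score(S<sub>j</sub>) = α·Base(S<sub>j</sub>) + β·Position(S<sub>j</sub>),
and the top-N sentences (N = abstract length, by the evaluation protocol)
are emitted in document order. Summaries are scored against the author
abstract with recall-oriented ROUGE-2 and ROUGE-SU4 (skip distance 4,
unigram credit), with paired Wilcoxon signed-rank tests across a corpus.

## Worked example

The shipped fixture is a five-sentence passage on the LRF-1/JunB/c-Jun/
c-Fos regulatory program in liver regeneration, annotated with 17 distinct
concepts:

```r
library(sectsum)
doc   <- load_worked_example()
svecs <- lapply(doc$sentences, sentence_vector)
dvec  <- document_vector(svecs)
dvec[c("LRF", "c-Jun", "c-fos", "Liver")]
#>   LRF c-Jun c-fos Liver
#>     7     3     3     3
vapply(svecs, cf_score, numeric(1), doc_vec = dvec)
#> [1] 18 26 31 10 13
```

Sentence 3 has the highest concept-frequency score (31), so the plain CF
summarizer picks it first:

```r
summarize_document(doc, engine = "frequency", strategy = "none", n = 1)
#> <summary_result: engine=frequency strategy=none, 1 sentences>
#>   [3] In liver cells, high levels of c-Fos/c-Jun, c-Fos/JunB, LRF-1/c-Jun, ...
```

A desk-scale benchmark on a 20-document synthetic corpus (topical concepts
planted in the methods and results sections) reproduces the directional
finding — section weighting helps, distance-to-the-ends hurts:

```r
docs <- generate_synthetic_corpus(20, synthetic_spec(seed = 101L))
tab <- run_benchmark(docs, list(
  list(label = "baseline",  strategy = "none",      weights = mixing_weights(1, 0)),
  list(label = "section",   strategy = "section",   weights = mixing_weights(0.8, 0.2)),
  list(label = "begin_end", strategy = "begin_end", weights = mixing_weights(0.75, 0.25))))
tab[, c("label", "mean_rouge2", "p_rouge2")]
#>       label mean_rouge2   p_rouge2
#> 1  baseline   0.6823218         NA
#> 2   section   0.6913496 0.31731051
#> 3 begin_end   0.6425780 0.01477253
```

(Absolute recalls on synthetic corpora reflect the generator's planted
abstracts; only the comparisons between configurations are meaningful.)

Command-line wrappers live in `inst/cli/`:
`summarize.R` (document + annotations → summary) and
`make-synthetic.R` (corpus generation).

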