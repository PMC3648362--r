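Package: sectsum
Title: Section-Aware Extractive Summarization of Biomedical Articles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extractive summarization of structured biomedical articles
    using two concept-based sentence scorers, one built on a weighted
    concept graph with degree-based hub-vertex clustering and one built
    on concept frequencies, each combinable with three positional
    sentence-weighting strategies (reciprocal position, distance to both
    document ends, and per-section-class weights). Includes parsers for
    structured documents and MetaMap-style concept annotations, a
    dictionary-based fallback annotator, a concept-hierarchy interface,
    recall-oriented ROUGE-2 and ROUGE-SU4 metrics, a paired Wilcoxon
    signed-rank test, a benchmarking harness, and a synthetic-document
    generator for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
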