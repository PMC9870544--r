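Package: microemo
Title: Lexicon-Based Fine-Grained Emotion Classification for Chinese Microblog Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies Chinese microblog (Weibo-style) posts into eight
    bidirectional emotion categories (good-disgust, joy-sadness, anger-fear,
    surprise-anticipation) plus neutral, using an affective lexicon with
    intensity scores, degree-adverb factors, negation handling, and
    position-weighted sentence aggregation. Includes preprocessing of raw
    crawled post tables, macro-averaged multiclass evaluation, corpus-level
    sentiment/emotion aggregation with official-versus-personal comparison and
    lead-lag diagnostics, LDA topic-number selection (perplexity elbow plus
    sliding-window coherence), and a synthetic-corpus generator with planted
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
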