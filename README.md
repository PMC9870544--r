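# microemo

Lexicon-based fine-grained emotion classification for Chinese microblog
(Weibo-style) posts, with the surrounding corpus analysis used in
infodemiology studies: preprocessing of raw crawled post tables,
macro-averaged evaluation, corpus-level sentiment/emotion aggregation with an
official-versus-personal account comparison, and LDA topic-number selection
for mining the concerns behind negative emotions.

## The method

Posts are labeled with one of **eight bidirectional emotion categories** —
four opposed pairs, good–disgust, joy–sadness, anger–fear,
surprise–anticipation — plus neutral. The scoring model:

1. **Sentence splitting with position weights.** A post is split on sentence
   separators. With *n* sentences, the first and last carry weight
   *w*₁ = *wₙ* = 2/(*n*+2) and interior sentences 1/(*n*+2); for *n* ≤ 2 each
   sentence gets 1/*n*. Weights always sum to 1.
2. **Emotion units.** Each lexicon hit (a word with category *j* and
   intensity *q*) is joined with its attached negation words (*m* of them)
   and degree modifiers with factors *c₁…cₗ*, scoring
   *eⱼ* = (−1)^*m* · ∏ᵥ *cᵥ* · *q*.
3. **Bidirectional conversion.** A negative score expresses the opposite
   category of the pair: (surprise, −3) becomes (anticipation, 3).
   Anticipation has no lexicon entries of its own and is reachable only this
   way.
4. **Aggregation and thresholding.** Converted unit scores are summed into a
   sentence vector *Eᵢ* ∈ ℝ⁸, post vector 𝔼 = Σ *wᵢEᵢ*, and the label is
   argmaxⱼ 𝔼ⱼ — or **neutral** when max 𝔼ⱼ < δ (default δ = 0.5). The four
   categories good/joy/surprise/anticipation roll up to positive sentiment,
   the other four to negative.

Around the classifier the package provides evaluation
(per-class precision/recall/F1, accuracy, macro averages), distribution
tables with a Pearson chi-square comparison of official and personal
accounts, zero-filled daily time series with a cross-correlation lead-lag
diagnostic, and LDA topic-number selection (perplexity elbow for an upper
bound, sliding-window NPMI coherence for the choice, Jensen–Shannon overlap
pairs as a merge diagnostic). A synthetic-corpus generator with planted gold
labels makes the whole pipeline testable end to end.

## Worked example

```r
library(microemo)

lex  <- load_lexicon(toy_lexicon_path("lexicon"))
mods <- load_modifiers(toy_lexicon_path("degree"), toy_lexicon_path("negation"))
clf  <- emotion_classifier(lex, mods, delta = 0.5)
predict(clf, c("今天非常高兴！", "天气一般。", "天空云朵，很不开心。书页风铃。"))
```

```
  good   joy sadness  score   label sentiment
1    0 12.25   0.000 12.250     joy  positive
2    0  0.00   0.000  0.000 neutral   neutral
3    0  0.00   4.375  4.375 sadness  negative
```

Post 1: one sentence, 高兴 (joy, *q* = 7) intensified by 非常 (*c* = 1.75)
gives 𝔼(joy) = 12.25. Post 2 has no lexicon hits and falls below δ, hence
neutral. Post 3: 开心 (joy, *q* = 5) negated by 不 and intensified by 很
scores −8.75, converts to sadness 8.75, and the sentence weight 1/2 gives
𝔼(sadness) = 4.375.

A full simulated pipeline run (simulate → preprocess → annotate → evaluate →
distribution → timeseries → topics):

```r
cfg <- run_config(output_dir = "demo_run", n_posts = 400, seed = 3, k_range = 1:4)
run_pipeline(cfg)
```

```
[microemo] simulate: 400 posts -> demo_run/corpus.csv
[microemo] preprocess: 400 cleaned posts -> demo_run/clean.jsonl
[microemo] annotate: 400 labeled posts -> demo_run/labels.jsonl
[microemo] evaluate: emotion acc 1.000, sentiment acc 1.000 -> demo_run/metrics.json
[microemo] distribution: n = 400 -> demo_run/distribution.json
[microemo] timeseries: 4 emotions -> demo_run/timeseries.csv
[microemo] topics: k_upper = 3, k_best = 1 -> demo_run/topics.json
```

On an unambiguous synthetic corpus the classifier recovers 100% of the
planted gold labels — a construction guarantee of the generator, exercised
as a regression test. The same subcommands are available from a shell via
`inst/cli/microemo.R`.

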