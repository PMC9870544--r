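---
title: "Lexicon-based microblog emotion classification: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexicon-based microblog emotion classification: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microemo)
```

## The model

`microemo` labels Chinese microblog posts with one of eight emotion
categories organised as four bidirectional pairs — good–disgust, joy–sadness,
anger–fear, surprise–anticipation — plus neutral. The method is entirely
lexicon-driven: no training data, no fitted weights. Its assumptions are
worth stating explicitly because they bound where the classifier is
trustworthy.

**Position-weighted sentences.** Microblog authors tend to open and close
with their point, so the first and last sentences of a post carry double
weight: with $n$ sentences, $w_1 = w_n = 2/(n+2)$ and $w_i = 1/(n+2)$ for
interior sentences; for $n \le 2$, $w_i = 1/n$. The weights always sum to 1,
so the post score is a convex combination of sentence scores and the neutral
threshold $\delta$ has the same meaning for short and long posts.

**Emotion units.** Each emotion word found in a sentence anchors a unit: the
word's category $j$ and intensity $q$ (DLUT-style odd integers 1–9), the
count $m$ of attached negation words, and the factors $c_1,\dots,c_l$ of
attached degree modifiers. The unit scores

$$ e_j = (-1)^m \prod_{v=1}^{l} c_v \, q, $$

and zero for every other category. The formula is order-free: "很不好" and
"不很好" score identically. That is a modelling simplification — in natural
Chinese these differ in strength — but the printed form of the score admits
no order term, and we do not add one.

**Bidirectional conversion.** An odd number of negations makes $e_j$
negative, which is read as the *opposite* emotion: the score moves to the
paired category with positive magnitude. Anticipation exists only through
this route (the seven-class lexicon has no anticipation entries), mirroring
the wheel-of-emotions view that negated surprise is anticipation. Conversion
is applied **per unit**, before any summation, so sentence vectors
$E_i \in \mathbb{R}^8_{\ge 0}$ are always nonnegative. Converting at the
sentence or post level instead would let opposite-category units cancel
before conversion; the per-unit choice keeps the vector space well defined
and is the one implemented (it is a design choice, not an assertion about
the original authors' intent).

**Thresholded argmax.** The post vector is
$\mathbb{E} = \sum_i w_i E_i$; the label is $\arg\max_j \mathbb{E}_j$,
or neutral when the maximum falls below $\delta$. Ties are broken in a fixed
category order (good, joy, surprise, anticipate, fear, disgust, sadness,
anger) purely for determinism; ties are measure-zero in real scoring and the
order has no semantic weight. Sentiment rolls up the four
good/joy/surprise/anticipate categories to positive and the rest to
negative.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.5 | neutral threshold on the winning post score. Unit-free in the score scale (intensity × factors × weight). The smallest non-zero post score with the packaged lexicon is 0.25 (q = 1, one 0.5 diminisher, weight 1/2); 0.5 keeps single weak diminished words neutral while any undiminished hit (q ≥ 1 at weight ≥ 1/4) can label a post. |
| `separators` | 。！？!?；; and newline | sentence enders. The half-width forms matter because microblog text mixes widths. |
| `window` | 3 tokens | fallback modifier attachment: the up-to-3 tokens immediately before the emotion word, not crossing a comma/enumeration-comma/colon/space boundary, each modifier consumed at most once. A dependency parser can replace the window via the `parser` argument; the window reproduces standard lexicon-method practice when no parser is available. |
| degree factors | most 2.0, very 1.75, more 1.5, ish 1.2, insufficiently 0.5, over 1.5 | six-level multiplicative table used when a degree file carries level labels; any numeric file overrides it. |
| tie order | fixed category order | determinism only. |

Scale equivariance is a useful sanity property: multiplying all intensities
by $\lambda > 0$ multiplies $\mathbb{E}$ by $\lambda$ and leaves labels
unchanged when $\delta$ is rescaled; the tests assert it.

## Preprocessing choices

Stopwords are stripped **only** on the topic-mining path. Chinese stopword
lists contain 不, 没有, 很 — exactly the negations and degree adverbs the
scorer needs — so removing them before emotion scoring would silently break
negation handling. Topic markers are removed only as paired `#…#` spans; an
unpaired `#` is ordinary text. User typing (official vs personal) is a
keyword rule over the publisher name after case and character-width
normalization; the packaged keyword list is an editable stand-in, since no
authoritative list exists, and posts whose type cannot be determined are
excluded from group comparisons but kept in overall distributions.

## Evaluation and aggregation

Metrics are the standard confusion-matrix quantities; macro averages are
unweighted arithmetic means across classes, and classes with a zero
denominator score 0 with a warning rather than NaN. Display rounding is
half-away-from-zero at 2 decimals; full precision is kept internally.
Distribution tables report emotion percentages at 2 decimals and group
sentiment rollups at 1, matching the mixed precision conventional in
published tables; percentages are always computed from the actual column
sums of the counts supplied. The official/personal comparison is Pearson's
chi-square on the 2×3 group-by-sentiment table without continuity
correction; columns that are entirely zero are dropped before testing, and a
warning is attached when any expected count falls below 1.

The lead-lag diagnostic formalizes "official peaks precede personal peaks":
it scans lags in $[-L, L]$ for the Pearson-correlation maximum between the
two daily series, breaking ties toward the smaller |lag|. It needs sharp
shared structure to be identifiable — a perfectly smooth unimodal series
correlates almost equally at neighbouring lags, which is why the synthetic
generator gives its daily volume profile day-level event multipliers (see
below).

## Topic-number selection

LDA is fitted by a compiled collapsed Gibbs sampler (symmetric priors,
$\alpha = 50/k$, $\beta = 0.1$, 200 sweeps, seed-deterministic). The
selection procedure, which is the point, runs in three steps:

1. **Perplexity elbow.** Training perplexity decreases in $k$ almost
   monotonically, so its minimum is useless; the "turn" is operationalized
   as the $k$ with the maximal positive second-order forward difference.
   A curve with no positive second difference has no elbow and the maximum
   candidate is returned with a warning. Training (held-in) perplexity is
   used and labeled as such.
2. **Coherence maximum.** Among $k \le k_{\text{upper}}$, the $k$ maximizing
   sliding-window NPMI coherence (window 10, top 10 words per topic), ties
   to the smaller $k$. This is the boolean-sliding-window family of
   coherence measures; the full four-stage c_v pipeline adds context-vector
   cosines on top of the same co-occurrence statistics and was not needed
   for the selection to be stable on planted corpora.
3. **Overlap diagnostic.** Pairs of topics whose word distributions lie
   within Jensen–Shannon distance 0.25 (base-2 logs, so the distance lives
   in [0, 1]) are reported as merge candidates — a reproducible replacement
   for judging overlap on an interactive intertopic projection; a static
   MDS plot of the same distances is still emitted for inspection.

On planted corpora with disjoint topic vocabularies the selected $k$ equals
the planted number (±1) in essentially every seeded run; the acceptance
suite checks ≥ 80% over 60 runs. One caveat learned from those experiments:
LDA *splits* duplicated topics across disjoint word subsets rather than
fitting two identical distributions, so the overlap diagnostic is exercised
with constructed near-duplicate distributions, which is also the situation
it is meant to flag in practice.

## The synthetic generator: what it does and does not show

The generator emulates the *shape* of a crawled corpus, not its language:
template fragments over a filler vocabulary deliberately disjoint from the
lexicon, one seeded emotion unit per non-neutral post whose net category
equals the gold label (a gold-category word, or a negated opposite-category
word; anticipation always the latter), intensifiers injected at rate 0.3 and
negations at rate 0.2, seeded intensities ≥ 5 placed in a first/last
sentence so every non-neutral post clears $\delta$ by construction. The
default emotion mixture is the bundled benchmark distribution (about 51%
positive, 25% neutral, 24% negative); the default official share is 0.2;
dates span July–August 2022 with a smooth epidemic wave modulated by
day-level event multipliers (log-normal, $\sigma = 0.6$) so that volume
spikes — the feature the lead-lag diagnostic keys on — exist, and personal
posts echo the official profile `lead_lag_days` later.

Because recovery is guaranteed by construction, a 100% gold-recovery test
validates the *plumbing* (tokenization, windows, conversion, weighting,
thresholds, I/O round-trips), not linguistic accuracy. Real microblog text
has sarcasm, emoji, internet slang, multi-clause scope ambiguity and words
outside any lexicon; nothing in the passing tests speaks to those, and
published accuracies of lexicon methods on hand-annotated posts (≈ 0.8)
should be taken as the realistic ceiling, not the synthetic 100%.

## Numerical and degenerate-input choices

Sentence weights are exact rationals summing to 1 (asserted to 1e-12).
Empty posts, and posts that are empty after cleaning, are neutral. An empty
lexicon file yields an empty lexicon with a warning; a word listed as both
degree adverb and negation is a configuration error (the scorer could not
decide whether it flips or scales). Polysemous lexicon rows keep the
maximum-intensity sense per (word, category) — deterministic and
conservative. Constant series make the lead-lag correlation undefined and
raise an error rather than returning an arbitrary lag. The greedy
longest-match tokenizer is deterministic and segmenter-free; a real
segmenter (jieba-style) can be plugged in, and with it the modifier window
semantics are unchanged.

## Problem sizes used in the checks

The bundled checks run at deliberately modest sizes chosen to make the
statistical assertions meaningful rather than large: gold recovery at
n = 500, mixture recovery at n = 5,000 (within 3 multinomial standard
errors per class), topic recovery over 60 seeded runs of ~120–200 document
corpora, lead-lag at n = 4,000 posts over a 62-day span.

## Known limitations

- The unit score is order-free in its modifiers and linear in intensity;
  degree words compose multiplicatively with no saturation.
- "Gerund"-like modifier words are treated as ordinary multiplicative
  modifiers; no separate grammatical analysis is attempted.
- The fallback window attaches only *preceding* modifiers; post-posed
  negation ("高兴不起来") is missed without a parser.
- Topic keywords are reported; naming or interpreting topics is human work.
- The official-user keyword list is a stand-in; real deployments should
  curate one and use the manual-override path.
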