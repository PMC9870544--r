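#' Perplexity and coherence curves over candidate topic numbers
#'
#' Fits one LDA model per k and records its training perplexity and
#' sliding-window NPMI coherence. Deterministic for a fixed `seed` (the seed
#' controls every fit).
#'
#' @param docs tokenized, stopword-stripped documents (list of character
#'   vectors).
#' @param k_range integer vector of candidate topic numbers (default 1:20).
#' @param seed RNG seed.
#' @param min_vocab minimum vocabulary size required (default 10).
#' @param ... passed to [lda_fit()] (alpha, beta, n_iter).
#' @return data.frame with columns `k`, `perplexity`, `coherence`.
#' @export
topic_curves <- function(docs, k_range = 1:20, seed = 1L, min_vocab = 10L,
                         ...) {
  vocab <- unique(unlist(docs))
  if (length(vocab) < min_vocab) {
    stop("vocabulary too small (", length(vocab), " < ", min_vocab, ")")
  }
  res <- lapply(k_range, function(k) {
    fit <- lda_fit(docs, k, seed = seed, ...)
    coh <- topic_coherence(fit, docs)
    c(perplexity = lda_perplexity(fit), coherence = coh$coherence)
  })
  data.frame(k = as.integer(k_range),
             perplexity = vapply(res, `[[`, numeric(1), "perplexity"),
             coherence = vapply(res, `[[`, numeric(1), "coherence"))
}

#' Elbow of a perplexity curve
#'
#' Operationalizes "the obvious turn" as the k with the maximal positive
#' second-order forward difference of the perplexity curve. A curve with no
#' positive second difference (flat or linear decrease) has no elbow: the
#' maximum k is returned with a warning.
#'
#' @param perplexity numeric curve (length >= 3), one value per k.
#' @param k_values the matching topic numbers (default `seq_along`).
#' @return The chosen upper bound k (integer).
#' @export
#' @examples
#' perplexity_elbow(c(100, 50, 48, 47, 46))  # 2
perplexity_elbow <- function(perplexity, k_values = seq_along(perplexity)) {
  stopifnot(length(perplexity) == length(k_values))
  if (length(perplexity) < 3L) stop("curve must have length >= 3")
  n <- length(perplexity)
  d2 <- perplexity[3:n] - 2 * perplexity[2:(n - 1)] + perplexity[1:(n - 2)]
  if (max(d2) <= 0) {
    warning("no turn in perplexity curve; returning the maximum k")
    return(as.integer(k_values[n]))
  }
  as.integer(k_values[which.max(d2) + 1L])
}

#' Pick the topic number by coherence under the elbow bound
#'
#' The argmax of coherence restricted to k <= `k_upper`; ties go to the
#' smaller k.
#'
#' @param coherence numeric coherence curve.
#' @param k_values matching topic numbers.
#' @param k_upper upper bound from [perplexity_elbow()].
#' @return The selected k (integer).
#' @export
select_k <- function(coherence, k_values = seq_along(coherence),
                     k_upper = max(k_values)) {
  stopifnot(length(coherence) == length(k_values))
  if (!k_upper %in% k_values && k_upper > max(k_values)) {
    k_upper <- max(k_values)
  }
  keep <- k_values <= k_upper
  if (!any(keep)) stop("k_upper below the candidate range")
  kv <- k_values[keep]
  cv <- coherence[keep]
  as.integer(kv[which.max(cv)])  # which.max takes the first (smaller k) on ties
}

#' Full topic-number selection pipeline
#'
#' Runs [topic_curves()], bounds k by the perplexity elbow, selects the
#' coherence maximum below the bound, refits at the chosen k and reports
#' overlapping topic pairs and per-topic keywords.
#'
#' @inheritParams topic_curves
#' @param overlap_threshold JS distance threshold for [topic_overlap()].
#' @param top_n keywords per topic in the report.
#' @return Object of class `topic_selection`: `curves`, `k_upper`, `k_best`,
#'   `model`, `overlap_pairs`, `keywords`.
#' @export
select_topics <- function(docs, k_range = 1:20, seed = 1L,
                          overlap_threshold = 0.25, top_n = 10L, ...) {
  curves <- topic_curves(docs, k_range, seed = seed, ...)
  k_upper <- perplexity_elbow(curves$perplexity, curves$k)
  k_best <- select_k(curves$coherence, curves$k, k_upper)
  model <- lda_fit(docs, k_best, seed = seed, ...)
  overlap <- if (k_best >= 2L) topic_overlap(model, overlap_threshold) else
    data.frame(topic_a = integer(), topic_b = integer(), distance = numeric())
  structure(list(curves = curves, k_upper = k_upper, k_best = k_best,
                 model = model, overlap_pairs = overlap,
                 keywords = topic_keywords(model, top_n), seed = seed),
            class = "topic_selection")
}

#' @export
print.topic_selection <- function(x, ...) {
  cat(sprintf("Topic-number selection over k = %d..%d\n",
              min(x$curves$k), max(x$curves$k)))
  cat(sprintf("  perplexity elbow (upper bound): k_upper = %d\n", x$k_upper))
  cat(sprintf("  coherence maximum below bound : k_best  = %d\n", x$k_best))
  if (nrow(x$overlap_pairs) > 0L) {
    cat("  overlapping topic pairs (merge candidates):\n")
    print(x$overlap_pairs, row.names = FALSE)
  } else {
    cat("  no overlapping topic pairs\n")
  }
  for (i in seq_along(x$keywords)) {
    cat(sprintf("  topic %d: %s\n", i,
                paste(x$keywords[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Tokenize cleaned posts for topic modelling
#'
#' Applies the topic-path cleaning (stopwords stripped) and greedy
#' segmentation against the supplied dictionary, dropping single-character
#' leftovers and empty documents' entries.
#'
#' @param texts character vector of post contents.
#' @param dictionary vocabulary for segmentation (e.g. lexicon + filler
#'   words); tokens not in it fall back to single characters, which are
#'   dropped.
#' @param stopwords stopword list applied before segmentation.
#' @return List of character token vectors (one per input text).
#' @export
tokenize_for_topics <- function(texts, dictionary,
                                stopwords = load_stopwords()) {
  cleaned <- clean_content(texts, stopwords, for_topics = TRUE)
  toks <- tokenize_greedy(cleaned, dictionary)
  lapply(toks, function(t) t[nchar(t) > 1L])
}
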