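#' Build a lexicon-based emotion classifier
#'
#' Bundles the emotion lexicon, modifier lexicon and scoring configuration
#' into a classifier object. Prediction splits each post into
#' position-weighted sentences, extracts emotion units (emotion word +
#' attached negations and degree modifiers), scores each unit as
#' \eqn{e_j = (-1)^m \prod c_v q}, converts negative scores onto the opposite
#' category of the bidirectional pair, sums into an 8-dimensional post vector,
#' and labels the post with the argmax category -- or neutral when the maximum
#' falls below the threshold `delta`.
#'
#' @param lexicon an `emotion_lexicon` from [load_lexicon()].
#' @param modifiers a `modifier_lexicon` from [load_modifiers()].
#' @param delta neutral threshold (> 0). A post whose strongest category
#'   scores below `delta` is neutral. Default 0.5.
#' @param separators sentence separators; see [default_separators()].
#' @param window fallback modifier-attachment window (tokens).
#' @param tie_order argmax tie-breaking order over categories.
#' @param parser optional parser adapter: function(sentence) -> list of
#'   list(word, modifiers). Used instead of the token window when supplied.
#' @param tokenizer tokenization backend; defaults to [tokenize_greedy()].
#' @return An object of class `emotion_classifier`.
#' @seealso [predict.emotion_classifier()]
#' @export
#' @examples
#' lex <- load_lexicon(toy_lexicon_path("lexicon"))
#' mods <- load_modifiers(toy_lexicon_path("degree"), toy_lexicon_path("negation"))
#' clf <- emotion_classifier(lex, mods)
#' predict(clf, c("今天非常高兴！", "天气一般。"))
emotion_classifier <- function(lexicon, modifiers, delta = 0.5,
                               separators = default_separators(),
                               window = 3L,
                               tie_order = emotion_categories(),
                               parser = NULL,
                               tokenizer = tokenize_greedy) {
  stopifnot(inherits(lexicon, "emotion_lexicon"),
            inherits(modifiers, "modifier_lexicon"),
            is.numeric(delta), delta > 0,
            setequal(tie_order, emotion_categories()))
  structure(list(
    lexicon = lexicon, modifiers = modifiers, delta = delta,
    separators = separators, window = as.integer(window),
    tie_order = tie_order, parser = parser, tokenizer = tokenizer
  ), class = "emotion_classifier")
}

#' Classify posts with an emotion classifier
#'
#' @param object an [emotion_classifier()].
#' @param newdata character vector of post texts, or a data.frame with a
#'   `content_clean` (preferred) or `content` column.
#' @param ... unused.
#' @return A data.frame with one row per post: the eight category scores,
#'   `score` (winning score), `label` and `sentiment`. Posts that are empty
#'   after cleaning are neutral.
#' @export
predict.emotion_classifier <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    col <- if ("content_clean" %in% names(newdata)) "content_clean" else "content"
    if (!col %in% names(newdata)) {
      stop("newdata must contain a content_clean or content column")
    }
    texts <- as.character(newdata[[col]])
  } else {
    texts <- as.character(newdata)
  }
  cats <- emotion_categories()
  scores <- matrix(0, nrow = length(texts), ncol = 8L,
                   dimnames = list(NULL, cats))
  label <- character(length(texts))
  sentiment <- character(length(texts))
  top <- numeric(length(texts))
  for (p in seq_along(texts)) {
    v <- post_emotion_vector(object, texts[p])
    cls <- classify_post(v, object$delta, object$tie_order)
    scores[p, ] <- v[cats]
    label[p] <- cls$label
    sentiment[p] <- cls$sentiment
    top[p] <- cls$score
  }
  out <- as.data.frame(scores)
  out$score <- top
  out$label <- label
  out$sentiment <- sentiment
  out
}

#' @rdname predict.emotion_classifier
#' @param text one post text.
#' @export
post_emotion_vector <- function(object, text) {
  spans <- split_sentences(text, object$separators)
  if (nrow(spans) == 0L) {
    return(stats::setNames(numeric(8L), emotion_categories()))
  }
  vecs <- lapply(spans$text, function(s) {
    sentence_vector(extract_units(s, object$lexicon, object$modifiers,
                                  parser = object$parser,
                                  window = object$window,
                                  tokenizer = object$tokenizer))
  })
  post_vector(spans$weight, vecs)
}

#' @export
print.emotion_classifier <- function(x, ...) {
  cat("Lexicon-based emotion classifier\n")
  cat(sprintf("  lexicon entries : %d (%d words)\n",
              nrow(x$lexicon), length(unique(x$lexicon$word))))
  cat(sprintf("  degree factors  : %d, negation words: %d\n",
              length(x$modifiers$degree_factors),
              length(x$modifiers$negation_words)))
  cat(sprintf("  neutral threshold delta = %g, window = %d, parser: %s\n",
              x$delta, x$window,
              if (is.null(x$parser)) "token window (fallback)" else "custom"))
  invisible(x)
}

#' @export
summary.emotion_classifier <- function(object, ...) {
  tab <- table(factor(object$lexicon$category, levels = emotion_categories()))
  cat("Lexicon coverage by category:\n")
  print(tab)
  cat(sprintf("\nIntensity range: [%g, %g]; delta = %g\n",
              min(object$lexicon$intensity), max(object$lexicon$intensity),
              object$delta))
  invisible(list(coverage = tab, delta = object$delta))
}
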