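#' The eight-category bidirectional emotion scheme
#'
#' The classifier uses eight emotion categories organised as four opposed
#' pairs: good-disgust, joy-sadness, anger-fear and surprise-anticipation.
#' Negating an emotion word flips its category to the paired opposite, so a
#' negated surprise word expresses anticipation (the only category with no
#' lexicon entries of its own in the seven-class DLUT-style ontology).
#'
#' `emotion_categories()` returns the categories in the fixed tie-breaking
#' order used throughout the package: ties in the post-level argmax are
#' resolved toward the earlier category in this order.
#'
#' @return Character vector of the eight category names, in tie order.
#' @export
#' @examples
#' emotion_categories()
#' opposite_category("joy")
#' category_sentiment(c("good", "fear"))
emotion_categories <- function() {
  c("good", "joy", "surprise", "anticipate",
    "fear", "disgust", "sadness", "anger")
}

.OPPOSITE <- c(
  good = "disgust", disgust = "good",
  joy = "sadness", sadness = "joy",
  anger = "fear", fear = "anger",
  surprise = "anticipate", anticipate = "surprise"
)

.SENTIMENT <- c(
  good = "positive", joy = "positive",
  surprise = "positive", anticipate = "positive",
  fear = "negative", disgust = "negative",
  sadness = "negative", anger = "negative"
)

#' @rdname emotion_categories
#' @param category character vector of category names.
#' @export
opposite_category <- function(category) {
  bad <- setdiff(category, names(.OPPOSITE))
  if (length(bad) > 0L) {
    stop("unknown emotion category: ", paste(bad, collapse = ", "))
  }
  unname(.OPPOSITE[category])
}

#' @rdname emotion_categories
#' @export
category_sentiment <- function(category) {
  out <- .SENTIMENT[category]
  out[category == "neutral"] <- "neutral"
  if (anyNA(out)) {
    stop("unknown emotion category: ",
         paste(category[is.na(out)], collapse = ", "))
  }
  unname(out)
}

#' All labels a post can receive (eight emotions plus neutral)
#' @return Character vector of length nine.
#' @export
emotion_labels <- function() c(emotion_categories(), "neutral")

#' The three sentiment labels
#' @return Character vector: positive, neutral, negative.
#' @export
sentiment_labels <- function() c("positive", "neutral", "negative")
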