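#' Split a post into position-weighted sentences
#'
#' Posts are split on the separator set (defaults: full/half-width sentence
#' enders plus newline and semicolon). The first and last sentences of a long
#' post carry more emotional weight: for n > 2 sentences the first and last
#' get weight 2/(n+2) and interior sentences 1/(n+2); for n <= 2 every
#' sentence gets 1/n. Weights always sum to 1.
#'
#' @param text a single string.
#' @param separators character vector of single-character separators.
#' @return A data.frame with columns `index`, `text`, `weight` (zero rows for
#'   empty input).
#' @export
#' @examples
#' split_sentences("今天很好。明天呢？")
split_sentences <- function(text, separators = default_separators()) {
  if (length(text) != 1L) stop("split_sentences() expects a single string")
  empty <- data.frame(index = integer(), text = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (is.na(text) || text == "") return(empty)
  cls <- paste0("[", paste(vapply(separators, regex_escape, ""), collapse = ""), "]")
  parts <- strsplit(text, cls, perl = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[parts != ""]
  n <- length(parts)
  if (n == 0L) return(empty)
  w <- sentence_weights(n)
  data.frame(index = seq_len(n), text = parts, weight = w,
             stringsAsFactors = FALSE)
}

#' @rdname split_sentences
#' @param n number of sentences.
#' @export
sentence_weights <- function(n) {
  if (n < 1L) return(numeric())
  if (n <= 2L) return(rep(1 / n, n))
  w <- rep(1 / (n + 2), n)
  w[c(1L, n)] <- 2 / (n + 2)
  w
}

#' @rdname split_sentences
#' @export
default_separators <- function() {
  c("。", "！", "？", "!", "?", "；", ";", "\n")
}

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# tokens treated as clause boundaries by the fallback modifier window
.BOUNDARY_TOKENS <- c("，", ",", "、", " ", "　", "：", ":")

#' Extract emotion units from one sentence
#'
#' An emotion unit is an emotion word together with the negation words and
#' degree modifiers attached to it. Attachment uses a pluggable parser when
#' supplied (a function `sentence -> list of list(word, modifiers)`); the
#' default fallback attaches the up-to-`window` tokens immediately preceding
#' the emotion word, without crossing a clause boundary (comma, enumeration
#' comma, colon or space), and consumes each modifier at most once. If the
#' parser throws, the fallback window is used with a warning.
#'
#' @param sentence sentence text (one string).
#' @param lexicon an `emotion_lexicon` from [load_lexicon()].
#' @param modifiers a `modifier_lexicon` from [load_modifiers()].
#' @param parser optional parser adapter function.
#' @param window fallback window size in tokens (default 3).
#' @param tokenizer function(text, dictionary) -> list of token vectors;
#'   defaults to [tokenize_greedy()].
#' @return A list of units; each unit is a list with elements `word`,
#'   `category`, `q`, `m` (negation count), `factors` (degree factors).
#' @export
extract_units <- function(sentence, lexicon, modifiers, parser = NULL,
                          window = 3L, tokenizer = tokenize_greedy) {
  if (is.na(sentence) || sentence == "") return(list())
  lex_words <- unique(lexicon$word)
  if (!is.null(parser)) {
    parsed <- tryCatch(parser(sentence), error = function(e) {
      warning("parser failed (", conditionMessage(e),
              "); falling back to window attachment")
      NULL
    })
    if (!is.null(parsed)) {
      return(units_from_pairs(parsed, lexicon, modifiers))
    }
  }
  dict <- c(lex_words, names(modifiers$degree_factors), modifiers$negation_words)
  toks <- tokenizer(sentence, dict)[[1L]]
  n <- length(toks)
  used <- rep(FALSE, n)
  units <- list()
  for (i in seq_len(n)) {
    if (!(toks[i] %in% lex_words)) next
    m <- 0L
    factors <- numeric()
    j <- i - 1L
    steps <- 0L
    while (j >= 1L && steps < window) {
      tk <- toks[j]
      if (tk %in% .BOUNDARY_TOKENS) break
      if (!used[j]) {
        if (tk %in% modifiers$negation_words) {
          m <- m + 1L
          used[j] <- TRUE
        } else if (tk %in% names(modifiers$degree_factors)) {
          factors <- c(modifiers$degree_factors[[tk]], factors)
          used[j] <- TRUE
        }
      }
      j <- j - 1L
      steps <- steps + 1L
    }
    entries <- lexicon[lexicon$word == toks[i], , drop = FALSE]
    for (r in seq_len(nrow(entries))) {
      units[[length(units) + 1L]] <- list(
        word = toks[i], category = entries$category[r],
        q = entries$intensity[r], m = m, factors = factors
      )
    }
  }
  units
}

units_from_pairs <- function(parsed, lexicon, modifiers) {
  units <- list()
  for (p in parsed) {
    entries <- lexicon[lexicon$word == p$word, , drop = FALSE]
    if (nrow(entries) == 0L) next
    mods <- p$modifiers %||% character()
    m <- sum(mods %in% modifiers$negation_words)
    factors <- unname(modifiers$degree_factors[
      mods[mods %in% names(modifiers$degree_factors)]])
    for (r in seq_len(nrow(entries))) {
      units[[length(units) + 1L]] <- list(
        word = p$word, category = entries$category[r],
        q = entries$intensity[r], m = m, factors = factors
      )
    }
  }
  units
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score an emotion unit
#'
#' The signed unit score is \eqn{e_j = (-1)^m \prod_{v=1}^{l} c_v \, q}:
#' intensity `q`, flipped once per negation word (`m` of them), scaled by the
#' product of the degree factors `c_v`. The unit scores 0 for every other
#' emotion category.
#'
#' @param unit a unit from [extract_units()], or a list with `q`, `m`,
#'   `factors`.
#' @return The signed score (numeric scalar).
#' @export
#' @examples
#' score_unit(list(q = 5, m = 1, factors = 1.75))  # -8.75
score_unit <- function(unit) {
  stopifnot(unit$q > 0, unit$m >= 0)
  if (length(unit$factors) > 0 && any(unit$factors <= 0)) {
    stop("degree factors must be positive")
  }
  (-1)^unit$m * prod(unit$factors) * unit$q
}

#' Convert a signed score to its bidirectional category
#'
#' A negative score expresses the opposite member of the category's pair
#' (good-disgust, joy-sadness, anger-fear, surprise-anticipation): the score
#' is reflected onto the opposite category with positive magnitude. A
#' nonnegative score is returned unchanged.
#'
#' @param category an emotion category name.
#' @param score signed numeric score.
#' @return List with elements `category` and `score` (nonnegative).
#' @export
#' @examples
#' convert_bidirectional("surprise", -3)  # anticipate, 3
convert_bidirectional <- function(category, score) {
  if (score < 0) {
    list(category = opposite_category(category), score = -score)
  } else {
    list(category = category, score = score)
  }
}

#' Aggregate units into a sentence emotion vector
#'
#' Each unit is converted to its nonnegative bidirectional form, then scores
#' are summed per category, giving the sentence's 8-dimensional emotion
#' vector.
#'
#' @param units list of units from [extract_units()].
#' @return Named numeric vector over the eight categories (all >= 0).
#' @export
sentence_vector <- function(units) {
  v <- stats::setNames(numeric(8L), emotion_categories())
  for (u in units) {
    conv <- convert_bidirectional(u$category, score_unit(u))
    v[conv$category] <- v[conv$category] + conv$score
  }
  v
}

#' Combine sentence vectors into the post emotion vector
#'
#' The post vector is the position-weighted sum of its sentence vectors.
#'
#' @param weights numeric vector of sentence weights (summing to 1).
#' @param vectors list (or matrix rows) of 8-dimensional sentence vectors.
#' @return Named numeric 8-vector.
#' @export
post_vector <- function(weights, vectors) {
  if (length(weights) != length(vectors)) {
    stop("weights and vectors differ in length")
  }
  v <- stats::setNames(numeric(8L), emotion_categories())
  for (i in seq_along(weights)) v <- v + weights[i] * vectors[[i]]
  v
}

#' Classify a post emotion vector
#'
#' The label is the argmax category of the post vector, with ties broken in
#' the fixed order of [emotion_categories()]. If the maximum score falls
#' below the neutral threshold `delta`, the post is neutral. Sentiment rolls
#' up as positive (good, joy, surprise, anticipate), negative (fear, disgust,
#' sadness, anger) or neutral.
#'
#' @param v named numeric 8-vector from [post_vector()].
#' @param delta neutral threshold (> 0); default 0.5.
#' @param tie_order category order used for tie-breaking.
#' @return List with `label`, `sentiment`, `score` (the winning score).
#' @export
classify_post <- function(v, delta = 0.5, tie_order = emotion_categories()) {
  stopifnot(delta > 0)
  v <- v[tie_order]
  k <- which.max(v)  # first maximum in tie order
  if (v[k] < delta) {
    list(label = "neutral", sentiment = "neutral", score = unname(v[k]))
  } else {
    lab <- tie_order[k]
    list(label = lab, sentiment = category_sentiment(lab),
         score = unname(v[k]))
  }
}
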