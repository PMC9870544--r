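#' Greedy longest-match tokenizer
#'
#' A deterministic, dictionary-driven segmenter used as the default
#' tokenization backend: at each position the longest dictionary word is
#' consumed; characters not starting any dictionary word become single-character
#' tokens. This keeps fixture tests segmenter-free and reproducible; a
#' full-fledged Chinese word segmenter can be plugged into
#' [emotion_classifier()] via its `tokenizer` argument.
#'
#' @param text character vector.
#' @param dictionary character vector of known words (multi-character entries
#'   are matched longest-first).
#' @return A list of character vectors, one per input string.
#' @export
#' @examples
#' tokenize_greedy("非常高兴", c("非常", "高兴"))
tokenize_greedy <- function(text, dictionary) {
  dictionary <- unique(dictionary[nchar(dictionary) > 1L])
  by_len <- split(dictionary, nchar(dictionary))
  lens <- sort(as.integer(names(by_len)), decreasing = TRUE)
  sets <- lapply(by_len, function(w) stats::setNames(rep(TRUE, length(w)), w))
  lapply(text, function(s) {
    if (is.na(s) || s == "") return(character())
    ch <- strsplit(s, "", fixed = FALSE)[[1L]]
    n <- length(ch)
    out <- character(n)
    k <- 0L
    i <- 1L
    while (i <= n) {
      matched <- FALSE
      for (L in lens) {
        if (i + L - 1L > n) next
        cand <- paste(ch[i:(i + L - 1L)], collapse = "")
        if (!is.na(sets[[as.character(L)]][cand])) {
          k <- k + 1L
          out[k] <- cand
          i <- i + L
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        k <- k + 1L
        out[k] <- ch[i]
        i <- i + 1L
      }
    }
    out[seq_len(k)]
  })
}
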