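#' Default mapping from DLUT-style fine-grained codes to the eight categories
#'
#' The DLUT-style affective ontology labels words with two-letter codes nested
#' under seven major emotion classes. This map collapses the codes onto the
#' package's eight-category scheme. "anticipate" has no codes: it is reachable
#' only by negating a surprise word. The map ships as an editable JSON file
#' (`system.file("extdata", "dlut_code_map.json", package = "microemo")`).
#'
#' @param path optional path to a JSON file mapping code -> category; the
#'   packaged default is used when omitted.
#' @return Named character vector: names are codes, values are categories.
#' @export
default_code_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dlut_code_map.json", package = "microemo")
  }
  map <- unlist(jsonlite::read_json(path))
  bad <- setdiff(unique(map), emotion_categories())
  if (length(bad) > 0L) {
    stop("code map contains unknown categories: ", paste(bad, collapse = ", "))
  }
  map
}

#' Load an emotion lexicon
#'
#' Reads a CSV/TSV lexicon with columns `word`, `code`, `intensity`,
#' `polarity` (DLUT convention: intensity is an odd integer 1-9; the polarity
#' flag is carried through unused by the scorer). Rows whose code is missing
#' from `code_map` are reported and skipped. When a word carries several
#' senses in the same category, the maximum-intensity sense is kept -- a
#' deterministic, conservative resolution of polysemy.
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line).
#' @param code_map named character vector code -> category; defaults to
#'   [default_code_map()].
#' @return A data.frame of class `emotion_lexicon` with columns
#'   `word`, `code`, `category`, `intensity`, `polarity`.
#' @export
load_lexicon <- function(path, code_map = default_code_map()) {
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    warning("empty lexicon file: ", path)
    out <- data.frame(word = character(), code = character(),
                      category = character(), intensity = numeric(),
                      polarity = integer(), stringsAsFactors = FALSE)
    class(out) <- c("emotion_lexicon", "data.frame")
    return(out)
  }
  df <- read_table_auto(path)
  need <- c("word", "code", "intensity", "polarity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("lexicon file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("empty lexicon file: ", path)
    out <- data.frame(word = character(), code = character(),
                      category = character(), intensity = numeric(),
                      polarity = integer(), stringsAsFactors = FALSE)
    class(out) <- c("emotion_lexicon", "data.frame")
    return(out)
  }
  df$word <- trimws(as.character(df$word))
  df$code <- trimws(as.character(df$code))
  df$intensity <- as.numeric(df$intensity)
  if (anyNA(df$intensity) || any(df$intensity <= 0)) {
    bad <- which(is.na(df$intensity) | df$intensity <= 0)
    stop("non-positive or unparseable intensity in lexicon row(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(df$word == "")) {
    stop("empty word in lexicon row(s): ",
         paste(which(df$word == ""), collapse = ", "))
  }
  mapped <- unname(code_map[df$code])
  if (anyNA(mapped)) {
    skipped <- unique(df$code[is.na(mapped)])
    warning("skipping ", sum(is.na(mapped)), " row(s) with unmappable code(s): ",
            paste(skipped, collapse = ", "))
  }
  df$category <- mapped
  df <- df[!is.na(df$category), , drop = FALSE]
  # polysemy: keep the maximum-intensity sense per (word, category)
  df <- df[order(df$word, df$category, -df$intensity), , drop = FALSE]
  df <- df[!duplicated(df[c("word", "category")]), , drop = FALSE]
  rownames(df) <- NULL
  out <- df[c("word", "code", "category", "intensity", "polarity")]
  class(out) <- c("emotion_lexicon", "data.frame")
  out
}

# Six-level default degree table used when a degree file gives level labels
# rather than numeric factors.
.DEGREE_LEVELS <- c(
  most = 2.0, very = 1.75, more = 1.5,
  ish = 1.2, insufficiently = 0.5, over = 1.5
)

#' Load degree-adverb factors and negation words
#'
#' The degree file is one- or two-column text/CSV: `word` and either a numeric
#' multiplicative factor or one of the level labels
#' `most, very, more, ish, insufficiently, over` (mapped to
#' 2.0, 1.75, 1.5, 1.2, 0.5, 1.5). The negation file is one word per line.
#' A word present in both files is a configuration error: the scorer could not
#' decide whether it flips or scales.
#'
#' @param degree_path CSV with columns `word,factor` (factor numeric or level
#'   label); a bare one-column file is rejected.
#' @param negation_path plain-text file, one negation word per line.
#' @return List of class `modifier_lexicon` with elements `degree_factors`
#'   (named numeric vector) and `negation_words` (character vector).
#' @export
load_modifiers <- function(degree_path, negation_path) {
  deg <- read_table_auto(degree_path)
  if (!all(c("word", "factor") %in% names(deg))) {
    stop("degree file must have columns word, factor")
  }
  raw <- trimws(as.character(deg$factor))
  fac <- suppressWarnings(as.numeric(raw))
  lab <- is.na(fac) & raw %in% names(.DEGREE_LEVELS)
  fac[lab] <- .DEGREE_LEVELS[raw[lab]]
  if (anyNA(fac)) {
    stop("unparseable degree factor(s): ",
         paste(unique(raw[is.na(fac)]), collapse = ", "))
  }
  if (any(fac <= 0)) stop("degree factors must be positive")
  degree_factors <- stats::setNames(fac, trimws(as.character(deg$word)))

  neg <- readLines(negation_path, encoding = "UTF-8", warn = FALSE)
  neg <- trimws(neg)
  neg <- unique(neg[neg != "" & !startsWith(neg, "#")])

  both <- intersect(names(degree_factors), neg)
  if (length(both) > 0L) {
    stop("word(s) listed as both degree adverb and negation: ",
         paste(both, collapse = ", "))
  }
  structure(list(degree_factors = degree_factors, negation_words = neg),
            class = "modifier_lexicon")
}

#' Packaged toy lexicon and word lists
#'
#' A small (~60 word) Chinese emotion lexicon covering all seven DLUT-style
#' lexical classes, together with matching degree-adverb, negation, stopword
#' and official-user keyword lists. Intended for tests, examples and the
#' synthetic-corpus generator; it is not a redistribution of any published
#' ontology.
#'
#' @param what one of "lexicon", "degree", "negation", "stopwords",
#'   "official_keywords", "code_map".
#' @return A file path (character scalar).
#' @export
#' @examples
#' lex <- load_lexicon(toy_lexicon_path("lexicon"))
#' nrow(lex)
toy_lexicon_path <- function(what = c("lexicon", "degree", "negation",
                                      "stopwords", "official_keywords",
                                      "code_map")) {
  what <- match.arg(what)
  fn <- switch(what,
    lexicon = "toy_lexicon.csv",
    degree = "degree_adverbs.csv",
    negation = "negation_words.txt",
    stopwords = "stopwords.txt",
    official_keywords = "official_keywords.txt",
    code_map = "dlut_code_map.json"
  )
  path <- system.file("extdata", fn, package = "microemo")
  if (path == "") stop("packaged file not found: ", fn)
  path
}

#' Load a stopword list
#' @param path plain-text file, one word per line; defaults to the packaged
#'   toy list.
#' @return Character vector of stopwords.
#' @export
load_stopwords <- function(path = toy_lexicon_path("stopwords")) {
  sw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  unique(trimws(sw[trimws(sw) != ""]))
}

# Sniff the delimiter (tab vs comma) from the first line and read as UTF-8.
# "NA" must survive as the anger code, so NA-string coercion is disabled.
read_table_auto <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  sep <- if (length(first) > 0L && grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, na.strings = character(),
                    fileEncoding = "UTF-8", comment.char = "")
}
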