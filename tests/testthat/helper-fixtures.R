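# Shared fixtures: packaged toy lexicon and modifiers, loaded once.
.fixtures <- new.env(parent = emptyenv())

toy_lex <- function() {
  if (is.null(.fixtures$lex)) {
    .fixtures$lex <- load_lexicon(toy_lexicon_path("lexicon"))
  }
  .fixtures$lex
}

toy_mods <- function() {
  if (is.null(.fixtures$mods)) {
    .fixtures$mods <- load_modifiers(toy_lexicon_path("degree"),
                                     toy_lexicon_path("negation"))
  }
  .fixtures$mods
}

toy_clf <- function(...) emotion_classifier(toy_lex(), toy_mods(), ...)

# a unit literal for scorer tests
unit <- function(category, q, m = 0L, factors = numeric()) {
  list(word = "w", category = category, q = q, m = m, factors = factors)
}

write_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f, useBytes = TRUE)
  f
}
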