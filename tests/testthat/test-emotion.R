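test_that("sentence splitting assigns the position-weight formula", {
  sp <- split_sentences("A。B！C？D")
  expect_equal(sp$text, c("A", "B", "C", "D"))
  expect_equal(sp$weight, c(1/3, 1/6, 1/6, 1/3))
  expect_equal(split_sentences("A")$weight, 1)
  expect_equal(split_sentences("A。B。")$weight, c(0.5, 0.5))
  expect_equal(nrow(split_sentences("")), 0L)
})

test_that("weights sum to one and ends get 2/(n+2) for every n", {
  for (n in 1:50) {
    w <- sentence_weights(n)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    if (n > 2) {
      expect_equal(w[1], 2 / (n + 2))
      expect_equal(w[n], 2 / (n + 2))
      expect_true(all(w[2:(n - 1)] == 1 / (n + 2)))
    } else {
      expect_true(all(w == 1 / n))
    }
  }
})

test_that("unit scores match a brute-force product oracle", {
  defaults <- c(2.0, 1.75, 1.5, 1.2, 0.5)
  combos <- c(list(numeric()), as.list(defaults),
              apply(expand.grid(defaults, defaults), 1, c, simplify = FALSE))
  for (q in c(1, 3, 5, 7, 9)) {
    for (m in 0:3) {
      for (f in combos) {
        expected <- q
        for (cv in f) expected <- expected * cv
        if (m %% 2 == 1) expected <- -expected
        expect_equal(score_unit(unit("joy", q, m, f)), expected,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("negative scores convert to the opposite category", {
  expect_equal(convert_bidirectional("surprise", -3),
               list(category = "anticipate", score = 3))
  expect_equal(convert_bidirectional("joy", -2),
               list(category = "sadness", score = 2))
  expect_equal(convert_bidirectional("good", 5),
               list(category = "good", score = 5))
  # double negation comes back to the original category
  for (cat in emotion_categories()) {
    once <- convert_bidirectional(cat, -1)
    twice <- convert_bidirectional(once$category, -once$score)
    expect_identical(twice$category, cat)
  }
})

test_that("the fallback window attaches preceding modifiers within a clause", {
  u <- extract_units("非常高兴", toy_lex(), toy_mods())
  expect_length(u, 1L)
  expect_identical(u[[1]]$category, "joy")
  expect_equal(u[[1]]$m, 0L)
  expect_equal(u[[1]]$factors, 1.75)

  u2 <- extract_units("不高兴", toy_lex(), toy_mods())
  expect_equal(u2[[1]]$m, 1L)
  expect_length(u2[[1]]$factors, 0L)

  expect_length(extract_units("天气晴朗", toy_lex(), toy_mods()), 0L)

  # a comma is a clause boundary: the modifier does not attach across it
  u3 <- extract_units("非常，高兴", toy_lex(), toy_mods())
  expect_length(u3[[1]]$factors, 0L)

  # a modifier attaches to at most one emotion word
  u4 <- extract_units("不高兴高兴", toy_lex(), toy_mods())
  expect_equal(vapply(u4, `[[`, integer(1), "m"), c(1L, 0L))
})

test_that("a parser adapter overrides the window, and falls back on failure", {
  parser <- function(s) list(list(word = "高兴", modifiers = c("不", "很")))
  u <- extract_units("高兴但这里文本无关", toy_lex(), toy_mods(),
                     parser = parser)
  expect_equal(u[[1]]$m, 1L)
  expect_equal(u[[1]]$factors, 1.75)

  boom <- function(s) stop("parser crashed")
  expect_warning(u2 <- extract_units("不高兴", toy_lex(), toy_mods(),
                                     parser = boom), "falling back")
  expect_equal(u2[[1]]$m, 1L)
})

test_that("sentence vectors convert units before summing", {
  units <- list(unit("joy", 5), unit("joy", 2, m = 1))
  v <- sentence_vector(units)
  expect_equal(unname(v["joy"]), 5)
  expect_equal(unname(v["sadness"]), 2)
  expect_equal(sum(v), 7)
  expect_true(all(sentence_vector(list()) == 0))
  v2 <- sentence_vector(list(unit("good", 3), unit("good", 4)))
  expect_equal(unname(v2["good"]), 7)
})

test_that("post vectors are the weighted sentence sums", {
  e1 <- sentence_vector(list(unit("good", 4)))
  e2 <- sentence_vector(list(unit("good", 2)))
  v <- post_vector(c(0.5, 0.5), list(e1, e2))
  expect_equal(unname(v["good"]), 3)

  # n = 3, only the last sentence emotional: w3 = 2/5
  zero <- sentence_vector(list())
  fear5 <- sentence_vector(list(unit("fear", 5)))
  v3 <- post_vector(sentence_weights(3), list(zero, zero, fear5))
  expect_equal(unname(v3["fear"]), 2)
})

test_that("classification applies the threshold and fixed tie order", {
  z <- sentence_vector(list())
  expect_identical(classify_post(z, 0.5)$label, "neutral")
  g <- z; g["good"] <- 3.2
  expect_identical(classify_post(g, 0.5)$label, "good")
  expect_identical(classify_post(g, 0.5)$sentiment, "positive")
  g2 <- z; g2["good"] <- 0.3
  expect_identical(classify_post(g2, 0.5)$label, "neutral")
  tie <- z; tie[c("good", "anger")] <- 1
  expect_identical(classify_post(tie, 0.5)$label, "good")
})

test_that("scaling every intensity rescales scores but not labels", {
  set.seed(42)
  for (r in 1:25) {
    v <- stats::setNames(round(stats::runif(8, 0, 5), 3),
                         emotion_categories())
    lam <- stats::runif(1, 0.1, 10)
    base <- classify_post(v, delta = 0.5)
    scaled <- classify_post(lam * v, delta = 0.5 * lam)
    expect_identical(scaled$label, base$label)
    expect_equal(scaled$score, lam * base$score, tolerance = 1e-12)
  }
})

test_that("prediction is deterministic and neutral on empty text", {
  clf <- toy_clf()
  texts <- c("今天非常高兴！", "", "不要怕。一切可靠。", "天空云朵")
  p1 <- predict(clf, texts)
  p2 <- predict(clf, texts)
  expect_identical(p1, p2)
  expect_identical(p1$label[2], "neutral")
  expect_identical(p1$label[4], "neutral")
})
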