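test_that("the generator is byte-identical under a fixed seed", {
  cc <- corpus_config(n_posts = 120, seed = 5)
  s1 <- generate_corpus(cc)
  s2 <- generate_corpus(cc)
  expect_identical(s1, s2)
  s3 <- generate_corpus(corpus_config(n_posts = 120, seed = 6))
  expect_false(identical(s1$posts$content, s3$posts$content))
})

test_that("configuration is validated", {
  expect_error(corpus_config(mixture = c(good = 1)), "mixture")
  m <- default_mixture(); m["good"] <- m[["good"]] + 0.1
  expect_error(corpus_config(mixture = m), "sum to 1")
  expect_error(corpus_config(official_fraction = 1.5), "rates")
  expect_error(corpus_config(start_date = "2022-07-10",
                             end_date = "2022-07-01"), "follow")
})

test_that("anticipation gold requires surprise words to negate", {
  lex <- toy_lex()
  no_surprise <- lex[lex$category != "surprise", ]
  class(no_surprise) <- class(lex)
  m <- stats::setNames(rep(0, 9), emotion_labels())
  m["anticipate"] <- 1
  cc <- corpus_config(n_posts = 10, mixture = m, seed = 1)
  expect_error(generate_corpus(cc, no_surprise, toy_mods()), "config error")
})

test_that("gold labels are perfectly recoverable by the classifier", {
  cc <- corpus_config(n_posts = 250, seed = 21)
  sim <- generate_corpus(cc)
  clean <- preprocess_posts(sim$posts)
  pred <- predict(toy_clf(), clean)
  expect_equal(mean(pred$label == sim$gold$emotion), 1)
  expect_equal(mean(pred$sentiment == sim$gold$sentiment), 1)
  # preprocessing round-trips the rendered posting times exactly
  expect_true(all(clean$posted_at == sim$gold$posted_at))
})

test_that("neutral posts contain no lexicon words", {
  cc <- corpus_config(n_posts = 200, seed = 13)
  sim <- generate_corpus(cc)
  neutral <- clean_content(sim$posts$content[sim$gold$emotion == "neutral"])
  lex_words <- toy_lex()$word
  hits <- vapply(neutral, function(x) {
    any(vapply(lex_words, grepl, logical(1), x = x, fixed = TRUE))
  }, logical(1))
  expect_false(any(hits))
})

test_that("the mixture is recovered within multinomial error", {
  cc <- corpus_config(n_posts = 1500, seed = 2)
  sim <- generate_corpus(cc)
  clean <- preprocess_posts(sim$posts)
  pred <- predict(toy_clf(), clean)
  phat <- table(factor(pred$label, emotion_labels())) / nrow(clean)
  p <- cc$mixture
  se <- sqrt(p * (1 - p) / nrow(clean))
  expect_true(all(abs(as.numeric(phat[names(p)]) - p) <= 3 * se + 1e-12))
})

test_that("a configured lead-lag appears in the daily series", {
  cc <- corpus_config(n_posts = 4000, lead_lag_days = 1, seed = 9)
  sim <- generate_corpus(cc)
  g <- sim$gold
  days <- seq(cc$start_date, cc$end_date, by = "day")
  off <- table(factor(as.character(g$date[g$user_type == "official"]),
                      as.character(days)))
  per <- table(factor(as.character(g$date[g$user_type == "personal"]),
                      as.character(days)))
  ll <- lead_lag(as.numeric(off), as.numeric(per), max_lag = 5)
  expect_equal(ll$lag, 1L)
})

test_that("evaluation sets carry the designed confusion structure", {
  clean <- generate_gold_eval_set(n = 300, noise_rate = 0, seed = 3)
  m <- evaluate_predictions(clean$gold, clean$pred)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)

  noisy <- generate_gold_eval_set(n = 2000, labels = c("a", "b", "c"),
                                  noise_rate = 0.1, seed = 4)
  m2 <- evaluate_predictions(noisy$gold, noisy$pred)
  se <- sqrt(0.9 * 0.1 / 2000)
  expect_lt(abs(m2$accuracy - 0.9), 3 * se)

  # one class never predicted exercises the zero-metric warning path
  never <- generate_gold_eval_set(n = 200, labels = c("a", "b"),
                                  noise_rate = 0, seed = 5)
  never$pred$label[never$pred$label == "b"] <- "a"
  expect_warning(m3 <- evaluate_predictions(never$gold, never$pred), "b")
  expect_equal(m3$per_class$recall[m3$per_class$class == "b"], 0)
})
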