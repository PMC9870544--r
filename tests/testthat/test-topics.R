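fake_model <- function(phi, theta = NULL) {
  if (is.null(theta)) theta <- matrix(1 / nrow(phi), 2, nrow(phi))
  structure(list(phi = phi, theta = theta,
                 vocab = colnames(phi) %||% paste0("w", seq_len(ncol(phi))),
                 k = nrow(phi)),
            class = "lda_model")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the perplexity elbow is the maximal second difference", {
  expect_equal(perplexity_elbow(c(100, 50, 48, 47, 46)), 2L)
  expect_equal(perplexity_elbow(c(90, 60, 40, 39, 38, 37)), 3L)
  expect_warning(k <- perplexity_elbow(c(50, 40, 30, 20, 10)), "no turn")
  expect_equal(k, 5L)
  expect_error(perplexity_elbow(c(2, 1)), "length")
})

test_that("select_k takes the coherence argmax below the bound, ties to smaller k", {
  expect_equal(select_k(c(0.30, 0.50, 0.40), 1:3, 3), 2L)
  expect_equal(select_k(c(0.4, 0.4, 0.4), 1:3, 3), 1L)
  expect_equal(select_k(c(0.1, 0.2, 0.9), 1:3, 2), 2L)
  set.seed(5)
  for (i in 1:20) {
    coh <- runif(8)
    ku <- sample(1:8, 1)
    expect_lte(select_k(coh, 1:8, ku), ku)
  }
})

test_that("LDA fitting is deterministic under a fixed seed", {
  pc <- generate_topic_corpus(3, docs_per_topic = 15, seed = 2)
  f1 <- lda_fit(pc$docs, 3, seed = 99)
  f2 <- lda_fit(pc$docs, 3, seed = 99)
  expect_identical(f1$phi, f2$phi)
  expect_identical(f1$theta, f2$theta)
  c1 <- topic_curves(pc$docs, 1:4, seed = 31)
  c2 <- topic_curves(pc$docs, 1:4, seed = 31)
  expect_identical(c1, c2)
})

test_that("a one-topic model has unigram perplexity", {
  pc <- generate_topic_corpus(2, docs_per_topic = 10, seed = 4)
  fit <- lda_fit(pc$docs, 1, beta = 0.1, seed = 1)
  toks <- unlist(pc$docs)
  nw <- table(factor(toks, levels = fit$vocab))
  phi_uni <- (as.numeric(nw) + 0.1) / (length(toks) + length(fit$vocab) * 0.1)
  names(phi_uni) <- fit$vocab
  expected <- exp(-sum(log(phi_uni[toks])) / length(toks))
  expect_equal(lda_perplexity(fit), expected, tolerance = 1e-10)
})

test_that("overlap flags identical topics, not disjoint ones", {
  p <- rbind(c(0.5, 0.5, 0, 0), c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5))
  colnames(p) <- paste0("w", 1:4)
  ov <- topic_overlap(fake_model(p), threshold = 0.25)
  expect_equal(nrow(ov), 1L)
  expect_equal(c(ov$topic_a, ov$topic_b), c(1L, 2L))
  expect_equal(ov$distance, 0)

  disj <- rbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5))
  colnames(disj) <- paste0("w", 1:4)
  expect_equal(nrow(topic_overlap(fake_model(disj), 0.25)), 0L)
  expect_error(topic_overlap(fake_model(disj[1, , drop = FALSE])), "two topics")
})

test_that("a duplicated planted topic flags exactly one pair", {
  # three planted word distributions plus a noisy duplicate of the second:
  # only the (2, 4) pair should fall under the distance threshold
  set.seed(8)
  V <- 30L
  planted <- t(vapply(1:3, function(k) {
    p <- numeric(V)
    p[((k - 1) * 10 + 1):(k * 10)] <- 1 / 10
    p
  }, numeric(V)))
  dup <- planted[2, ] * exp(rnorm(V, 0, 0.05))
  dup <- dup / sum(dup)
  phi <- rbind(planted, dup)
  colnames(phi) <- sprintf("w%02d", 1:V)
  ov <- topic_overlap(fake_model(phi), threshold = 0.25)
  expect_equal(nrow(ov), 1L)
  expect_equal(c(ov$topic_a, ov$topic_b), c(2L, 4L))
})

test_that("keywords come out in descending weight, with vocabulary guard", {
  p <- rbind(c(0.6, 0.3, 0.1), c(0.1, 0.2, 0.7))
  colnames(p) <- c("alpha", "beta", "gamma")
  kw <- topic_keywords(fake_model(p), 1)
  expect_equal(kw, list("alpha", "gamma"))
  expect_warning(all_kw <- topic_keywords(fake_model(p), 10), "vocabulary")
  expect_equal(lengths(all_kw), c(3L, 3L))
})

test_that("planted disjoint vocabularies are recovered in curves and keywords", {
  pc <- generate_topic_corpus(3, seed = 11)
  cur <- topic_curves(pc$docs, 1:6, seed = 11)
  expect_equal(nrow(cur), 6L)
  best <- cur$k[which.max(cur$coherence)]
  expect_true(best %in% 2:4)

  fit <- lda_fit(pc$docs, 3, seed = 11)
  kw <- topic_keywords(fit, 5)
  # each fitted topic's keywords come predominantly from one planted vocabulary
  for (words in kw) {
    planted <- substr(words, 1, 2)
    expect_gte(max(table(planted)), 4L)
  }
})

test_that("topic tokenization strips stopwords and single characters", {
  dict <- c("高兴", "天空")
  docs <- tokenize_for_topics(c("我的天空很高兴", ""), dict,
                              stopwords = c("我", "的", "很"))
  expect_equal(docs[[1]], c("天空", "高兴"))
  expect_length(docs[[2]], 0L)
  expect_error(topic_curves(list(c("a1", "a1")), 1:3, min_vocab = 10),
               "vocabulary too small")
})
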