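#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the shape of a crawled microblog post table during a
#' two-month epidemic-control period: a nine-part emotion mixture (defaulting
#' to the overall corpus distribution of the bundled benchmark tables), a
#' roughly one-fifth official-account share, posting dates over July-August
#' 2022 with a unimodal volume profile, and an optional official-to-personal
#' lead-lag in days. Every random choice is fixed by `seed`.
#'
#' @param n_posts number of posts.
#' @param mixture named numeric vector of proportions over
#'   [emotion_labels()]; must sum to 1.
#' @param official_fraction probability a post is from an official account.
#' @param start_date,end_date corpus date span (Date or string).
#' @param lead_lag_days personal posts echo the official daily profile this
#'   many days later (0 = synchronous).
#' @param negation_rate probability a seeded emotion word is expressed as a
#'   negated word of the opposite category (the net label is unchanged).
#' @param degree_rate probability an intensifying degree adverb is prepended.
#' @param seed integer RNG seed.
#' @return List of class `corpus_config`.
#' @export
corpus_config <- function(n_posts = 1000L,
                          mixture = default_mixture(),
                          official_fraction = 0.2,
                          start_date = "2022-07-01",
                          end_date = "2022-08-31",
                          lead_lag_days = 0L,
                          negation_rate = 0.2,
                          degree_rate = 0.3,
                          seed = 1L) {
  mixture <- mixture[emotion_labels()]
  if (anyNA(mixture)) stop("mixture must name all of: ",
                           paste(emotion_labels(), collapse = ", "))
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1")
  rates <- c(official_fraction, negation_rate, degree_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date <= start_date) stop("end_date must follow start_date")
  if (lead_lag_days < 0) stop("lead_lag_days must be >= 0")
  structure(list(
    n_posts = as.integer(n_posts), mixture = mixture,
    official_fraction = official_fraction,
    start_date = start_date, end_date = end_date,
    lead_lag_days = as.integer(lead_lag_days),
    negation_rate = negation_rate, degree_rate = degree_rate,
    seed = as.integer(seed)
  ), class = "corpus_config")
}

#' Default emotion mixture (benchmark overall distribution)
#' @return Named numeric vector over [emotion_labels()] summing to 1.
#' @export
default_mixture <- function() {
  d <- benchmark_table("distribution_overall")
  stats::setNames(d$count / sum(d$count), d$emotion)[emotion_labels()]
}

#' Packaged filler vocabulary (disjoint from the toy lexicon)
#' @return Character vector of neutral two-character words.
#' @export
filler_words <- function() {
  readLines(system.file("extdata", "filler_words.txt", package = "microemo"),
            encoding = "UTF-8", warn = FALSE)
}

#' Generate a synthetic raw post table with gold labels
#'
#' Each non-neutral post contains exactly one seeded emotion unit whose net
#' category equals the gold label: either a word of the gold category, or
#' (with probability `negation_rate`) a negated word of the opposite category.
#' Anticipation, which has no lexicon entries, is always seeded as a negated
#' surprise word. Degree adverbs (intensifiers only) are injected with
#' probability `degree_rate`. Neutral posts contain no lexicon words. Seeded
#' words have intensity >= 5 and sit in a first/last sentence, so the post
#' score always clears the default neutral threshold. Posting dates follow a
#' unimodal profile; personal posts echo the official profile
#' `lead_lag_days` later. Content is built from template fragments over a
#' filler vocabulary disjoint from the lexicon, so lexicon hits are exactly
#' the seeded ones.
#'
#' @param config a [corpus_config()].
#' @param lexicon an `emotion_lexicon`; defaults to the packaged toy lexicon.
#' @param modifiers a `modifier_lexicon`; defaults to the packaged lists.
#' @return List with `posts` (the nine-column raw table) and `gold`
#'   (data.frame: id, emotion, sentiment, user_type, date, posted_at).
#' @export
generate_corpus <- function(config,
                            lexicon = load_lexicon(toy_lexicon_path("lexicon")),
                            modifiers = load_modifiers(
                              toy_lexicon_path("degree"),
                              toy_lexicon_path("negation"))) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  n <- config$n_posts
  labs <- emotion_labels()

  pool <- function(cat) {
    w <- lexicon[lexicon$category == cat & lexicon$intensity >= 5, ]
    w[order(w$word), , drop = FALSE]
  }
  pools <- stats::setNames(lapply(emotion_categories(), pool),
                           emotion_categories())
  if (config$mixture[["anticipate"]] > 0 && nrow(pools[["surprise"]]) == 0L) {
    stop("config error: gold 'anticipate' requires surprise words to negate")
  }
  for (cat in emotion_categories()) {
    if (cat != "anticipate" && config$mixture[[cat]] > 0 &&
        nrow(pools[[cat]]) == 0L && nrow(pools[[opposite_category(cat)]]) == 0L) {
      stop("config error: no lexicon words (own or opposite) for gold '",
           cat, "'")
    }
  }
  amp <- names(config_amplifiers(modifiers))
  neg_words <- modifiers$negation_words
  fillers <- filler_words()

  gold_emotion <- sample(labs, n, replace = TRUE, prob = config$mixture)
  user_type <- ifelse(stats::runif(n) < config$official_fraction,
                      "official", "personal")

  # unimodal daily profile; personal users echo it lead_lag_days later
  span_days <- as.integer(config$end_date - config$start_date) + 1L
  lag <- config$lead_lag_days
  base_days <- span_days - lag
  if (base_days < 3L) stop("date span too short for the configured lead-lag")
  # smooth epidemic wave modulated by day-level event multipliers: real
  # posting volumes spike on news days, and those sharp peaks are what the
  # lead-lag diagnostic keys on
  prof <- (stats::dnorm(seq_len(base_days), mean = base_days / 2,
                        sd = base_days / 6) + 0.2 / base_days) *
    exp(stats::rnorm(base_days, 0, 0.6))
  day_idx <- sample.int(base_days, n, replace = TRUE, prob = prof)
  day_idx[user_type == "personal"] <- day_idx[user_type == "personal"] + lag
  date <- config$start_date + day_idx - 1L

  filler_sentence <- function() {
    paste(sample(fillers, sample(2:3, 1L)), collapse = "")
  }
  emotional_fragment <- function(gold) {
    negate <- gold == "anticipate" ||
      (stats::runif(1) < config$negation_rate &&
         nrow(pools[[opposite_category(gold)]]) > 0L)
    src <- if (negate) opposite_category(gold) else gold
    if (nrow(pools[[src]]) == 0L) {  # gold has no own words: must negate
      negate <- TRUE
      src <- opposite_category(gold)
    }
    word <- sample(pools[[src]]$word, 1L)
    frag <- word
    if (negate) frag <- paste0(sample(neg_words, 1L), frag)
    if (stats::runif(1) < config$degree_rate) {
      frag <- paste0(sample(amp, 1L), frag)
    }
    frag
  }

  content <- character(n)
  for (i in seq_len(n)) {
    n_s <- sample(1:3, 1L)
    sents <- vapply(seq_len(n_s), function(s) filler_sentence(), "")
    if (gold_emotion[i] != "neutral") {
      pos <- if (n_s == 1L) 1L else sample(c(1L, n_s), 1L)
      frag <- emotional_fragment(gold_emotion[i])
      sents[pos] <- if (stats::runif(1) < 0.5) {
        paste0(sample(fillers, 1L), "，", frag)
      } else {
        frag
      }
    }
    content[i] <- paste0("#话题", i, "# ",
                         paste0(sents, collapse = "。"), "。")
  }

  publisher <- synth_publishers(user_type)
  uid <- vapply(seq_len(n), function(i) {
    paste0(sample(1:9, 1L),
           paste0(sample(0:9, 9L, replace = TRUE), collapse = ""))
  }, "")
  link_form <- stats::runif(n) < 0.5
  publisher_link <- ifelse(
    link_form,
    paste0("https://weibo.com/", uid, "?refer_flag=1001030103"),
    paste0("https://weibo.com/u/", uid))

  tm <- render_posting_times(date, n)

  posts <- data.frame(
    publisher = publisher,
    content = content,
    publisher_link = publisher_link,
    posting_time = tm$posting_time,
    source = sample(c("微博 weibo.com", "iPhone", "Android",
                      "网页"), n, replace = TRUE),
    comments = stats::rpois(n, 3), retweets = stats::rpois(n, 2),
    likes = stats::rpois(n, 10),
    current_time = format(tm$current_time, "%Y-%m-%d %H:%M:%S"),
    stringsAsFactors = FALSE
  )
  gold <- data.frame(
    id = seq_len(n), emotion = gold_emotion,
    sentiment = category_sentiment(gold_emotion),
    user_type = user_type, date = date,
    posted_at = tm$posted_at,
    stringsAsFactors = FALSE
  )
  list(posts = posts, gold = gold)
}

config_amplifiers <- function(modifiers) {
  f <- modifiers$degree_factors
  f[f >= 1.2]
}

synth_publishers <- function(user_type) {
  n <- length(user_type)
  place <- c("江城", "北原", "南湖", "东川",
             "西岭")
  org <- c("日报", "电视台", "发布",
           "卫健委")
  pers1 <- c("小", "阿", "老")
  pers2 <- c("明", "芳", "强", "林", "雨", "桔",
             "岸", "河")
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (user_type[i] == "official") {
      paste0(sample(place, 1L), sample(org, 1L))
    } else {
      paste0(sample(pers1, 1L), sample(pers2, 1L),
             sample(pers2, 1L), sample(100:999, 1L))
    }
  }
  out
}

# Render posted_at as the crawler's string dialects so that preprocessing
# recovers the timestamp exactly.
render_posting_times <- function(date, n) {
  hour <- sample(7:18, n, replace = TRUE)
  minute <- sample(0:59, n, replace = TRUE)
  posted_at <- as.POSIXct(paste0(format(date), sprintf(" %02d:%02d:00",
                                                       hour, minute)),
                          tz = "UTC")
  form <- sample(c("abs", "min", "today", "sec"), n, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1))
  posting_time <- character(n)
  current_time <- posted_at
  for (i in seq_len(n)) {
    posting_time[i] <- switch(form[i],
      abs = {
        current_time[i] <- posted_at[i] + 3600
        format(posted_at[i], "%Y-%m-%d %H:%M:%S")
      },
      min = {
        k <- sample(1:120, 1L)
        current_time[i] <- posted_at[i] + k * 60
        paste0(k, "分钟前")
      },
      today = {
        current_time[i] <- posted_at[i] + sample(600:7200, 1L)
        paste0("今天 ", format(posted_at[i], "%H:%M"))
      },
      sec = {
        k <- sample(5:55, 1L)
        current_time[i] <- posted_at[i] + k
        paste0(k, "秒前")
      })
  }
  list(posting_time = posting_time, current_time = current_time,
       posted_at = posted_at)
}

#' Generate a gold evaluation set with controlled label noise
#'
#' Gold labels are drawn from `mixture`; predictions equal the gold label
#' except with probability `noise_rate`, where a uniformly random other class
#' is substituted (symmetric noise), so expected accuracy is
#' `1 - noise_rate`.
#'
#' @param n number of items.
#' @param labels class set (default the nine emotion labels).
#' @param mixture optional named proportions (default uniform).
#' @param noise_rate symmetric label-noise probability.
#' @param seed RNG seed.
#' @return List with `gold` and `pred` data.frames (columns id, label) and
#'   `noise_rate`.
#' @export
generate_gold_eval_set <- function(n = 1000L, labels = emotion_labels(),
                                   mixture = NULL, noise_rate = 0.1,
                                   seed = 1L) {
  stopifnot(noise_rate >= 0, noise_rate <= 1, length(labels) >= 2L)
  set.seed(seed)
  if (is.null(mixture)) mixture <- rep(1 / length(labels), length(labels))
  gold <- sample(labels, n, replace = TRUE, prob = mixture)
  pred <- gold
  flip <- stats::runif(n) < noise_rate
  for (i in which(flip)) pred[i] <- sample(setdiff(labels, gold[i]), 1L)
  list(gold = data.frame(id = seq_len(n), label = gold,
                         stringsAsFactors = FALSE),
       pred = data.frame(id = seq_len(n), label = pred,
                         stringsAsFactors = FALSE),
       noise_rate = noise_rate)
}

#' Generate a planted-topic corpus
#'
#' K topics with disjoint vocabularies (`t<k>w<j>` tokens, Zipf-weighted
#' within a topic). Each document draws `1 - mix` of its tokens from its own
#' topic and `mix` from the other topics, so the planted structure is
#' recoverable but not degenerate.
#'
#' @param k_true number of planted topics.
#' @param docs_per_topic documents per topic.
#' @param doc_len tokens per document.
#' @param vocab_per_topic words per topic vocabulary.
#' @param mix cross-topic contamination rate (default 0.1).
#' @param seed RNG seed.
#' @return List with `docs` (list of token vectors) and `topic` (gold topic
#'   index per document).
#' @export
generate_topic_corpus <- function(k_true, docs_per_topic = 40L,
                                  doc_len = 15L, vocab_per_topic = 15L,
                                  mix = 0.1, seed = 1L) {
  stopifnot(k_true >= 2L, mix >= 0, mix < 1)
  set.seed(seed)
  vocabs <- lapply(seq_len(k_true), function(k) {
    sprintf("t%dw%02d", k, seq_len(vocab_per_topic))
  })
  zipf <- (1 / seq_len(vocab_per_topic))
  zipf <- zipf / sum(zipf)
  docs <- list()
  topic <- integer()
  for (k in seq_len(k_true)) {
    for (d in seq_len(docs_per_topic)) {
      own <- stats::rbinom(1L, doc_len, 1 - mix)
      toks <- sample(vocabs[[k]], own, replace = TRUE, prob = zipf)
      if (doc_len - own > 0L) {
        other <- unlist(vocabs[-k])
        toks <- c(toks, sample(other, doc_len - own, replace = TRUE))
      }
      docs[[length(docs) + 1L]] <- sample(toks)
      topic <- c(topic, k)
    }
  }
  list(docs = docs, topic = topic)
}
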