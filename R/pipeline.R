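#' Build or load a pipeline run configuration
#'
#' Paths, scoring parameters and the seed for a full pipeline run. A YAML or
#' JSON file (by extension) can override any default; explicit arguments
#' override the file.
#'
#' @param path optional YAML/JSON config file.
#' @param ... named overrides (see Details).
#' @details Recognised fields: `lexicon`, `degree`, `negation`, `stopwords`,
#'   `official_keywords` (paths; default: the packaged toy files), `input`
#'   (raw post CSV; default: the simulated corpus), `output_dir`, `delta`,
#'   `window`, `seed`, `n_posts`, `lead_lag_days`, `k_range`, `top_n`,
#'   `overlap_threshold`, `rollup_digits`, `topics_emotion` (which emotion's
#'   personal posts feed topic mining).
#' @return List of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    lexicon = toy_lexicon_path("lexicon"),
    degree = toy_lexicon_path("degree"),
    negation = toy_lexicon_path("negation"),
    stopwords = toy_lexicon_path("stopwords"),
    official_keywords = toy_lexicon_path("official_keywords"),
    input = NULL,
    output_dir = "microemo_run",
    delta = 0.5, window = 3L, seed = 1L,
    n_posts = 1000L, lead_lag_days = 1L,
    k_range = 1:8, top_n = 10L, overlap_threshold = 0.25,
    rollup_digits = 1L, topics_emotion = "fear"
  )
  if (!is.null(path)) {
    file_cfg <- if (grepl("\\.ya?ml$", path)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (!is.numeric(cfg$delta) || cfg$delta <= 0) stop("delta must be > 0")
  for (f in c("lexicon", "degree", "negation", "stopwords",
              "official_keywords")) {
    if (!file.exists(cfg[[f]])) stop("config path does not exist: ", cfg[[f]])
  }
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

run_meta <- function(cfg) {
  list(tool = "microemo",
       version = as.character(utils::packageVersion("microemo")),
       config_hash = config_hash(cfg),
       created = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing one artifact
#' per stage into `config$output_dir`:
#' \describe{
#'   \item{simulate}{`corpus.csv`, `gold.csv` (synthetic raw table)}
#'   \item{preprocess}{`clean.jsonl` from `config$input` or the simulated
#'     corpus}
#'   \item{annotate}{`labels.jsonl` (emotion vectors, labels, sentiments)}
#'   \item{evaluate}{`metrics.json` against `gold.csv`}
#'   \item{distribution}{`distribution.json`, `distribution.csv`, and the
#'     official/personal comparison with chi-square}
#'   \item{timeseries}{`timeseries.csv` and a lead-lag report in
#'     `timeseries.json` (+ `timeseries.png`)}
#'   \item{topics}{`topics.json`, `topic_keywords.csv`, `intertopic.png`}
#' }
#' A stage whose upstream artifact is missing aborts with a dependency error.
#' All JSON artifacts embed the tool version and a config hash.
#'
#' @param config a [run_config()].
#' @param stages ordered subset of the stage names above (default: all).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "preprocess", "annotate",
                                    "evaluate", "distribution", "timeseries",
                                    "topics")) {
  all_stages <- c("simulate", "preprocess", "annotate", "evaluate",
                  "distribution", "timeseries", "topics")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$output_dir, f)
  need <- function(f, stage, from) {
    if (!file.exists(p(f))) {
      stop("dependency error: stage '", stage, "' requires ", f,
           " (run '", from, "' first)")
    }
  }
  meta <- run_meta(config)
  artifacts <- list()
  lex <- load_lexicon(config$lexicon)
  mods <- load_modifiers(config$degree, config$negation)
  msg <- function(...) message("[microemo] ", sprintf(...))

  if ("simulate" %in% stages) {
    cc <- corpus_config(n_posts = config$n_posts,
                        lead_lag_days = config$lead_lag_days,
                        seed = config$seed)
    sim <- generate_corpus(cc, lex, mods)
    utils::write.csv(sim$posts, p("corpus.csv"), row.names = FALSE,
                     fileEncoding = "UTF-8")
    utils::write.csv(sim$gold, p("gold.csv"), row.names = FALSE,
                     fileEncoding = "UTF-8")
    msg("simulate: %d posts -> %s", nrow(sim$posts), p("corpus.csv"))
    artifacts$corpus <- p("corpus.csv"); artifacts$gold <- p("gold.csv")
  }

  if ("preprocess" %in% stages) {
    input <- config$input
    if (is.null(input)) {
      need("corpus.csv", "preprocess", "simulate")
      input <- p("corpus.csv")
    }
    raw <- utils::read.csv(input, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
    keywords <- readLines(config$official_keywords, encoding = "UTF-8",
                          warn = FALSE)
    clean <- preprocess_posts(raw, keywords)
    clean$id <- seq_len(nrow(clean))
    write_jsonl(clean, p("clean.jsonl"))
    msg("preprocess: %d cleaned posts -> %s", nrow(clean), p("clean.jsonl"))
    artifacts$clean <- p("clean.jsonl")
  }

  if ("annotate" %in% stages) {
    need("clean.jsonl", "annotate", "preprocess")
    clean <- read_jsonl(p("clean.jsonl"))
    clf <- emotion_classifier(lex, mods, delta = config$delta,
                              window = config$window)
    pred <- predict(clf, clean)
    out <- cbind(clean[c("id", "user_type", "posted_at")], pred)
    write_jsonl(out, p("labels.jsonl"))
    msg("annotate: %d labeled posts -> %s", nrow(out), p("labels.jsonl"))
    artifacts$labels <- p("labels.jsonl")
  }

  if ("evaluate" %in% stages) {
    need("labels.jsonl", "evaluate", "annotate")
    need("gold.csv", "evaluate", "simulate")
    labels <- read_jsonl(p("labels.jsonl"))
    gold <- utils::read.csv(p("gold.csv"), stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
    rep_emotion <- evaluate_predictions(
      data.frame(id = gold$id, label = gold$emotion),
      data.frame(id = labels$id, label = labels$label))
    rep_sentiment <- evaluate_predictions(
      data.frame(id = gold$id, label = gold$sentiment),
      data.frame(id = labels$id, label = labels$sentiment))
    out <- list(meta = meta,
                emotion = unclass(rep_emotion),
                sentiment = unclass(rep_sentiment))
    jsonlite::write_json(out, p("metrics.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    msg("evaluate: emotion acc %.3f, sentiment acc %.3f -> %s",
        rep_emotion$accuracy, rep_sentiment$accuracy, p("metrics.json"))
    artifacts$metrics <- p("metrics.json")
  }

  if ("distribution" %in% stages) {
    need("labels.jsonl", "distribution", "annotate")
    labels <- read_jsonl(p("labels.jsonl"))
    overall <- emotion_distribution(labels$label)
    utils::write.csv(overall$emotions, p("distribution.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    grp <- NULL
    if (all(c("official", "personal") %in% labels$user_type)) {
      cmpr <- compare_groups(labels$label[labels$user_type == "official"],
                             labels$label[labels$user_type == "personal"],
                             rollup_digits = config$rollup_digits)
      grp <- list(table = as.data.frame(as.table(cmpr$table)),
                  statistic = cmpr$statistic, df = cmpr$df,
                  p_value = cmpr$p_value,
                  note = "percentages computed from group column sums")
    }
    jsonlite::write_json(list(meta = meta, overall = unclass(overall),
                              comparison = grp),
                         p("distribution.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    msg("distribution: n = %d -> %s", overall$total, p("distribution.json"))
    artifacts$distribution <- p("distribution.json")
  }

  if ("timeseries" %in% stages) {
    need("labels.jsonl", "timeseries", "annotate")
    labels <- read_jsonl(p("labels.jsonl"))
    labels$posted_at <- as.POSIXct(labels$posted_at, tz = "UTC")
    series <- list()
    ll <- NULL
    for (emo in c("good", "joy", "fear", "disgust")) {
      off <- daily_series(labels, emo, "official")
      per <- daily_series(labels, emo, "personal")
      off$scaled <- if (sum(off$count) > 0) {
        off$count * sum(per$count) / sum(off$count)
      } else {
        as.numeric(off$count)
      }
      series[[emo]] <- data.frame(date = off$date, emotion = emo,
                                  official = off$count,
                                  official_scaled = off$scaled,
                                  personal = per$count)
      if (emo == "good" && stats::sd(off$count) > 0 &&
          stats::sd(per$count) > 0) {
        ll <- lead_lag(off$count, per$count, max_lag = 7L)
      }
    }
    ts <- do.call(rbind, series)
    utils::write.csv(ts, p("timeseries.csv"), row.names = FALSE,
                     fileEncoding = "UTF-8")
    jsonlite::write_json(list(
      meta = meta,
      lead_lag = if (is.null(ll)) NULL else
        list(emotion = "good", lag = ll$lag, correlation = ll$correlation)),
      p("timeseries.json"), auto_unbox = TRUE, digits = NA)
    grDevices::png(p("timeseries.png"), width = 800, height = 500)
    g <- series[["good"]]
    graphics::plot(g$date, g$official_scaled, type = "l",
                   xlab = "date", ylab = "daily posts",
                   main = "good: official (scaled) vs personal")
    graphics::lines(g$date, g$personal, lty = 2, col = "grey40")
    grDevices::dev.off()
    msg("timeseries: 4 emotions -> %s", p("timeseries.csv"))
    artifacts$timeseries <- p("timeseries.csv")
  }

  if ("topics" %in% stages) {
    need("labels.jsonl", "topics", "annotate")
    need("clean.jsonl", "topics", "preprocess")
    labels <- read_jsonl(p("labels.jsonl"))
    clean <- read_jsonl(p("clean.jsonl"))
    sel_ids <- labels$id[labels$label == config$topics_emotion &
                           labels$user_type == "personal"]
    texts <- clean$content_clean[match(sel_ids, clean$id)]
    dict <- c(lex$word, filler_words())
    docs <- tokenize_for_topics(texts, dict,
                                load_stopwords(config$stopwords))
    docs <- docs[lengths(docs) > 0L]
    if (length(docs) < 20L) {
      stop("too few '", config$topics_emotion,
           "' posts for topic mining (", length(docs), ")")
    }
    sel <- select_topics(docs, k_range = config$k_range, seed = config$seed,
                         overlap_threshold = config$overlap_threshold,
                         top_n = config$top_n)
    kw <- data.frame(
      topic = rep(seq_along(sel$keywords), lengths(sel$keywords)),
      rank = unlist(lapply(sel$keywords, seq_along)),
      keyword = unlist(sel$keywords), stringsAsFactors = FALSE)
    utils::write.csv(kw, p("topic_keywords.csv"), row.names = FALSE,
                     fileEncoding = "UTF-8")
    jsonlite::write_json(list(meta = meta, curves = sel$curves,
                              k_upper = sel$k_upper, k_best = sel$k_best,
                              overlap_pairs = sel$overlap_pairs),
                         p("topics.json"), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    if (sel$k_best >= 2L) plot_intertopic(sel$model, p("intertopic.png"))
    msg("topics: k_upper = %d, k_best = %d -> %s",
        sel$k_upper, sel$k_best, p("topics.json"))
    artifacts$topics <- p("topics.json")
  }

  invisible(artifacts)
}
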