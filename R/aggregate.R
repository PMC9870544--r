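#' Corpus emotion and sentiment distribution
#'
#' Counts posts per emotion label (eight categories plus neutral) and rolls
#' them up to sentiment (positive/neutral/negative), with percentages of the
#' total. Emotion percentages print at 2 decimals and sentiment rollups at
#' `rollup_digits` (default 1), matching the mixed precision conventional in
#' reported tables.
#'
#' @param labels character vector of post labels.
#' @param digits decimals for emotion percentages (default 2).
#' @param rollup_digits decimals for sentiment percentages (default 2).
#' @return An object of class `distribution_table`: `emotions` data.frame
#'   (emotion, count, percentage), `sentiments` data.frame, `total`.
#' @export
emotion_distribution <- function(labels, digits = 2L, rollup_digits = 2L) {
  if (length(labels) == 0L) stop("empty corpus")
  bad <- setdiff(unique(labels), emotion_labels())
  if (length(bad) > 0L) stop("unknown label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(labels, levels = display_order()))
  distribution_from_counts(as.integer(counts),
                           names(counts), digits, rollup_digits)
}

display_order <- function() {
  c("good", "joy", "surprise", "anticipate", "neutral",
    "fear", "disgust", "sadness", "anger")
}

#' @rdname emotion_distribution
#' @param counts integer vector of per-label counts.
#' @param label_names label names matching `counts`.
#' @export
distribution_from_counts <- function(counts, label_names = display_order(),
                                     digits = 2L, rollup_digits = 2L) {
  stopifnot(length(counts) == length(label_names), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("empty corpus")
  emotions <- data.frame(
    emotion = label_names, count = as.integer(counts),
    percentage = round_half_up(100 * counts / total, digits),
    stringsAsFactors = FALSE
  )
  sent <- category_sentiment(label_names)
  scount <- vapply(sentiment_labels(),
                   function(s) sum(counts[sent == s]), numeric(1))
  sentiments <- data.frame(
    sentiment = sentiment_labels(), count = as.integer(scount),
    percentage = round_half_up(100 * scount / total, rollup_digits),
    stringsAsFactors = FALSE
  )
  structure(list(emotions = emotions, sentiments = sentiments,
                 total = total),
            class = "distribution_table")
}

#' @export
print.distribution_table <- function(x, ...) {
  cat(sprintf("Corpus distribution (n = %d)\n", x$total))
  print(x$emotions, row.names = FALSE)
  cat("\nSentiment rollup:\n")
  print(x$sentiments, row.names = FALSE)
  invisible(x)
}

#' Compare sentiment distributions of two user groups
#'
#' Builds the 2 (group) x 3 (sentiment) contingency table of post counts and
#' applies Pearson's chi-square test without continuity correction. A warning
#' is attached when any expected cell count falls below 1.
#'
#' @param labels_a,labels_b emotion labels of the two groups (e.g. official
#'   and personal posts).
#' @param group_names names for the two groups.
#' @param rollup_digits decimals for the groups' sentiment percentages.
#' @return An object of class `group_comparison`: two `distribution_table`s,
#'   the contingency `table`, `statistic`, `df`, `p_value`,
#'   `low_expected` flag.
#' @export
compare_groups <- function(labels_a, labels_b,
                           group_names = c("official", "personal"),
                           rollup_digits = 1L) {
  if (length(labels_a) == 0L || length(labels_b) == 0L) {
    stop("both groups must be non-empty")
  }
  da <- emotion_distribution(labels_a, rollup_digits = rollup_digits)
  db <- emotion_distribution(labels_b, rollup_digits = rollup_digits)
  tab <- rbind(da$sentiments$count, db$sentiments$count)
  dimnames(tab) <- list(group = group_names, sentiment = sentiment_labels())
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(ht$expected < 1)
  if (low) warning("expected cell count below 1; chi-square approximation is weak")
  structure(list(
    distributions = stats::setNames(list(da, db), group_names),
    table = tab, statistic = unname(ht$statistic),
    df = unname(ht$parameter), p_value = unname(ht$p.value),
    low_expected = low
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$table)
  cat(sprintf("\nPearson chi-square = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Daily post counts for one emotion and user type
#'
#' Zero-filled calendar-day counts over `span` (default: the corpus date
#' range). `scale_to` rescales the counts by `sum(scale_to)/sum(counts)` so
#' that two series of very different volume can be compared on one axis (the
#' usual official-versus-personal scaling).
#'
#' @param posts data.frame with `posted_at` and `label` columns
#'   (and `user_type` when filtering by it).
#' @param emotion emotion label to select (NULL for all posts).
#' @param user_type optional user type filter.
#' @param span optional Date vector of length 2.
#' @param scale_to optional numeric vector (e.g. the other group's counts) to
#'   scale this series toward.
#' @return A data.frame of class `daily_series`: `date`, `count`, `scaled`.
#' @export
daily_series <- function(posts, emotion = NULL, user_type = NULL,
                         span = NULL, scale_to = NULL) {
  stopifnot("posted_at" %in% names(posts))
  all_days <- as.Date(posts$posted_at)
  if (is.null(span)) span <- range(all_days, na.rm = TRUE)
  sel <- rep(TRUE, nrow(posts))
  if (!is.null(emotion)) sel <- sel & posts$label == emotion
  if (!is.null(user_type)) sel <- sel & posts$user_type == user_type
  days <- seq(span[1], span[2], by = "day")
  counts <- table(factor(as.character(all_days[sel]),
                         levels = as.character(days)))
  out <- data.frame(date = days, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$scaled <- if (!is.null(scale_to) && sum(out$count) > 0) {
    out$count * sum(scale_to) / sum(out$count)
  } else {
    as.numeric(out$count)
  }
  class(out) <- c("daily_series", "data.frame")
  out
}

#' Lead-lag between two daily series
#'
#' Finds the lag in [-max_lag, max_lag] maximizing the Pearson correlation
#' between `a[t]` and `b[t + lag]`; a positive lag means `b` follows `a`
#' (e.g. personal posts echoing official posts one day later give +1). Ties
#' are broken toward the smallest |lag|, then the smaller lag.
#'
#' @param a,b equal-length numeric series (length > max_lag + 2).
#' @param max_lag maximum |lag| in days (default 7).
#' @return List with `lag`, `correlation` and the full `by_lag` data.frame.
#' @export
lead_lag <- function(a, b, max_lag = 7L) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  if (length(a) <= max_lag + 2L) stop("series too short for max_lag")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant series: correlation undefined")
  }
  lags <- seq(-max_lag, max_lag)
  cors <- vapply(lags, function(L) {
    t0 <- max(1L, 1L - L); t1 <- min(length(a), length(b) - L)
    ai <- a[t0:t1]; bi <- b[(t0 + L):(t1 + L)]
    if (stats::sd(ai) == 0 || stats::sd(bi) == 0) return(NA_real_)
    stats::cor(ai, bi)
  }, numeric(1))
  ok <- which(!is.na(cors))
  if (length(ok) == 0L) stop("constant series in every overlap window")
  best_cor <- max(cors[ok])
  cand <- ok[cors[ok] >= best_cor - 1e-12]
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  best <- cand[1L]
  list(lag = lags[best], correlation = cors[best],
       by_lag = data.frame(lag = lags, correlation = cors))
}

#' Plot two scaled daily series
#'
#' Base-graphics line chart of an official series and a (scaled) personal
#' series, for the lead-lag comparison.
#'
#' @param x a `daily_series`.
#' @param y optional second `daily_series` drawn for comparison.
#' @param ... passed to [graphics::plot()].
#' @export
plot.daily_series <- function(x, y = NULL, ...) {
  graphics::plot(x$date, x$scaled, type = "l", xlab = "date",
                 ylab = "posts (scaled)", ...)
  if (!is.null(y)) {
    graphics::lines(y$date, y$scaled, lty = 2, col = "grey40")
    graphics::legend("topright", legend = c("series A", "series B"),
                     lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  }
  invisible(x)
}
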