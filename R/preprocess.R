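#' Resolve a relative posting time against the crawl time
#'
#' Crawled post tables carry posting times as "x seconds/minutes/hours ago",
#' "today HH:MM" (今天 HH:MM) or an absolute date-time. All forms are resolved
#' to an absolute timestamp using the record's `current_time` (crawl time).
#'
#' @param posting_time character vector of posting-time strings.
#' @param current_time a POSIXct (scalar or same length) crawl time.
#' @param tz time zone used for absolute forms (default "UTC").
#' @return POSIXct vector.
#' @export
#' @examples
#' now <- as.POSIXct("2022-07-05 10:00:00", tz = "UTC")
#' parse_relative_time("5分钟前", now)
parse_relative_time <- function(posting_time, current_time, tz = "UTC") {
  posting_time <- trimws(as.character(posting_time))
  if (length(current_time) == 1L) {
    current_time <- rep(current_time, length(posting_time))
  }
  stopifnot(length(current_time) == length(posting_time))
  out <- as.POSIXct(rep(NA_real_, length(posting_time)),
                    origin = "1970-01-01", tz = tz)
  for (i in seq_along(posting_time)) {
    out[i] <- parse_one_time(posting_time[i], current_time[i], tz)
  }
  out
}

parse_one_time <- function(s, now, tz) {
  specs <- list(
    c("^([0-9]+)\\s*(秒前|seconds? ago)$", 1),
    c("^([0-9]+)\\s*(分钟前|minutes? ago)$", 60),
    c("^([0-9]+)\\s*(小时前|hours? ago)$", 3600)
  )
  for (sp in specs) {
    if (grepl(sp[[1]], s, perl = TRUE)) {
      n <- as.numeric(sub(sp[[1]], "\\1", s, perl = TRUE))
      return(now - n * as.numeric(sp[[2]]))
    }
  }
  m <- regmatches(s, regexec("^(今天|[Tt]oday)\\s+([0-2]?[0-9]):([0-5][0-9])$", s))[[1]]
  if (length(m) == 4L) {
    day <- format(now, "%Y-%m-%d", tz = tz)
    return(as.POSIXct(sprintf("%s %s:%s:00", day, m[3], m[4]), tz = tz))
  }
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y/%m/%d %H:%M",
                "%Y-%m-%d")) {
    v <- as.POSIXct(s, format = fmt, tz = tz)
    if (!is.na(v)) return(v)
  }
  m <- regmatches(s, regexec(
    "^([0-9]{1,2})月([0-9]{1,2})日\\s*([0-2]?[0-9]):([0-5][0-9])$", s))[[1]]
  if (length(m) == 5L) {
    yr <- format(now, "%Y", tz = tz)
    return(as.POSIXct(sprintf("%s-%02d-%02d %s:%s:00", yr,
                              as.integer(m[2]), as.integer(m[3]), m[4], m[5]),
                      tz = tz))
  }
  stop("unrecognized posting time: '", s, "'")
}

#' Extract the user ID from a profile link
#'
#' Accepts both `weibo.com/<digits>` and `weibo.com/u/<digits>` profile-URL
#' dialects; query strings are ignored.
#'
#' @param publisher_link character vector of profile URLs.
#' @return Character vector of user IDs.
#' @export
#' @examples
#' extract_user_id("https://weibo.com/7412756093?refer_flag=1001030103")
extract_user_id <- function(publisher_link) {
  m <- regmatches(publisher_link,
                  regexpr("weibo\\.com/(u/)?[0-9]+", publisher_link))
  ok <- lengths(regmatches(publisher_link,
                           gregexpr("weibo\\.com/(u/)?[0-9]+", publisher_link))) > 0
  if (any(!ok)) {
    stop("no user ID segment in link(s): ",
         paste(utils::head(publisher_link[!ok], 3L), collapse = ", "))
  }
  sub(".*?([0-9]+)$", "\\1", m)
}

#' Clean post content
#'
#' Always removes paired #...# topic markers (an unpaired # is left intact),
#' user mentions (at-sign handles) and URLs. Stopwords are stripped only on the topic-mining path
#' (`for_topics = TRUE`): stopword lists contain negation and degree words,
#' which the emotion scorer must keep.
#'
#' @param text character vector.
#' @param stopwords character vector (used only when `for_topics = TRUE`).
#' @param for_topics logical; strip stopwords for topic modelling.
#' @return Character vector of cleaned text (possibly empty strings).
#' @export
#' @examples
#' clean_content("#疫情# @某人 http://t.cn/x 加油")
clean_content <- function(text, stopwords = character(), for_topics = FALSE) {
  x <- as.character(text)
  x[is.na(x)] <- ""
  x <- gsub("https?://[A-Za-z0-9./?=&_%#~+-]+", "", x, perl = TRUE)
  # paired topic markers only
  x <- gsub("#[^#]*#", "", x, perl = TRUE)
  x <- gsub("@[-_A-Za-z0-9一-龥]+", "", x, perl = TRUE)
  x <- gsub("[ \t]+", " ", x)
  x <- trimws(x)
  if (for_topics && length(stopwords) > 0L) {
    sw <- stopwords[order(nchar(stopwords), decreasing = TRUE)]
    for (w in sw) x <- gsub(w, "", x, fixed = TRUE)
    x <- trimws(x)
  }
  x
}

#' Classify a user as official or personal
#'
#' A user is official when any keyword matches the username or the profile
#' description after case and character-width normalization; unknown when both
#' fields are empty; personal otherwise.
#'
#' @param username,description character vectors (recycled to equal length).
#' @param keywords non-empty character vector of official-account keywords;
#'   defaults to the packaged editable list, a stand-in for platform-specific
#'   curation.
#' @return Character vector in {"official", "personal", "unknown"}.
#' @export
classify_user <- function(username, description,
                          keywords = readLines(
                            toy_lexicon_path("official_keywords"),
                            encoding = "UTF-8", warn = FALSE)) {
  keywords <- trimws(keywords[trimws(keywords) != ""])
  if (length(keywords) == 0L) stop("keyword list must be non-empty")
  n <- max(length(username), length(description))
  username <- rep_len(as.character(username), n)
  description <- rep_len(as.character(description), n)
  username[is.na(username)] <- ""
  description[is.na(description)] <- ""
  u <- normalize_width(tolower(username))
  d <- normalize_width(tolower(description))
  kw <- normalize_width(tolower(keywords))
  hit <- vapply(seq_len(n), function(i) {
    any(vapply(kw, function(k) grepl(k, u[i], fixed = TRUE) ||
                                grepl(k, d[i], fixed = TRUE), logical(1)))
  }, logical(1))
  out <- ifelse(hit, "official", "personal")
  out[u == "" & d == ""] <- "unknown"
  out
}

# full-width ASCII -> half-width; ideographic space -> space
normalize_width <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || s == "") return(s)
    cp <- utf8ToInt(s)
    full <- cp >= 0xFF01 & cp <= 0xFF5E
    cp[full] <- cp[full] - 0xFEE0L
    cp[cp == 0x3000] <- 32L
    intToUtf8(cp)
  }, "", USE.NAMES = FALSE)
}

#' Preprocess a raw crawled post table
#'
#' Deduplicates by (publisher, content), resolves posting times, extracts
#' user IDs, cleans content and assigns user types. Rows whose link yields no
#' user ID get `user_id = NA`; rows with unparseable posting times are dropped
#' with a warning.
#'
#' @param posts data.frame with columns `publisher`, `content`,
#'   `publisher_link`, `posting_time`, `source`, `comments`, `retweets`,
#'   `likes`, `current_time` (order-free, matched by name).
#' @param keywords official-user keyword list; see [classify_user()].
#' @param tz time zone for timestamps.
#' @return A data.frame of cleaned posts: `user_id`, `user_type`,
#'   `content_clean`, `posted_at`, plus the carried-over raw fields.
#' @export
preprocess_posts <- function(posts,
                             keywords = readLines(
                               toy_lexicon_path("official_keywords"),
                               encoding = "UTF-8", warn = FALSE),
                             tz = "UTC") {
  need <- c("publisher", "content", "publisher_link", "posting_time",
            "source", "comments", "retweets", "likes", "current_time")
  missing_cols <- setdiff(need, names(posts))
  if (length(missing_cols) > 0L) {
    stop("post table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  posts <- posts[!duplicated(posts[c("publisher", "content")]), , drop = FALSE]
  now <- as.POSIXct(posts$current_time, tz = tz)
  posted_at <- as.POSIXct(rep(NA_real_, nrow(posts)),
                          origin = "1970-01-01", tz = tz)
  bad_time <- logical(nrow(posts))
  for (i in seq_len(nrow(posts))) {
    posted_at[i] <- tryCatch(parse_one_time(posts$posting_time[i], now[i], tz),
                             error = function(e) {
                               bad_time[i] <<- TRUE
                               as.POSIXct(NA, tz = tz)
                             })
  }
  if (any(bad_time)) {
    warning("dropping ", sum(bad_time), " post(s) with unparseable posting time")
  }
  user_id <- rep(NA_character_, nrow(posts))
  for (i in seq_len(nrow(posts))) {
    user_id[i] <- tryCatch(extract_user_id(posts$publisher_link[i]),
                           error = function(e) NA_character_)
  }
  if (anyNA(user_id)) {
    warning(sum(is.na(user_id)), " post(s) without an extractable user ID")
  }
  out <- data.frame(
    user_id = user_id,
    user_type = classify_user(posts$publisher, "", keywords),
    content_clean = clean_content(posts$content),
    posted_at = posted_at,
    posts,
    stringsAsFactors = FALSE
  )
  out <- out[!bad_time, , drop = FALSE]
  rownames(out) <- NULL
  out
}
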