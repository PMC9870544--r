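now <- as.POSIXct("2022-07-05 10:00:00", tz = "UTC")

test_that("relative posting times resolve against the crawl time", {
  expect_equal(parse_relative_time("5分钟前", now),
               as.POSIXct("2022-07-05 09:55:00", tz = "UTC"))
  expect_equal(parse_relative_time("今天 08:30", now),
               as.POSIXct("2022-07-05 08:30:00", tz = "UTC"))
  expect_equal(parse_relative_time("30秒前", now),
               as.POSIXct("2022-07-05 09:59:30", tz = "UTC"))
  expect_equal(parse_relative_time("2022-07-01 12:00:00", now),
               as.POSIXct("2022-07-01 12:00:00", tz = "UTC"))
  expect_error(parse_relative_time("昨天晚些时候", now), "unrecognized")
})

test_that("parse_relative_time is monotone in the ago quantity", {
  ts <- parse_relative_time(paste0(c(1, 5, 30, 59), "分钟前"), now)
  expect_true(all(diff(as.numeric(ts)) < 0))
  ts2 <- parse_relative_time(paste0(c(10, 20, 50), "秒前"), now)
  expect_true(all(diff(as.numeric(ts2)) < 0))
})

test_that("user IDs are extracted from both profile-link dialects", {
  expect_identical(
    extract_user_id("https://weibo.com/7412756093?refer_flag=1001030103"),
    "7412756093")
  expect_identical(extract_user_id("https://weibo.com/u/123456"), "123456")
  expect_error(extract_user_id("https://weibo.com/"), "no user ID")
})

test_that("content cleaning removes topics, mentions and URLs, and is idempotent", {
  expect_identical(clean_content("#疫情# @某人 http://t.cn/x 加油"), "加油")
  expect_identical(clean_content(""), "")
  # unpaired topic marker is left intact
  expect_identical(clean_content("价格#新高"), "价格#新高")
  cases <- c("#a# @u http://x.cn/1 text", "嵌套#话题#文本@某某人结束",
             "price #rising", "")
  for (x in cases) {
    once <- clean_content(x)
    expect_identical(clean_content(once), once)
  }
})

test_that("stopwords are stripped only on the topic-mining path", {
  sw <- c("不", "的", "了")
  expect_identical(clean_content("不要慌", sw, for_topics = FALSE), "不要慌")
  expect_identical(clean_content("不要慌", sw, for_topics = TRUE), "要慌")
})

test_that("user typing matches keywords after case/width normalization", {
  kw <- readLines(toy_lexicon_path("official_keywords"), encoding = "UTF-8")
  expect_identical(classify_user("XX日报", "官方账号", kw), "official")
  expect_identical(classify_user("小明", "爱生活", kw), "personal")
  expect_identical(classify_user("", "", kw), "unknown")
  # full-width Latin in the name does not defeat a keyword match
  expect_identical(classify_user("ＸＸ日报", "", kw), "official")
  expect_error(classify_user("a", "b", character()), "non-empty")
})

test_that("preprocessing deduplicates by publisher and content", {
  raw <- data.frame(
    publisher = c("甲", "甲", "乙"),
    content = c("同一条内容", "同一条内容", "同一条内容"),
    publisher_link = paste0("https://weibo.com/", c(111, 111, 222)),
    posting_time = c("5分钟前", "5分钟前", "今天 08:00"),
    source = "web", comments = 0L, retweets = 0L, likes = 0L,
    current_time = "2022-07-05 10:00:00",
    stringsAsFactors = FALSE
  )
  clean <- preprocess_posts(raw)
  expect_equal(nrow(clean), 2L)
  expect_false(any(duplicated(clean[c("publisher", "content")])))
  expect_equal(clean$user_id, c("111", "222"))
  expect_true(all(clean$posted_at <=
                    as.POSIXct(clean$current_time, tz = "UTC")))
})
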