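test_that("distribution counts, percentages and rollups are consistent", {
  labs <- c(rep("good", 3), rep("fear", 2), "neutral")
  d <- emotion_distribution(labs)
  expect_equal(d$total, 6L)
  expect_equal(sum(d$emotions$count), 6L)
  expect_equal(sum(d$sentiments$count), 6L)
  expect_equal(d$emotions$percentage[d$emotions$emotion == "good"], 50)
  expect_equal(d$sentiments$percentage[d$sentiments$sentiment == "negative"],
               round(100 * 2 / 6, 2), tolerance = 0.005)
  expect_equal(sum(d$emotions$percentage), 100, tolerance = 0.05)

  single <- emotion_distribution("good")
  expect_equal(single$emotions$percentage[single$emotions$emotion == "good"],
               100)
  expect_error(emotion_distribution(character()), "empty")
  expect_error(emotion_distribution("meh"), "unknown")
})

test_that("identical groups give chi-square zero and p one", {
  labs <- rep(c("good", "neutral", "fear"), each = 10)
  cmp <- compare_groups(labs, labs)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$df, 2L)
})

test_that("a fully separated 2x2 table gives the hand-computed statistic", {
  cmp <- compare_groups(rep("good", 20), rep("fear", 20))
  expect_equal(cmp$statistic, 40)
  expect_equal(cmp$df, 1L)
  expect_lt(cmp$p_value, 1e-9)
})

test_that("group comparison is symmetric under swapping the groups", {
  set.seed(1)
  a <- sample(c("good", "neutral", "fear"), 60, TRUE, prob = c(0.5, 0.3, 0.2))
  b <- sample(c("good", "neutral", "fear"), 80, TRUE, prob = c(0.2, 0.3, 0.5))
  c1 <- compare_groups(a, b)
  c2 <- compare_groups(b, a)
  expect_equal(c1$statistic, c2$statistic)
  expect_equal(c1$p_value, c2$p_value)
})

test_that("p-values are roughly uniform when groups share one multinomial", {
  set.seed(7)
  p <- replicate(200, {
    a <- sample(c("good", "neutral", "fear"), 150, TRUE,
                prob = c(0.4, 0.3, 0.3))
    b <- sample(c("good", "neutral", "fear"), 150, TRUE,
                prob = c(0.4, 0.3, 0.3))
    compare_groups(a, b)$p_value
  })
  expect_lt(mean(p < 0.05), 0.12)
  expect_gt(mean(p), 0.35)
  expect_lt(mean(p), 0.65)
})

test_that("daily series are zero-filled and sum to the selected posts", {
  posts <- data.frame(
    posted_at = as.POSIXct(c("2022-07-02 10:00:00", "2022-07-02 11:00:00",
                             "2022-07-02 12:00:00", "2022-07-05 09:00:00"),
                           tz = "UTC"),
    label = c("fear", "fear", "fear", "good"),
    user_type = "personal",
    stringsAsFactors = FALSE
  )
  s <- daily_series(posts, "fear")
  expect_equal(nrow(s), 4L)  # 07-02 .. 07-05
  expect_equal(s$count, c(3L, 0L, 0L, 0L))
  expect_equal(sum(s$count), sum(posts$label == "fear"))

  empty <- daily_series(posts, "anger")
  expect_true(all(empty$count == 0L))

  # scaling makes series totals comparable
  s2 <- daily_series(posts, "fear", scale_to = c(6, 6))
  expect_equal(sum(s2$scaled), 12)
})

test_that("lead_lag recovers a constructed shift and rejects constants", {
  a <- c(1, 2, 5, 9, 5, 2, 1, 1, 2, 3, 2, 1, 0, 1)
  b <- c(0, a[-length(a)])  # b follows a by one day
  ll <- lead_lag(a, b, max_lag = 4)
  expect_equal(ll$lag, 1L)
  expect_equal(ll$correlation, 1, tolerance = 1e-12)
  expect_equal(lead_lag(a, a, max_lag = 4)$lag, 0L)
  expect_error(lead_lag(rep(1, 14), a, max_lag = 4), "constant")
  expect_error(lead_lag(a, b, max_lag = 13), "too short")

  set.seed(3)
  x <- rnorm(80); y <- rnorm(80)
  expect_lt(abs(lead_lag(x, y, max_lag = 5)$correlation), 0.45)
})
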