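lex <- default_lexicon()
matcher <- compile_lexicon(lex)

test_that("tokenization lowercases, strips sigils and urls, splits on punctuation", {
  expect_equal(as.vector(normalize_text("#ColonCancer screening!")),
               c("coloncancer", "screening"))
  expect_equal(attr(normalize_text("#ColonCancer screening!"), "offsets"),
               c(2L, 14L))
  expect_equal(as.vector(normalize_text("")), character(0))
  expect_equal(as.vector(normalize_text("Latinx/Latina voices")),
               c("latinx", "latina", "voices"))
  expect_equal(as.vector(normalize_text("read https://t.co/xyz now")),
               c("read", "now"))
  expect_equal(as.vector(normalize_text("ping @Some_User ok",
                                        exclude_mentions = TRUE)),
               c("ping", "ok"))
})

test_that("lexicon validation rejects malformed patterns", {
  expect_error(compile_lexicon(tibble::tibble(category = "black",
                                              pattern = "bl*ck")),
               "wildcard", class = "equityreach_schema_error")
  expect_error(compile_lexicon(tibble::tibble(category = "black",
                                              pattern = " ")),
               class = "equityreach_schema_error")
  expect_error(compile_lexicon(tibble::tibble(category = "purple",
                                              pattern = "x")),
               class = "equityreach_schema_error")
})

test_that("wildcard, phrase, and whole-token semantics", {
  m <- compile_lexicon(tibble::tibble(
    category = c("black", "crc_topic", "people_of_color"),
    pattern = c("black*", "colon cancer", "poc")))
  tag1 <- match_equity("blackhistorymonth events", m)
  expect_equal(tag1$equity_categories[[1]], "black")
  expect_true(match_crc("my colon cancer story", m))
  expect_false(match_crc("my colon story about cancer", m)) # not adjacent
  tag2 <- match_equity("a pocket guide", m)
  expect_equal(tag2$equity_categories[[1]], character(0))
  tag3 <- match_equity("resources for poc families", m)
  expect_equal(tag3$equity_categories[[1]], "people_of_color")
})

test_that("crc tagging matches the keyword list including hashtag forms", {
  expect_true(match_crc("Colorectal cancer screening saves lives", matcher))
  expect_false(match_crc("I love cancer research", matcher))
  expect_true(match_crc("#coloncancer awareness", matcher))
  expect_true(match_crc("big #ColorectalCancer news", matcher))
})

test_that("equity tagging returns all matching categories with audit trail", {
  t1 <- match_equity(
    "African Americans have the highest incidence of #colorectalcancer", matcher)
  expect_true(t1$is_crc)
  expect_equal(t1$equity_categories[[1]], "black")
  expect_true(t1$is_equity)
  expect_true("african american*" %in% t1$matched_terms[[1]]$pattern)

  t2 <- match_equity(
    "Promote colonoscopy screening among low-income Latinos #ColorectalCancer",
    matcher)
  expect_equal(t2$equity_categories[[1]], "hispanic_latino")

  t3 <- match_equity("Great colonoscopy today", matcher)
  expect_equal(t3$equity_categories[[1]], character(0))
  expect_false(t3$is_equity)

  # multiple categories are all reported
  t4 <- match_equity(
    "colon cancer burden among Black and Hispanic communities of color", matcher)
  expect_equal(t4$equity_categories[[1]],
               c("black", "hispanic_latino", "people_of_color"))
})

test_that("a crc-only match is not an equity tweet and vice versa", {
  tags <- tag_tweets(c("colon cancer update",
                       "Black health matters",
                       "colon cancer burden on Black families"), matcher)
  expect_equal(tags$is_crc, c(TRUE, FALSE, TRUE))
  expect_equal(tags$is_equity, c(FALSE, FALSE, TRUE))
})

random_texts <- function(n, seed) {
  vocab <- c("screening", "saves", "lives", "black", "blacks",
             "blackhistorymonth", "pocket", "poc", "brown", "browns",
             "sister", "sisterhood", "latino", "latinos", "latinx",
             "hispanic", "hispanics", "asian", "asians", "asiatic",
             "indigenous", "native", "american", "americans", "african",
             "colon", "cancer", "colorectal", "coloncancer",
             "colorectalcancer", "minority", "minorities", "minor",
             "colored", "colorful", "racism", "racial", "disparity",
             "disparities", "community", "communities", "of", "color",
             "woman", "woc", "people", "#ColonCancer", "#BlackHealth",
             "@sista_org", "https://t.co/abc123", "m4bl", "blm", "blk",
             "af", "brotha", "sista", "indian", "latina", "latinas", "RT")
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(vocab, sample(3:12, 1), replace = TRUE), collapse = " ")
    }, character(1))
  })
}

test_that("matcher equals the brute-force entry-by-entry oracle", {
  texts <- random_texts(300, seed = 11)
  tags <- tag_tweets(texts, matcher)
  for (i in seq_along(texts)) {
    want <- oracle_tag(texts[i], lex)
    expect_equal(tags$is_crc[i], want$is_crc, info = texts[i])
    expect_equal(tags$equity_categories[[i]], want$categories, info = texts[i])
  }
})

test_that("adding entries never removes matches; removing a category empties it", {
  texts <- random_texts(80, seed = 12)
  base <- tag_tweets(texts, matcher)
  bigger <- compile_lexicon(rbind(lex, tibble::tibble(
    category = "people_of_color", pattern = "underserved")))
  more <- tag_tweets(texts, bigger)
  for (i in seq_along(texts)) {
    expect_true(all(base$equity_categories[[i]] %in% more$equity_categories[[i]]))
    expect_true(base$is_crc[i] <= more$is_crc[i])
  }
  no_black <- compile_lexicon(lex[lex$category != "black", ])
  less <- tag_tweets(texts, no_black)
  for (i in seq_along(texts)) {
    expect_equal(less$equity_categories[[i]],
                 setdiff(base$equity_categories[[i]], "black"))
  }
})

test_that("tagging is deterministic and order-invariant", {
  texts <- random_texts(50, seed = 13)
  tweets <- tibble::tibble(tweet_id = sprintf("t%02d", seq_along(texts)),
                           text = texts)
  a <- tag_tweets(tweets, matcher)
  b <- tag_tweets(tweets[rev(seq_len(nrow(tweets))), ], matcher)
  b <- b[match(a$tweet_id, b$tweet_id), ]
  expect_equal(a$is_crc, b$is_crc)
  expect_equal(a$equity_categories, b$equity_categories)
})

test_that("mention bodies are matchable by default and excludable on request", {
  txt <- "salute @sista_org for the outreach on colon cancer"
  with_m <- match_equity(txt, matcher)
  expect_equal(with_m$equity_categories[[1]], "black")
  tags <- tag_tweets(txt, matcher, exclude_mentions = TRUE)
  expect_equal(tags$equity_categories[[1]], character(0))
})

test_that("timestamp window filtering is inclusive and optional", {
  tweets <- mk_tweets("a", c("x", "y", "z"),
                      ts = as.POSIXct(c("2018-12-31", "2020-06-01", "2022-01-05"),
                                      tz = "UTC"))
  got <- filter_tweets(tweets, from = "2019-01-01T00:00:00Z",
                       to = "2021-12-31T23:59:59Z")
  expect_equal(got$text, "y")
  expect_equal(nrow(filter_tweets(tweets)), 3)
})
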