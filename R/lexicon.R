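#' @title Keyword-dictionary tagging of tweets
#' @description
#' Tweets are tagged along two axes: topical relevance to colorectal cancer
#' (CRC) via a small keyword list, and mention of historically minoritized
#' racial/ethnic groups via a five-category dictionary (people of color,
#' Black, Hispanic/Latino, Indigenous, Asian). An *equity tweet* is a CRC
#' tweet matching at least one group category.
#'
#' Pattern language: patterns are matched against normalized tokens
#' (see [normalize_text()]). A pattern is a single token or a
#' whitespace-separated phrase matched over consecutive tokens; a terminal
#' `*` on a token matches any (possibly empty) alphanumeric suffix, so
#' `black*` covers `black`, `blacks`, and hashtag-style compounds like
#' `blackhistorymonth`. Non-wildcard tokens require whole-token equality
#' (`poc` never matches `pocket`). Matching is case-insensitive because
#' tokens are lowercased.
#' @name equity_lexicon
NULL

EQUITY_CATEGORIES <- c("people_of_color", "black", "hispanic_latino",
                       "indigenous", "asian")
LEXICON_CATEGORIES <- c(EQUITY_CATEGORIES, "crc_topic")

#' Tokenize tweet text
#'
#' Lowercases, removes URLs, then splits on every non-alphanumeric character,
#' which also strips `#`/`@` sigils from hashtag and mention heads (the body
#' is kept as a single token: `#ColonCancer` becomes `coloncancer`; compound
#' hashtags are not word-segmented). Character offsets of each token in the
#' original string are kept for audit.
#'
#' @param text A single string.
#' @param exclude_mentions If `TRUE`, `@`-mention bodies are dropped from the
#'   token stream (so dictionary terms inside account names cannot match).
#' @return Character vector of tokens with integer attribute `offsets`
#'   (start position of each token in `text`).
#' @examples
#' normalize_text("#ColonCancer screening!") # "coloncancer" "screening"
#' @export
normalize_text <- function(text, exclude_mentions = FALSE) {
  stopifnot(length(text) == 1)
  if (is.na(text)) text <- ""
  x <- tolower(text)
  x <- blank_out(x, "https?://[^[:space:]]+|www\\.[^[:space:]]+")
  if (exclude_mentions) x <- blank_out(x, "@[a-z0-9_]+")
  m <- gregexpr("[a-z0-9]+", x)[[1]]
  if (m[1] == -1) {
    return(structure(character(0), offsets = integer(0)))
  }
  structure(
    substring(x, m, m + attr(m, "match.length") - 1L),
    offsets = as.integer(m)
  )
}

# replace every regex match with spaces of equal length (offsets preserved)
blank_out <- function(x, pattern) {
  m <- gregexpr(pattern, x)
  regmatches(x, m) <- lapply(regmatches(x, m),
                             function(s) strrep(" ", nchar(s)))
  x
}

#' The packaged CRC equity lexicon
#'
#' Returns the default dictionary shipped with the package: CRC topic
#' keywords (`coloncancer`, `colorectalcancer`, `colon cancer`,
#' `colorectal cancer`) plus the five racial/ethnic-group categories.
#' Deliberately high-recall: ambiguous terms (`brown`, `colored`, `sister`,
#' ...) are retained, with match provenance supporting downstream human
#' review.
#'
#' @param path Optional path to a lexicon CSV (columns `category`,
#'   `pattern`) to load instead of the packaged default.
#' @return Tibble with columns `category`, `pattern`.
#' @export
default_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "equity_lexicon.csv", package = "equityreach",
                        mustWork = TRUE)
  }
  lex <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  require_cols(lex, c("category", "pattern"), "lexicon")
  lex
}

#' Compile a lexicon into a matcher
#'
#' Validates entries and indexes them for matching: single-token exact
#' entries, terminal-wildcard prefix entries, and multi-token phrases
#' (whose final token may carry a terminal wildcard).
#'
#' @param entries Tibble with columns `category`, `pattern`. Categories must
#'   be among `r paste(LEXICON_CATEGORIES, collapse = ", ")`.
#' @return An `equity_matcher` object.
#' @export
compile_lexicon <- function(entries) {
  require_cols(entries, c("category", "pattern"), "lexicon")
  entries <- tibble::as_tibble(entries)
  bad_cat <- setdiff(unique(entries$category), LEXICON_CATEGORIES)
  if (length(bad_cat) > 0) {
    abort_schema("unknown lexicon category: %s", paste(bad_cat, collapse = ", "))
  }
  if (any(!nzchar(trimws(entries$pattern)))) {
    abort_schema("lexicon patterns must be non-empty")
  }
  toks <- strsplit(tolower(trimws(entries$pattern)), "\\s+")
  ok <- vapply(toks, function(tt) all(grepl("^[a-z0-9]+\\*?$", tt)), logical(1))
  if (any(!ok)) {
    abort_schema("invalid pattern (wildcard '*' is only allowed at the end of a token): %s",
                 paste(entries$pattern[!ok], collapse = ", "))
  }
  compiled <- tibble::tibble(
    category = entries$category,
    pattern = entries$pattern,
    tokens = toks,
    n_tokens = lengths(toks)
  )
  structure(list(entries = compiled), class = "equity_matcher")
}

#' @export
print.equity_matcher <- function(x, ...) {
  cat(sprintf("<equity matcher: %d patterns, categories: %s>\n",
              nrow(x$entries),
              paste(sort(unique(x$entries$category)), collapse = ", ")))
  invisible(x)
}

# does pattern token p (possibly 'prefix*') match each of tokens? vectorized
token_matches <- function(tokens, p) {
  if (endsWith(p, "*")) {
    startsWith(tokens, substr(p, 1, nchar(p) - 1L))
  } else {
    tokens == p
  }
}

#' Match every lexicon entry against a set of tweets
#'
#' The audit-level matcher: one row per (tweet, entry, position) hit.
#'
#' @param tweets Tweet tibble (needs `tweet_id`, `text`), or a character
#'   vector of texts (ids are then `seq_along`).
#' @param matcher An [compile_lexicon()] result.
#' @param exclude_mentions Passed to [normalize_text()].
#' @return Tibble `tweet_id`, `category`, `pattern`, `match` (the matched
#'   token or phrase as it appears in the token stream).
#' @export
match_terms <- function(tweets, matcher, exclude_mentions = FALSE) {
  stopifnot(inherits(matcher, "equity_matcher"))
  if (is.character(tweets)) {
    tweets <- tibble::tibble(tweet_id = as.character(seq_along(tweets)),
                             text = tweets)
  }
  ids <- tweets$tweet_id
  tok_list <- lapply(tweets$text, normalize_text,
                     exclude_mentions = exclude_mentions)
  # long token stream with tweet index; phrase adjacency respects boundaries
  n_tok <- lengths(tok_list)
  tok <- unlist(tok_list, use.names = FALSE)
  tw <- rep.int(seq_along(tok_list), n_tok)
  ent <- matcher$entries
  out <- vector("list", nrow(ent))
  for (i in seq_len(nrow(ent))) {
    pt <- ent$tokens[[i]]
    k <- length(pt)
    if (length(tok) < 1) break
    hit <- token_matches(tok, pt[1])
    if (k > 1) {
      for (j in 2:k) {
        nxt <- c(token_matches(tok[-seq_len(j - 1L)], pt[j]),
                 rep(FALSE, j - 1L))
        same_tweet <- c(tw[-seq_len(j - 1L)] == tw[seq_len(length(tw) - j + 1L)],
                        rep(FALSE, j - 1L))
        hit <- hit & nxt & same_tweet
      }
    }
    idx <- which(hit)
    if (length(idx) > 0) {
      phrase <- tok[idx]
      if (k > 1) {
        for (j in 2:k) phrase <- paste(phrase, tok[idx + j - 1L])
      }
      out[[i]] <- tibble::tibble(
        tweet_id = ids[tw[idx]],
        category = ent$category[i],
        pattern = ent$pattern[i],
        match = phrase
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(tweet_id = character(), category = character(),
                          pattern = character(), match = character())
  }
  dplyr::distinct(res)
}

#' Is each tweet about colorectal cancer?
#'
#' @inheritParams match_terms
#' @return Logical vector, one element per tweet: `TRUE` iff any `crc_topic`
#'   keyword or phrase matches.
#' @export
match_crc <- function(tweets, matcher, exclude_mentions = FALSE) {
  if (is.character(tweets)) {
    tweets <- tibble::tibble(tweet_id = as.character(seq_along(tweets)),
                             text = tweets)
  }
  crc <- compile_lexicon(matcher$entries[matcher$entries$category == "crc_topic",
                                         c("category", "pattern")])
  hits <- match_terms(tweets, crc, exclude_mentions = exclude_mentions)
  tweets$tweet_id %in% hits$tweet_id
}

#' Tag tweets with CRC and equity-group categories
#'
#' The main tagging entry point: applies the full lexicon to every tweet.
#' A tweet is an equity tweet iff it is a CRC tweet *and* mentions at least
#' one racial/ethnic group category. Categories are not mutually exclusive.
#'
#' @inheritParams match_terms
#' @return Tibble with one row per tweet: `tweet_id`, `is_crc`,
#'   `equity_categories` (list-column of category names), `is_equity`, and
#'   `matched_terms` (list-column of audit tibbles: `category`, `pattern`,
#'   `match`).
#' @export
tag_tweets <- function(tweets, matcher, exclude_mentions = FALSE) {
  if (is.character(tweets)) {
    tweets <- tibble::tibble(tweet_id = as.character(seq_along(tweets)),
                             text = tweets)
  }
  hits <- match_terms(tweets, matcher, exclude_mentions = exclude_mentions)
  split_hits <- split(hits[c("category", "pattern", "match")], hits$tweet_id)
  empty <- tibble::tibble(category = character(), pattern = character(),
                          match = character())
  matched <- lapply(tweets$tweet_id, function(id) {
    h <- split_hits[[id]]
    if (is.null(h)) empty else tibble::as_tibble(h)
  })
  cats <- lapply(matched, function(h) {
    sort(unique(h$category[h$category != "crc_topic"]))
  })
  tibble::tibble(
    tweet_id = tweets$tweet_id,
    is_crc = vapply(matched, function(h) any(h$category == "crc_topic"),
                    logical(1)),
    equity_categories = cats,
    is_equity = vapply(matched, function(h) any(h$category == "crc_topic"),
                       logical(1)) & lengths(cats) > 0,
    matched_terms = matched
  )
}

#' Per-tweet equity tag (single-tweet convenience)
#'
#' @param text One tweet text.
#' @param matcher An [compile_lexicon()] result.
#' @return One-row tibble as in [tag_tweets()].
#' @export
match_equity <- function(text, matcher) {
  tag_tweets(tibble::tibble(tweet_id = "t", text = text), matcher)
}

#' Restrict tweets to a date window
#'
#' Study-design windows (the source data covered 2019-2021) are input-data
#' concerns, applied explicitly rather than hard-coded.
#'
#' @param tweets Tweet tibble.
#' @param from,to Inclusive UTC bounds (anything [parse_utc] accepts, or
#'   POSIXct); `NULL` leaves that side open.
#' @return Filtered tweet tibble.
#' @export
filter_tweets <- function(tweets, from = NULL, to = NULL) {
  ts <- tweets$timestamp
  keep <- rep(TRUE, nrow(tweets))
  if (!is.null(from)) {
    if (!inherits(from, "POSIXct")) from <- parse_utc(from)
    keep <- keep & ts >= from
  }
  if (!is.null(to)) {
    if (!inherits(to, "POSIXct")) to <- parse_utc(to)
    keep <- keep & ts <= to
  }
  tweets[keep, ]
}
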