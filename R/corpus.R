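#' @title Corpus container and validation
#' @description
#' A corpus bundles the three tables the pipeline consumes: accounts, follow
#' edges, and tweets. Tables are plain tibbles so that every downstream step
#' composes with dplyr; `corpus()` enforces the schema and referential
#' integrity once, up front.
#'
#' Schema:
#' * accounts: `account_id`, `handle`, `profile_text`, `is_org` (logical),
#'   `expert_label` (`"expert"`, `"nonexpert"` or `"unlabeled"`),
#'   `follower_count` (optional integer).
#' * edges: `follower_id`, `followee_id`. Followee accounts must exist in the
#'   account table; follower ids may be peripheral (followers-only users
#'   typically have no account row of their own).
#' * tweets: `tweet_id`, `author_id`, `text`, `timestamp` (POSIXct, UTC),
#'   `is_retweet` (logical), `source_tweet_id` (NA unless a retweet).
#' @name corpus
NULL

ACCOUNT_COLS <- c("account_id", "handle", "profile_text", "is_org", "expert_label")
EDGE_COLS <- c("follower_id", "followee_id")
TWEET_COLS <- c("tweet_id", "author_id", "text", "timestamp", "is_retweet",
                "source_tweet_id")
EXPERT_LEVELS <- c("expert", "nonexpert", "unlabeled")

#' Build a validated corpus
#'
#' @param accounts,edges,tweets Data frames following the documented schema
#'   (see [corpus]). `tweets$timestamp` may be POSIXct or ISO-8601 strings.
#' @return An object of class `equityreach_corpus`: a list with tibbles
#'   `accounts`, `edges`, `tweets`.
#' @examples
#' corp <- corpus(
#'   accounts = tibble::tibble(
#'     account_id = c("a1", "a2"), handle = c("h1", "h2"),
#'     profile_text = "", is_org = FALSE, expert_label = "unlabeled"
#'   ),
#'   edges = tibble::tibble(follower_id = "f1", followee_id = "a1"),
#'   tweets = tibble::tibble(
#'     tweet_id = "t1", author_id = "a1", text = "hello",
#'     timestamp = "2020-01-01T00:00:00Z", is_retweet = FALSE,
#'     source_tweet_id = NA_character_
#'   )
#' )
#' @export
corpus <- function(accounts, edges = NULL, tweets = NULL) {
  accounts <- validate_accounts(accounts)
  edges <- validate_edges(edges, accounts)
  tweets <- validate_tweets(tweets, accounts)
  structure(
    list(accounts = accounts, edges = edges, tweets = tweets),
    class = "equityreach_corpus"
  )
}

#' @export
print.equityreach_corpus <- function(x, ...) {
  cat(sprintf(
    "<equityreach corpus: %d accounts (%d orgs), %d follow edges, %d tweets>\n",
    nrow(x$accounts), sum(x$accounts$is_org), nrow(x$edges), nrow(x$tweets)
  ))
  invisible(x)
}

abort_schema <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "equityreach_schema_error")
}

abort_integrity <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "equityreach_integrity_error")
}

require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_schema("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", "))
  }
}

validate_accounts <- function(accounts) {
  if (is.null(accounts)) abort_schema("an account table is required")
  require_cols(accounts, ACCOUNT_COLS, "account")
  accounts <- tibble::as_tibble(accounts)
  accounts$account_id <- as.character(accounts$account_id)
  accounts$is_org <- as.logical(accounts$is_org)
  dup <- accounts$account_id[duplicated(accounts$account_id)]
  if (length(dup) > 0) {
    abort_integrity("duplicate account_id: %s",
                    paste(utils::head(unique(dup), 5), collapse = ", "))
  }
  bad <- setdiff(unique(accounts$expert_label), EXPERT_LEVELS)
  if (length(bad) > 0) {
    abort_schema("expert_label must be one of %s; found: %s",
                 paste(EXPERT_LEVELS, collapse = "/"),
                 paste(bad, collapse = ", "))
  }
  if (!"follower_count" %in% names(accounts)) {
    accounts$follower_count <- NA_integer_
  }
  accounts$follower_count <- as.integer(accounts$follower_count)
  accounts[c(ACCOUNT_COLS, "follower_count")]
}

validate_edges <- function(edges, accounts) {
  if (is.null(edges)) {
    edges <- tibble::tibble(follower_id = character(), followee_id = character())
  }
  require_cols(edges, EDGE_COLS, "edge")
  edges <- tibble::as_tibble(edges)[EDGE_COLS]
  edges$follower_id <- as.character(edges$follower_id)
  edges$followee_id <- as.character(edges$followee_id)
  n_self <- sum(edges$follower_id == edges$followee_id)
  n_dup <- sum(duplicated(edges))
  if (n_self + n_dup > 0) {
    message(sprintf("dropping %d self-edge(s) and %d duplicate edge(s)",
                    n_self, n_dup))
    edges <- dplyr::distinct(edges[edges$follower_id != edges$followee_id, ])
  }
  dangling <- setdiff(unique(edges$followee_id), accounts$account_id)
  if (length(dangling) > 0) {
    abort_integrity("edge followee_id not in account table: %s",
                    paste(utils::head(dangling, 5), collapse = ", "))
  }
  edges
}

validate_tweets <- function(tweets, accounts) {
  if (is.null(tweets)) {
    tweets <- tibble::tibble(
      tweet_id = character(), author_id = character(), text = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      is_retweet = logical(), source_tweet_id = character()
    )
  }
  if (!"source_tweet_id" %in% names(tweets)) {
    tweets$source_tweet_id <- NA_character_
  }
  require_cols(tweets, TWEET_COLS, "tweet")
  tweets <- tibble::as_tibble(tweets)[TWEET_COLS]
  for (col in c("tweet_id", "author_id", "text", "source_tweet_id")) {
    tweets[[col]] <- as.character(tweets[[col]])
  }
  tweets$is_retweet <- as.logical(tweets$is_retweet)
  if (!inherits(tweets$timestamp, "POSIXct")) {
    parsed <- parse_utc(as.character(tweets$timestamp))
    bad <- is.na(parsed) & !is.na(tweets$timestamp)
    if (any(bad)) {
      message(sprintf("rejecting %d tweet(s) with malformed timestamps", sum(bad)))
      tweets <- tweets[!bad, ]
      parsed <- parsed[!bad]
    }
    tweets$timestamp <- parsed
  }
  attr(tweets$timestamp, "tzone") <- "UTC"
  dup <- tweets$tweet_id[duplicated(tweets$tweet_id)]
  if (length(dup) > 0) {
    abort_integrity("duplicate tweet_id: %s",
                    paste(utils::head(unique(dup), 5), collapse = ", "))
  }
  unknown <- setdiff(unique(tweets$author_id), accounts$account_id)
  if (length(unknown) > 0) {
    abort_integrity("tweet author_id not in account table: %s",
                    paste(utils::head(unknown, 5), collapse = ", "))
  }
  rt_mismatch <- xor(tweets$is_retweet, !is.na(tweets$source_tweet_id))
  if (any(rt_mismatch)) {
    abort_integrity("source_tweet_id must be present iff is_retweet (%d row(s))",
                    sum(rt_mismatch))
  }
  tweets
}

# Accepts "2020-01-02T03:04:05Z", with offset, or space-separated; returns UTC.
parse_utc <- function(x) {
  x <- sub(" ", "T", trimws(x), fixed = TRUE)
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-]\\d\\d):(\\d\\d)$", "\\1\\2", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  bare <- is.na(out)
  if (any(bare)) {
    out[bare] <- as.POSIXct(x[bare], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  out
}

format_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Read a corpus from disk
#'
#' Reads the account, edge, and tweet files and returns a validated
#' [corpus()]. Edges are always CSV; accounts and tweets may be CSV or
#' JSON-lines (one JSON object per line).
#'
#' @param accounts_path,edges_path,tweets_path File paths. `tweets_path` may
#'   be `NULL` for a tweet-less corpus.
#' @param format `"csv"` or `"jsonl"` for the account/tweet files.
#' @return An `equityreach_corpus`.
#' @export
read_corpus <- function(accounts_path, edges_path, tweets_path = NULL,
                        format = c("csv", "jsonl")) {
  format <- rlang::arg_match(format)
  accounts <- read_table_file(accounts_path, format)
  edges <- read_table_file(edges_path, "csv")
  tweets <- if (is.null(tweets_path)) NULL else read_table_file(tweets_path, format)
  if (!is.null(tweets) && nrow(tweets) == 0 && !"tweet_id" %in% names(tweets)) {
    tweets <- NULL # empty jsonl carries no schema
  }
  corpus(accounts, edges, tweets)
}

#' Write a corpus to a directory
#'
#' Inverse of [read_corpus()]: writes `accounts.<fmt>`, `edges.csv`,
#' `tweets.<fmt>` under `dir`.
#'
#' @param corp An `equityreach_corpus`.
#' @param dir Output directory (created if absent).
#' @param format `"csv"` or `"jsonl"` for accounts and tweets.
#' @return The paths written, invisibly.
#' @export
write_corpus <- function(corp, dir, format = c("csv", "jsonl")) {
  format <- rlang::arg_match(format)
  stopifnot(inherits(corp, "equityreach_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "csv") "csv" else "jsonl"
  paths <- c(
    accounts = file.path(dir, paste0("accounts.", ext)),
    edges = file.path(dir, "edges.csv"),
    tweets = file.path(dir, paste0("tweets.", ext))
  )
  tweets <- corp$tweets
  tweets$timestamp <- format_utc(tweets$timestamp)
  write_table(corp$accounts, paths[["accounts"]], format)
  write_table(corp$edges, paths[["edges"]], "csv")
  write_table(tweets, paths[["tweets"]], format)
  invisible(paths)
}

#' Write a derived table to CSV or JSON-lines
#'
#' @param records A data frame.
#' @param path Output file path.
#' @param format `"csv"` (UTF-8, comma, quoted, header row) or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("csv", "jsonl")) {
  format <- rlang::arg_match(format)
  stopifnot(is.data.frame(records))
  if (format == "csv") {
    readr::write_csv(records, path, na = "NA", progress = FALSE)
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(records) > 0) {
      lines <- vapply(seq_len(nrow(records)), function(i) {
        as.character(jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                                      na = "null", digits = NA))
      }, character(1))
      writeLines(lines, con, useBytes = FALSE)
    }
  }
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @inheritParams write_table
#' @return A tibble; character ids are never coerced to numbers.
#' @export
read_table_file <- function(path, format = c("csv", "jsonl")) {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) abort_schema("file does not exist: %s", path)
  if (format == "csv") {
    id_cols <- c("account_id", "follower_id", "followee_id", "tweet_id",
                 "author_id", "source_tweet_id", "handle", "profile_text",
                 "text")
    header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                    progress = FALSE))
    spec <- stats::setNames(
      lapply(header, function(nm) {
        if (nm %in% id_cols) readr::col_character() else readr::col_guess()
      }),
      header
    )
    out <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE,
                           col_types = do.call(readr::cols, spec))
    tibble::as_tibble(out)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(tibble::tibble())
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
      x[vapply(x, is.null, logical(1))] <- NA
      tibble::as_tibble(x)
    })
    dplyr::bind_rows(rows)
  }
}

# --- tweet deduplication ------------------------------------------------

#' Normalize tweet text for duplicate detection
#'
#' Lowercases, strips URLs and a leading retweet prefix (`rt @handle:`),
#' and collapses runs of whitespace, so that a retweet and its source tweet
#' (and trivially re-spaced copies) fall into one equivalence class.
#'
#' @param text Character vector.
#' @return Character vector of normalized keys.
#' @export
dedupe_key <- function(text) {
  x <- tolower(text)
  x <- gsub("https?://\\S+|www\\.\\S+", " ", x)
  x <- sub("^\\s*rt\\s+@\\S+:?\\s*", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Deduplicate tweets by normalized text
#'
#' Content analyses operate on unique tweets; exposure analyses on all
#' posting events. One representative is kept per normalized-text class
#' ([dedupe_key()]): the earliest timestamp, ties broken by smallest
#' `tweet_id`, so output is deterministic.
#'
#' @param tweets Tweet tibble (see [corpus]).
#' @return Tibble of unique tweets, original columns preserved.
#' @export
dedupe_tweets <- function(tweets) {
  if (nrow(tweets) == 0) return(tweets)
  key <- dedupe_key(tweets$text)
  ord <- order(key, tweets$timestamp, tweets$tweet_id)
  tweets <- tweets[ord, ]
  tweets[!duplicated(key[ord]), ]
}
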