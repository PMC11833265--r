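# Brute-force oracles and tiny fixture builders shared across tests.
# Oracles are deliberately written as direct enumerations, independent of the
# package's join-based implementations.

# -- fixture builders ----------------------------------------------------

mk_accounts <- function(ids, orgs = character(0), experts = character(0),
                        nonexperts = character(0)) {
  tibble::tibble(
    account_id = ids,
    handle = paste0("h_", ids),
    profile_text = "",
    is_org = ids %in% orgs,
    expert_label = ifelse(ids %in% experts, "expert",
                          ifelse(ids %in% nonexperts, "nonexpert", "unlabeled"))
  )
}

mk_edges <- function(...) {
  pairs <- list(...)
  tibble::tibble(
    follower_id = vapply(pairs, `[`, character(1), 1),
    followee_id = vapply(pairs, `[`, character(1), 2)
  )
}

mk_tweets <- function(author_id, text, ts = NULL, is_retweet = FALSE,
                      source = NA_character_) {
  n <- length(text)
  tibble::tibble(
    tweet_id = sprintf("t%03d", seq_len(n)),
    author_id = rep_len(author_id, n),
    text = text,
    timestamp = if (is.null(ts)) {
      as.POSIXct("2020-06-01 12:00:00", tz = "UTC") + seq_len(n)
    } else ts,
    is_retweet = rep_len(is_retweet, n),
    source_tweet_id = rep_len(source, n)
  )
}

# roles table with just the columns exposure/unique-source need
mk_roles <- function(account_id, n_crc_u = 0L, n_eq_u = 0L,
                     n_crc_nu = n_crc_u, n_eq_nu = n_eq_u) {
  tibble::tibble(
    account_id = account_id,
    is_disseminator = TRUE,
    is_expert = NA, is_broker = NA,
    n_crc_tweets_unique = as.integer(rep_len(n_crc_u, length(account_id))),
    n_equity_tweets_unique = as.integer(rep_len(n_eq_u, length(account_id))),
    n_crc_tweets_nonunique = as.integer(rep_len(n_crc_nu, length(account_id))),
    n_equity_tweets_nonunique = as.integer(rep_len(n_eq_nu, length(account_id)))
  )
}

# -- lexicon oracle ------------------------------------------------------

oracle_tokens <- function(text) {
  x <- tolower(text)
  x <- gsub("https?://[^ ]+|www\\.[^ ]+", " ", x)
  toks <- unlist(strsplit(x, "[^a-z0-9]+"))
  toks[nzchar(toks)]
}

oracle_entry_hits <- function(tokens, pattern) {
  pt <- strsplit(tolower(trimws(pattern)), "\\s+")[[1]]
  k <- length(pt)
  n <- length(tokens)
  if (n < k || k == 0) return(FALSE)
  for (i in seq_len(n - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      p <- pt[j]
      tk <- tokens[i + j - 1]
      if (endsWith(p, "*")) {
        pre <- substr(p, 1, nchar(p) - 1L)
        if (substr(tk, 1, nchar(pre)) != pre) { ok <- FALSE; break }
      } else if (tk != p) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# every-entry-against-every-position scan; returns list(is_crc, categories)
oracle_tag <- function(text, lexicon) {
  tokens <- oracle_tokens(text)
  hit <- vapply(seq_len(nrow(lexicon)), function(i) {
    oracle_entry_hits(tokens, lexicon$pattern[i])
  }, logical(1))
  cats <- unique(lexicon$category[hit])
  list(is_crc = "crc_topic" %in% cats,
       categories = sort(setdiff(cats, "crc_topic")))
}

# -- network oracles -----------------------------------------------------

oracle_brokers <- function(edges, disseminators, experts, threshold = 0.5) {
  followees <- split(edges$followee_id, edges$follower_id)
  vapply(stats::setNames(disseminators, disseminators), function(a) {
    fl <- edges$follower_id[edges$followee_id == a]
    if (length(fl) == 0) return(FALSE)
    others <- setdiff(experts, a)
    unexposed <- vapply(fl, function(f) {
      !any(followees[[f]] %in% others)
    }, logical(1))
    mean(unexposed) > threshold
  }, logical(1))
}

# dense incidence-matrix product: followers x accounts %*% count vector
oracle_exposure <- function(edges, counts) {
  accts <- names(counts)
  e <- edges[edges$followee_id %in% accts, ]
  followers <- sort(unique(e$follower_id))
  m <- matrix(0, nrow = length(followers), ncol = length(accts),
              dimnames = list(followers, accts))
  for (i in seq_len(nrow(e))) {
    m[e$follower_id[i], e$followee_id[i]] <- 1
  }
  tibble::tibble(
    follower_id = followers,
    n_followed = as.integer(rowSums(m)),
    n_exposed = as.numeric(m %*% counts),
    n_sources = as.integer(m %*% as.numeric(counts > 0))
  )
}

oracle_unique_source <- function(edges, equity_counts) {
  posters <- names(equity_counts)[equity_counts > 0]
  followees <- split(edges$followee_id, edges$follower_id)
  vapply(stats::setNames(posters, posters), function(a) {
    fl <- edges$follower_id[edges$followee_id == a]
    if (length(fl) == 0) return(0)
    reliant <- vapply(fl, function(f) {
      sum(followees[[f]] %in% posters) == 1
    }, logical(1))
    mean(reliant)
  }, numeric(1))
}

# random graph with expert/disseminator structure for property tests
random_role_graph <- function(seed, n_accounts = 40, n_followers = 400) {
  withr::with_seed(seed, {
    accts <- sprintf("a%03d", seq_len(n_accounts))
    diss <- sort(sample(accts, max(2, round(0.8 * n_accounts))))
    experts <- sort(sample(diss, max(1, round(0.5 * length(diss)))))
    fols <- sprintf("f%05d", seq_len(n_followers))
    k <- sample(1:4, n_followers, replace = TRUE)
    edges <- tibble::tibble(
      follower_id = rep.int(fols, k),
      followee_id = accts[unlist(lapply(k, function(kk) {
        sample.int(n_accounts, kk)
      }))]
    )
    # a hub followee keeps every account present in the graph even when it
    # has no followers of its own
    edges <- dplyr::distinct(dplyr::bind_rows(
      edges, tibble::tibble(follower_id = accts, followee_id = "hub000")))
    counts <- stats::setNames(stats::rpois(length(diss), 2), diss)
    list(edges = edges, disseminators = diss, experts = experts,
         equity_counts = counts)
  })
}
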