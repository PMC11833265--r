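#' @title Network roles: candidates, disseminators, brokers
#' @description
#' Role derivation follows the study design: *candidates* are accounts
#' following at least `min_orgs` of the equity-organization core;
#' *disseminators* are candidates with at least one CRC tweet; a
#' disseminator is a *broker* when strictly more than half of its followers
#' follow no expert account other than (possibly) the focal account itself;
#' an *expert-broker* is both expert and broker. All operations are
#' set/join based on the edge table — the brokerage rule is
#' follower-composition based, not path based, so no graph traversal is
#' needed.
#' @name network_roles
NULL

#' Build a follow graph from an edge table
#'
#' @param edges Tibble with `follower_id`, `followee_id` (directed:
#'   follower -> followee). Self-edges and duplicate pairs are rejected.
#' @return An `follow_graph` object wrapping the validated edge tibble.
#' @export
follow_graph <- function(edges) {
  require_cols(edges, EDGE_COLS, "edge")
  edges <- tibble::as_tibble(edges)[EDGE_COLS]
  edges$follower_id <- as.character(edges$follower_id)
  edges$followee_id <- as.character(edges$followee_id)
  if (any(edges$follower_id == edges$followee_id)) {
    abort_integrity("follow graph must not contain self-edges")
  }
  if (anyDuplicated(edges)) {
    abort_integrity("follow graph must not contain duplicate edges")
  }
  structure(list(edges = edges), class = "follow_graph")
}

as_follow_graph <- function(x) {
  if (inherits(x, "follow_graph")) return(x)
  if (inherits(x, "equityreach_corpus")) return(follow_graph(x$edges))
  follow_graph(x)
}

#' @export
print.follow_graph <- function(x, ...) {
  cat(sprintf("<follow graph: %d edges, %d followers, %d followees>\n",
              nrow(x$edges), dplyr::n_distinct(x$edges$follower_id),
              dplyr::n_distinct(x$edges$followee_id)))
  invisible(x)
}

#' @rdname follow_graph
#' @param graph A `follow_graph`.
#' @param id A single account id.
#' @export
followees_of <- function(graph, id) {
  graph <- as_follow_graph(graph)
  graph$edges$followee_id[graph$edges$follower_id == id]
}

#' @rdname follow_graph
#' @export
followers_of <- function(graph, id) {
  graph <- as_follow_graph(graph)
  graph$edges$follower_id[graph$edges$followee_id == id]
}

graph_ids <- function(graph) {
  unique(c(graph$edges$follower_id, graph$edges$followee_id))
}

#' Select candidate accounts by organization co-following
#'
#' An account qualifies as a candidate when it follows at least `min_orgs`
#' of the organization core accounts; organization accounts themselves are
#' excluded.
#'
#' @param graph A `follow_graph` (or edge tibble / corpus).
#' @param org_ids Character vector of organization account ids.
#' @param min_orgs Minimum number of distinct organizations followed
#'   (default 2).
#' @return Character vector of candidate account ids (sorted).
#' @export
select_candidates <- function(graph, org_ids, min_orgs = 2) {
  graph <- as_follow_graph(graph)
  stopifnot(min_orgs >= 1)
  org_ids <- unique(as.character(org_ids))
  unknown <- setdiff(org_ids, graph_ids(graph))
  if (length(unknown) > 0) {
    abort_integrity("organization id(s) not present in the follow graph: %s",
                    paste(unknown, collapse = ", "))
  }
  e <- graph$edges[graph$edges$followee_id %in% org_ids, ]
  n_orgs_followed <- table(e$follower_id)
  cand <- names(n_orgs_followed)[n_orgs_followed >= min_orgs]
  sort(setdiff(cand, org_ids))
}

#' Identify disseminators among the candidates
#'
#' A candidate becomes a disseminator if it authored at least one
#' CRC-tagged tweet (original or retweet).
#'
#' @param candidates Character vector of candidate ids.
#' @param tags Tag table from [tag_tweets()] (needs `tweet_id`, `is_crc`).
#' @param tweets Tweet tibble (needs `tweet_id`, `author_id`).
#' @return Character vector of disseminator ids (sorted).
#' @export
identify_disseminators <- function(candidates, tags, tweets) {
  crc_ids <- tags$tweet_id[tags$is_crc]
  crc_authors <- unique(tweets$author_id[tweets$tweet_id %in% crc_ids])
  sort(intersect(candidates, crc_authors))
}

#' Classify disseminators as brokers or non-brokers
#'
#' For each disseminator `a`, every follower `f` of `a` counts as
#' "otherwise unexposed" when `f` follows zero accounts in
#' `expert_ids \ {a}` — the focal account itself is excluded, so an
#' expert does not disqualify its own followers. `a` is a broker when the
#' unexposed share strictly exceeds `threshold` (default 0.5). Accounts
#' with zero followers cannot reach anyone and are non-brokers.
#'
#' @param disseminators Character vector of disseminator ids; all must be
#'   known to the graph.
#' @param graph A `follow_graph` (or edge tibble / corpus).
#' @param expert_ids Expert-labeled disseminator ids (subset of
#'   `disseminators`).
#' @param threshold Unexposed-share threshold; brokerage requires a strict
#'   majority at the default 0.5.
#' @return Tibble `account_id`, `n_followers`, `n_unexposed`,
#'   `frac_unexposed`, `is_broker`.
#' @export
classify_brokers <- function(disseminators, graph, expert_ids,
                             threshold = 0.5) {
  graph <- as_follow_graph(graph)
  disseminators <- unique(as.character(disseminators))
  expert_ids <- unique(as.character(expert_ids))
  if (length(setdiff(expert_ids, disseminators)) > 0) {
    abort_integrity("expert_ids must be a subset of the disseminator set")
  }
  missing <- setdiff(disseminators, graph_ids(graph))
  if (length(missing) > 0) {
    abort_integrity("disseminator(s) absent from the follow graph: %s",
                    paste(utils::head(missing, 5), collapse = ", "))
  }
  e <- graph$edges
  # how many experts each follower follows (including, possibly, the focal one)
  n_exp <- dplyr::count(e[e$followee_id %in% expert_ids, ],
                        .data$follower_id, name = "n_experts_followed")
  fa <- e[e$followee_id %in% disseminators, ]
  fa <- dplyr::left_join(fa, n_exp, by = "follower_id")
  fa$n_experts_followed[is.na(fa$n_experts_followed)] <- 0L
  # the follower follows the focal account, so if the focal account is an
  # expert its own edge is inside the count and must be discounted
  fa$n_other_experts <- fa$n_experts_followed -
    as.integer(fa$followee_id %in% expert_ids)
  per_acct <- dplyr::summarise(
    dplyr::group_by(fa, account_id = .data$followee_id),
    n_followers = dplyr::n(),
    n_unexposed = sum(.data$n_other_experts == 0L),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::tibble(account_id = sort(disseminators)),
                          per_acct, by = "account_id")
  out$n_followers[is.na(out$n_followers)] <- 0L
  out$n_unexposed[is.na(out$n_unexposed)] <- 0L
  out$frac_unexposed <- ifelse(out$n_followers == 0, 0,
                               out$n_unexposed / out$n_followers)
  out$is_broker <- out$n_followers > 0 & out$frac_unexposed > threshold
  out
}

#' Derive the full per-account role table
#'
#' Runs candidate selection, disseminator identification, expert labeling,
#' and broker classification, and attaches per-account tweet counts (unique
#' counts from the deduplicated corpus, non-unique from all posting events).
#'
#' @param corp An `equityreach_corpus`.
#' @param tags Tag table from [tag_tweets()] over *all* tweets in `corp`.
#' @param org_ids Organization core ids; defaults to accounts flagged
#'   `is_org`.
#' @param min_orgs Candidate threshold (default 2).
#' @param broker_threshold Passed to [classify_brokers()].
#' @return Tibble with one row per account: `account_id`, `is_candidate`,
#'   `is_disseminator`, `is_expert`, `is_broker`, `is_expert_broker`
#'   (role flags are `NA` outside the stratum where they are defined),
#'   `n_followers`, and tweet counts `n_crc_tweets_unique`,
#'   `n_equity_tweets_unique`, `n_crc_tweets_nonunique`,
#'   `n_equity_tweets_nonunique`.
#' @export
assign_roles <- function(corp, tags, org_ids = NULL, min_orgs = 2,
                         broker_threshold = 0.5) {
  stopifnot(inherits(corp, "equityreach_corpus"))
  if (is.null(org_ids)) org_ids <- corp$accounts$account_id[corp$accounts$is_org]
  graph <- follow_graph(corp$edges)
  candidates <- select_candidates(graph, org_ids, min_orgs)
  disseminators <- identify_disseminators(candidates, tags, corp$tweets)

  labels <- stats::setNames(corp$accounts$expert_label, corp$accounts$account_id)
  unlabeled <- disseminators[labels[disseminators] == "unlabeled"]
  if (length(unlabeled) > 0) {
    abort_integrity(
      "every disseminator needs an expert/nonexpert label; unlabeled: %s",
      paste(utils::head(unlabeled, 5), collapse = ", "))
  }
  expert_ids <- disseminators[labels[disseminators] == "expert"]
  brokers <- classify_brokers(disseminators, graph, expert_ids,
                              threshold = broker_threshold)

  counts_all <- tweet_counts(corp$tweets, tags)
  uniq <- dedupe_tweets(corp$tweets)
  counts_uniq <- tweet_counts(uniq, tags)

  out <- tibble::tibble(account_id = corp$accounts$account_id)
  out$is_candidate <- out$account_id %in% candidates
  out$is_disseminator <- out$account_id %in% disseminators
  out$is_expert <- ifelse(out$is_disseminator,
                          out$account_id %in% expert_ids, NA)
  out <- dplyr::left_join(
    out, brokers[c("account_id", "n_followers", "is_broker")],
    by = "account_id")
  fcount <- dplyr::count(corp$edges, account_id = .data$followee_id,
                         name = "n_followers_all")
  out <- dplyr::left_join(out, fcount, by = "account_id")
  out$n_followers <- dplyr::coalesce(out$n_followers, out$n_followers_all, 0L)
  out$n_followers_all <- NULL
  out$is_expert_broker <- out$is_expert & out$is_broker
  out <- dplyr::left_join(out, counts_uniq, by = "account_id")
  names(out)[names(out) %in% c("n_crc", "n_equity")] <-
    c("n_crc_tweets_unique", "n_equity_tweets_unique")
  out <- dplyr::left_join(out, counts_all, by = "account_id")
  names(out)[names(out) %in% c("n_crc", "n_equity")] <-
    c("n_crc_tweets_nonunique", "n_equity_tweets_nonunique")
  cc <- c("n_crc_tweets_unique", "n_equity_tweets_unique",
          "n_crc_tweets_nonunique", "n_equity_tweets_nonunique")
  for (col in cc) out[[col]] <- dplyr::coalesce(out[[col]], 0L)
  out
}

tweet_counts <- function(tweets, tags) {
  joined <- dplyr::inner_join(tweets[c("tweet_id", "author_id")],
                              tags[c("tweet_id", "is_crc", "is_equity")],
                              by = "tweet_id")
  dplyr::summarise(dplyr::group_by(joined, account_id = .data$author_id),
                   n_crc = sum(.data$is_crc),
                   n_equity = sum(.data$is_equity),
                   .groups = "drop")
}

#' Cross-tabulate expertise and brokerage
#'
#' @param roles Role table from [assign_roles()].
#' @param digits Decimal places for the percentage column (default 0,
#'   matching how such shares are usually quoted).
#' @return Tibble `stratum`, `n`, `denominator`, `pct`: disseminator
#'   counts overall, by expertise, by brokerage, and the expert x broker
#'   cross (expert-broker share is computed among experts).
#' @export
summarize_roles <- function(roles, digits = 0) {
  d <- roles[roles$is_disseminator, ]
  n_d <- nrow(d)
  n_exp <- sum(d$is_expert)
  n_nonexp <- sum(!d$is_expert)
  n_brk <- sum(d$is_broker)
  n_eb <- sum(d$is_expert & d$is_broker)
  n_neb <- sum(!d$is_expert & d$is_broker)
  row <- function(stratum, n, den) {
    tibble::tibble(stratum = stratum, n = n, denominator = den,
                   pct = if (den > 0) pct(n, den, digits) else NA_real_)
  }
  dplyr::bind_rows(
    row("disseminators", n_d, n_d),
    row("experts", n_exp, n_d),
    row("nonexperts", n_nonexp, n_d),
    row("brokers", n_brk, n_d),
    row("nonbrokers", n_d - n_brk, n_d),
    row("expert_brokers", n_eb, n_exp),
    row("expert_nonbrokers", n_exp - n_eb, n_exp),
    row("nonexpert_brokers", n_neb, n_nonexp)
  )
}
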