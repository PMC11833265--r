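#' @title Follower exposure estimation
#' @description
#' Exposure follows a deterministic "follow implies see" model: a follower
#' is potentially exposed to every posting event of every account it
#' follows. Exposure therefore uses *non-unique* counts (originals plus
#' retweets accumulate), while content analyses elsewhere use the
#' deduplicated corpus. All computations are join/aggregate over the edge
#' table; no dense follower-by-account matrix is ever formed.
#' @name exposure
NULL

#' Per-follower exposure table
#'
#' For every follower of at least one disseminator, counts the
#' disseminators followed and the CRC / equity posting events those
#' accounts produced.
#'
#' @param graph A `follow_graph` (or edge tibble / corpus).
#' @param roles Role table from [assign_roles()].
#' @param dedup_mode `"nonunique"` (default; the exposure convention) or
#'   `"unique"` to sum deduplicated tweet counts instead.
#' @return Tibble `follower_id`, `n_followed_disseminators`,
#'   `n_crc_exposed`, `n_equity_exposed`, `n_equity_sources` (number of
#'   followed accounts with at least one equity posting event).
#' @export
exposure_per_follower <- function(graph, roles,
                                  dedup_mode = c("nonunique", "unique")) {
  dedup_mode <- rlang::arg_match(dedup_mode)
  graph <- as_follow_graph(graph)
  crc_col <- paste0("n_crc_tweets_", dedup_mode)
  eq_col <- paste0("n_equity_tweets_", dedup_mode)
  diss <- roles[roles$is_disseminator,
                unique(c("account_id", crc_col, eq_col,
                         "n_equity_tweets_nonunique"))]
  absent <- setdiff(diss$account_id, graph_ids(graph))
  if (length(absent) > 0) {
    rlang::warn(sprintf("skipping %d disseminator(s) unknown to the graph: %s",
                        length(absent),
                        paste(utils::head(absent, 5), collapse = ", ")))
    diss <- diss[!diss$account_id %in% absent, ]
  }
  e <- graph$edges[graph$edges$followee_id %in% diss$account_id, ]
  e <- dplyr::inner_join(e, diss, by = c(followee_id = "account_id"))
  out <- dplyr::summarise(
    dplyr::group_by(e, follower_id = .data$follower_id),
    n_followed_disseminators = dplyr::n(),
    n_crc_exposed = sum(.data[[crc_col]]),
    n_equity_exposed = sum(.data[[eq_col]]),
    n_equity_sources = sum(.data$n_equity_tweets_nonunique > 0L),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$follower_id)
}

#' Share of followers with zero equity exposure
#'
#' @param exposure Table from [exposure_per_follower()].
#' @return Proportion in `[0, 1]` of followers whose `n_equity_exposed`
#'   is zero.
#' @export
zero_exposure_share <- function(exposure) {
  if (nrow(exposure) == 0) {
    rlang::abort("exposure table is empty", class = "equityreach_schema_error")
  }
  mean(exposure$n_equity_exposed == 0)
}

#' Unique-source statistics per equity-posting account
#'
#' For every account with at least one equity posting event, the number and
#' share of its followers for whom it is the *only* followed equity-posting
#' disseminator — the account's unique reach into audiences that would
#' otherwise see no equity content.
#'
#' @inheritParams exposure_per_follower
#' @return Tibble `account_id`, `n_followers`, `n_unique_reliant`,
#'   `fraction_unique_reliant` (0 when the account has no followers).
#' @export
unique_source_stats <- function(graph, roles) {
  graph <- as_follow_graph(graph)
  posters <- roles$account_id[roles$is_disseminator &
                                roles$n_equity_tweets_nonunique > 0L]
  e_post <- graph$edges[graph$edges$followee_id %in% posters, ]
  n_src <- dplyr::count(e_post, .data$follower_id, name = "n_equity_sources")
  e_post <- dplyr::left_join(e_post, n_src, by = "follower_id")
  reliant <- dplyr::summarise(
    dplyr::group_by(e_post, account_id = .data$followee_id),
    n_unique_reliant = sum(.data$n_equity_sources == 1L),
    .groups = "drop"
  )
  fcount <- dplyr::count(graph$edges, account_id = .data$followee_id,
                         name = "n_followers")
  out <- tibble::tibble(account_id = sort(posters))
  out <- dplyr::left_join(out, fcount, by = "account_id")
  out <- dplyr::left_join(out, reliant, by = "account_id")
  out$n_followers <- dplyr::coalesce(out$n_followers, 0L)
  out$n_unique_reliant <- dplyr::coalesce(out$n_unique_reliant, 0L)
  out$fraction_unique_reliant <- ifelse(out$n_followers == 0, 0,
                                        out$n_unique_reliant / out$n_followers)
  out
}

#' Distribution summaries by account stratum
#'
#' Summarises the unique-source fractions of equity-posting accounts within
#' each role stratum (broker/nonbroker, expert/nonexpert, and the
#' expert x broker cross), plus one row for the follower-level equity
#' exposure distribution. Quartiles use linear interpolation
#' (`stats::quantile` type 7); the interquartile range is reported as its
#' endpoints.
#'
#' @param exposure Table from [exposure_per_follower()].
#' @param unique_source Table from [unique_source_stats()].
#' @param roles Role table from [assign_roles()].
#' @return Tibble `stratum`, `measure`, `n`, `mean`, `sd`, `median`,
#'   `q1`, `q3`. Empty strata yield a row of `NA` statistics.
#' @export
exposure_by_role <- function(exposure, unique_source, roles) {
  us <- dplyr::left_join(
    unique_source,
    roles[c("account_id", "is_expert", "is_broker")],
    by = "account_id")
  strata <- list(
    all_equity_posters = rep(TRUE, nrow(us)),
    brokers = us$is_broker %in% TRUE,
    nonbrokers = us$is_broker %in% FALSE,
    experts = us$is_expert %in% TRUE,
    nonexperts = us$is_expert %in% FALSE,
    expert_brokers = us$is_expert %in% TRUE & us$is_broker %in% TRUE,
    expert_nonbrokers = us$is_expert %in% TRUE & us$is_broker %in% FALSE
  )
  summ <- function(x, stratum, measure) {
    if (length(x) == 0) {
      return(tibble::tibble(stratum = stratum, measure = measure, n = 0L,
                            mean = NA_real_, sd = NA_real_, median = NA_real_,
                            q1 = NA_real_, q3 = NA_real_))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(stratum = stratum, measure = measure, n = length(x),
                   mean = mean(x), sd = stats::sd(x), median = q[2],
                   q1 = q[1], q3 = q[3])
  }
  rows <- lapply(names(strata), function(nm) {
    summ(us$fraction_unique_reliant[strata[[nm]]], nm, "unique_source_fraction")
  })
  rows <- c(rows, list(summ(exposure$n_equity_exposed, "followers_overall",
                            "n_equity_exposed")))
  dplyr::bind_rows(rows)
}
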