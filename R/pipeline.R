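#' Run the full analysis pipeline
#'
#' Orchestrates tagging, role derivation, exposure estimation, and the
#' comparison statistics over one corpus, and (optionally) writes the five
#' standard artifacts to `out_dir`: `roles.csv`, `exposure.csv`,
#' `unique_source.csv`, `proportions.csv`, and `summary.txt`, plus
#' `config.json` recording the resolved parameters. Any stage failure
#' aborts with the stage name; artifacts already written are retained and a
#' `FAILED` marker is left in `out_dir`.
#'
#' @param corp An `equityreach_corpus`, an `equityreach_sim`, or a
#'   directory containing `accounts.csv`, `edges.csv`, `tweets.csv`.
#' @param out_dir Optional output directory for the artifacts.
#' @param lexicon Lexicon tibble (`category`, `pattern`); defaults to the
#'   packaged dictionary.
#' @param org_ids Organization core ids; defaults to `is_org` accounts.
#' @param min_orgs Candidate threshold (default 2).
#' @param broker_threshold Broker majority threshold (default 0.5).
#' @param exclude_mentions Passed to the tokenizer.
#' @return A list (invisibly when `out_dir` is given): `tags`, `roles`,
#'   `role_summary`, `exposure`, `unique_source`, `by_role`, `proportions`,
#'   `volume` (headline counts/shares), `tests` (z-test and regressions),
#'   `summary_text`.
#' @export
run_pipeline <- function(corp, out_dir = NULL, lexicon = default_lexicon(),
                         org_ids = NULL, min_orgs = 2, broker_threshold = 0.5,
                         exclude_mentions = FALSE) {
  if (inherits(corp, "equityreach_sim")) corp <- corp$corpus
  if (is.character(corp)) {
    corp <- read_corpus(file.path(corp, "accounts.csv"),
                        file.path(corp, "edges.csv"),
                        file.path(corp, "tweets.csv"), format = "csv")
  }
  stopifnot(inherits(corp, "equityreach_corpus"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }

  matcher <- stage("tag", compile_lexicon(lexicon))
  tags <- stage("tag", tag_tweets(corp$tweets, matcher,
                                  exclude_mentions = exclude_mentions))
  roles <- stage("roles", assign_roles(corp, tags, org_ids = org_ids,
                                       min_orgs = min_orgs,
                                       broker_threshold = broker_threshold))
  role_summary <- stage("roles", summarize_roles(roles))
  graph <- follow_graph(corp$edges)
  expo <- stage("exposure", exposure_per_follower(graph, roles))
  usrc <- stage("exposure", unique_source_stats(graph, roles))
  by_role <- stage("exposure", exposure_by_role(expo, usrc, roles))

  uniq <- dedupe_tweets(corp$tweets)
  uniq_tags <- dplyr::inner_join(
    tags, uniq[c("tweet_id", "author_id")], by = "tweet_id")
  props <- stage("stats", proportion_table(uniq_tags, roles))
  volume <- stage("stats", volume_summary(corp, tags, uniq_tags, roles))
  tests <- stage("stats", headline_tests(volume, expo, usrc, roles))
  summary_text <- stage("report",
                        render_summary(volume, role_summary, by_role, tests))

  res <- list(tags = tags, roles = roles, role_summary = role_summary,
              exposure = expo, unique_source = usrc, by_role = by_role,
              proportions = props, volume = volume, tests = tests,
              summary_text = summary_text)
  if (!is.null(out_dir)) {
    stage("write", {
      write_table(roles, file.path(out_dir, "roles.csv"), "csv")
      write_table(expo, file.path(out_dir, "exposure.csv"), "csv")
      write_table(usrc, file.path(out_dir, "unique_source.csv"), "csv")
      write_table(props, file.path(out_dir, "proportions.csv"), "csv")
      writeLines(summary_text, file.path(out_dir, "summary.txt"))
      jsonlite::write_json(
        list(min_orgs = min_orgs, broker_threshold = broker_threshold,
             exclude_mentions = exclude_mentions,
             n_lexicon_entries = nrow(lexicon)),
        file.path(out_dir, "config.json"), auto_unbox = TRUE, pretty = TRUE)
    })
    return(invisible(res))
  }
  res
}

volume_summary <- function(corp, tags, uniq_tags, roles) {
  diss <- roles$account_id[roles$is_disseminator]
  d_tags <- uniq_tags[uniq_tags$author_id %in% diss, ]
  crc <- d_tags[d_tags$is_crc, ]
  labels <- stats::setNames(roles$is_expert, roles$account_id)
  crc$by_expert <- labels[crc$author_id]
  all_d <- tags$tweet_id %in%
    corp$tweets$tweet_id[corp$tweets$author_id %in% diss]
  list(
    n_tweets_nonunique = sum(tags$is_crc & all_d),
    n_tweets_unique = nrow(crc),
    n_equity_unique = sum(crc$is_equity),
    n_equity_nonunique = sum(tags$is_equity & all_d),
    n_expert_unique = sum(crc$by_expert %in% TRUE),
    n_expert_equity_unique = sum(crc$is_equity & crc$by_expert %in% TRUE),
    n_nonexpert_unique = sum(crc$by_expert %in% FALSE),
    n_nonexpert_equity_unique = sum(crc$is_equity & crc$by_expert %in% FALSE)
  )
}

headline_tests <- function(volume, expo, usrc, roles) {
  zt <- tryCatch(
    two_prop_ztest(volume$n_expert_equity_unique, volume$n_expert_unique,
                   volume$n_nonexpert_equity_unique, volume$n_nonexpert_unique),
    error = function(e) NULL)
  reg_exposure <- tryCatch(
    ols_simple(expo$n_equity_exposed, expo$n_followed_disseminators),
    error = function(e) NULL)
  us <- dplyr::left_join(usrc, roles[c("account_id", "is_broker")],
                         by = "account_id")
  reg_unique_source <- tryCatch(
    ols_simple(100 * us$fraction_unique_reliant, as.numeric(us$is_broker)),
    error = function(e) NULL)
  list(z_expert_vs_nonexpert = zt,
       ols_exposure_on_n_followed = reg_exposure,
       ols_unique_source_on_broker = reg_unique_source)
}

render_summary <- function(volume, role_summary, by_role, tests) {
  v <- volume
  g <- function(df, s) df[df$stratum == s, ]
  us_b <- g(by_role[by_role$measure == "unique_source_fraction", ], "brokers")
  us_n <- g(by_role[by_role$measure == "unique_source_fraction", ], "nonbrokers")
  fo <- by_role[by_role$stratum == "followers_overall", ]
  fmt_us <- function(r) {
    if (nrow(r) == 0 || r$n == 0) return("n/a (empty stratum)")
    sprintf("mean %.0f%%, median %.0f%% (IQR %.0f%%-%.0f%%), n=%d",
            100 * r$mean, 100 * r$median, 100 * r$q1, 100 * r$q3, r$n)
  }
  zline <- if (is.null(tests$z_expert_vs_nonexpert)) "z-test: not estimable" else
    sprintf("expert vs nonexpert equity share: z = %.2f, p = %.3g",
            tests$z_expert_vs_nonexpert$z,
            tests$z_expert_vs_nonexpert$p_two_sided)
  b1 <- if (is.null(tests$ols_exposure_on_n_followed)) "regression: not estimable" else
    sprintf("equity exposure ~ accounts followed: beta = %.3f (p = %.3g)",
            tests$ols_exposure_on_n_followed$beta,
            tests$ols_exposure_on_n_followed$p)
  b2 <- if (is.null(tests$ols_unique_source_on_broker)) "regression: not estimable" else
    sprintf("unique-source %% ~ broker: beta = %.1f (p = %.3g)",
            tests$ols_unique_source_on_broker$beta,
            tests$ols_unique_source_on_broker$p)
  c(
    "== Volume ==",
    sprintf("CRC tweets by disseminators: %d (%d unique)",
            v$n_tweets_nonunique, v$n_tweets_unique),
    sprintf("unique equity tweets: %d (%.1f%%); nonunique: %d",
            v$n_equity_unique,
            ifelse(v$n_tweets_unique > 0,
                   100 * v$n_equity_unique / v$n_tweets_unique, NA),
            v$n_equity_nonunique),
    sprintf("experts: %d/%d equity (%s%%); nonexperts: %d/%d (%s%%)",
            v$n_expert_equity_unique, v$n_expert_unique,
            ifelse(v$n_expert_unique > 0,
                   format(pct(v$n_expert_equity_unique, v$n_expert_unique, 1)), "-"),
            v$n_nonexpert_equity_unique, v$n_nonexpert_unique,
            ifelse(v$n_nonexpert_unique > 0,
                   format(pct(v$n_nonexpert_equity_unique, v$n_nonexpert_unique, 1)), "-")),
    zline,
    "",
    "== Roles ==",
    utils::capture.output(print(as.data.frame(role_summary), row.names = FALSE)),
    "",
    "== Exposure ==",
    if (nrow(fo) > 0 && fo$n > 0) {
      sprintf("follower equity exposure: mean %.2f, SD %.2f, %d followers",
              fo$mean, fo$sd, fo$n)
    } else "no followers of disseminators",
    b1,
    "",
    "== Unique sources ==",
    sprintf("brokers:    %s", fmt_us(us_b)),
    sprintf("nonbrokers: %s", fmt_us(us_n)),
    b2
  )
}
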