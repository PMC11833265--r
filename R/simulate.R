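#' @title Synthetic corpus generator
#' @description
#' Generates follow networks and tweet corpora with the statistical
#' structure the analysis assumes — an organization core, an
#' expert/nonexpert disseminator layer with heavy-tailed popularity, a
#' follower periphery mixing *insular* followers (who follow several
#' disseminators with a strong bias toward experts) and *peripheral*
#' followers (who follow exactly one disseminator), and role-dependent
#' tweet content with embedded dictionary keywords. Ground-truth roles and
#' tags are emitted alongside the corpus so that recovery can be tested.
#' All randomness flows from the single `seed` in the configuration.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults mirror the observed study population: 7 organization accounts,
#' 798 disseminators of which 479 are experts, intended-broker rates of
#' 254/479 (experts) and 246/319 (nonexperts), equity rates of 8.7%
#' (experts) and 3.7% (nonexperts) per CRC tweet, a mean of 19559/798
#' unique CRC tweets per account, and a retweet share of posting events of
#' 1 - 19559/25093.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_orgs Number of equity-organization core accounts.
#' @param n_disseminators Number of disseminator accounts.
#' @param expert_fraction Share of disseminators labeled expert.
#' @param n_followers Size of the follower periphery.
#' @param crc_tweet_mean Mean unique CRC tweets per disseminator (each
#'   account posts at least one; counts are overdispersed negative
#'   binomial).
#' @param crc_tweet_size Negative-binomial dispersion (`size`) of the CRC
#'   tweet counts.
#' @param noise_tweet_mean Mean non-CRC tweets per disseminator (Poisson).
#' @param equity_rate_expert,equity_rate_nonexpert Probability that a CRC
#'   tweet by an expert / nonexpert mentions a racial/ethnic group.
#' @param p_intended_broker_expert,p_intended_broker_nonexpert Probability
#'   that an expert / nonexpert disseminator is generated as an intended
#'   broker.
#' @param homophily_insular Probability that a follower of an intended
#'   *non-broker* is insular (follows additional, expert-biased accounts).
#' @param homophily_peripheral Probability that a follower of an intended
#'   *broker* is insular.
#' @param homophily Optional single mixture weight; when given it overrides
#'   both of the above (so `homophily = 1` makes every follower insular and
#'   brokerage vanishes; `homophily = 0` makes every follower
#'   single-followee and every followed account a broker).
#' @param insular_extra_mean Mean number of extra followees (beyond the
#'   primary) for insular followers; at least 1, shifted Poisson.
#' @param expert_bias Multiplicative sampling weight of expert accounts
#'   when insular followers choose extra followees.
#' @param broker_extra_damp Multiplicative damping (in `[0, 1]`) of an
#'   intended broker's weight when insular followers choose extra
#'   followees: the dense co-following core forms around intended
#'   non-brokers, while intended brokers reach audiences from outside it.
#' @param popularity_exponent Exponent of the power-law popularity weights
#'   that skew follower counts across disseminators.
#' @param retweet_rate Share of CRC posting events that are retweets of an
#'   existing CRC tweet.
#' @param ambiguous_term_rate Probability that an equity tweet uses only
#'   ambiguous dictionary terms, and that a non-equity CRC tweet contains
#'   an ambiguous term in a non-racial sense (0 makes lexicon tags equal
#'   ground truth exactly).
#' @param org_follow_share Share of disseminators following at least 2
#'   organizations (the candidate criterion).
#' @param p_follower_org Probability that a periphery follower also follows
#'   exactly one organization (such users stay below the candidate
#'   threshold).
#' @param min_followers_per_account Floor on followers per disseminator.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_orgs = 7L,
                       n_disseminators = 798L,
                       expert_fraction = 479 / 798,
                       n_followers = 20000L,
                       crc_tweet_mean = 19559 / 798,
                       crc_tweet_size = 0.6,
                       noise_tweet_mean = 5,
                       equity_rate_expert = 0.087,
                       equity_rate_nonexpert = 0.037,
                       p_intended_broker_expert = 254 / 479,
                       p_intended_broker_nonexpert = 246 / 319,
                       homophily_insular = 0.85,
                       homophily_peripheral = 0.15,
                       homophily = NULL,
                       insular_extra_mean = 2,
                       expert_bias = 8,
                       broker_extra_damp = 0.05,
                       popularity_exponent = 0.8,
                       retweet_rate = 1 - 19559 / 25093,
                       ambiguous_term_rate = 0,
                       org_follow_share = 1,
                       p_follower_org = 0.05,
                       min_followers_per_account = 3L) {
  if (!is.null(homophily)) {
    homophily_insular <- homophily
    homophily_peripheral <- homophily
  }
  cfg <- list(
    seed = as.integer(seed), n_orgs = as.integer(n_orgs),
    n_disseminators = as.integer(n_disseminators),
    expert_fraction = expert_fraction,
    n_followers = as.integer(n_followers),
    crc_tweet_mean = crc_tweet_mean, crc_tweet_size = crc_tweet_size,
    noise_tweet_mean = noise_tweet_mean,
    equity_rate_expert = equity_rate_expert,
    equity_rate_nonexpert = equity_rate_nonexpert,
    p_intended_broker_expert = p_intended_broker_expert,
    p_intended_broker_nonexpert = p_intended_broker_nonexpert,
    homophily_insular = homophily_insular,
    homophily_peripheral = homophily_peripheral,
    insular_extra_mean = insular_extra_mean,
    expert_bias = expert_bias,
    broker_extra_damp = broker_extra_damp,
    popularity_exponent = popularity_exponent,
    retweet_rate = retweet_rate,
    ambiguous_term_rate = ambiguous_term_rate,
    org_follow_share = org_follow_share,
    p_follower_org = p_follower_org,
    min_followers_per_account = as.integer(min_followers_per_account)
  )
  probs <- c("expert_fraction", "equity_rate_expert", "equity_rate_nonexpert",
             "p_intended_broker_expert", "p_intended_broker_nonexpert",
             "homophily_insular", "homophily_peripheral", "retweet_rate",
             "ambiguous_term_rate", "org_follow_share", "p_follower_org",
             "broker_extra_damp")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort_schema("sim_config: %s must be in [0, 1] (got %g)", p, cfg[[p]])
    }
  }
  if (cfg$n_orgs < 1 || cfg$n_disseminators < 1 || cfg$n_followers < 0) {
    abort_schema("sim_config: counts must be positive (n_followers may be 0)")
  }
  if (cfg$expert_fraction * cfg$n_disseminators < 1) {
    abort_schema("sim_config: expert_fraction x n_disseminators must be >= 1")
  }
  if (cfg$crc_tweet_mean < 1) {
    abort_schema("sim_config: crc_tweet_mean must be >= 1 (every disseminator posts)")
  }
  structure(cfg, class = "sim_config")
}

#' Named simulation presets
#'
#' * `demo`: 5 orgs, 50 disseminators, 2000 followers — runs the full
#'   pipeline in seconds.
#' * `study-scale-lite`: 7 orgs, 798 disseminators, 20,000 followers.
#' * `study-scale`: 7 orgs, 798 disseminators, 100,000 followers
#'   (the full observed account layer with a reduced follower periphery).
#'
#' @param preset Preset name.
#' @param seed Seed passed through to [sim_config()].
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(preset = c("demo", "study-scale-lite", "study-scale"),
                       seed = 1L, ...) {
  preset <- rlang::arg_match(preset)
  base <- switch(preset,
    "demo" = list(n_orgs = 5L, n_disseminators = 50L, n_followers = 2000L),
    "study-scale-lite" = list(n_orgs = 7L, n_disseminators = 798L,
                              n_followers = 20000L),
    "study-scale" = list(n_orgs = 7L, n_disseminators = 798L,
                         n_followers = 100000L)
  )
  do.call(sim_config, c(list(seed = seed), base, list(...)))
}

#' Generate the account layer and follow network
#'
#' @param config A [sim_config()].
#' @return List with `accounts`, `edges` (tibbles), and `account_truth`
#'   (`account_id`, `kind`, `is_expert`, `intended_broker`).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_network_impl(config))
}

generate_network_impl <- function(cfg) {
  org_ids <- sprintf("org%02d", seq_len(cfg$n_orgs))
  n_d <- cfg$n_disseminators
  diss_ids <- sprintf("d%04d", seq_len(n_d))
  n_exp <- max(1L, round(cfg$expert_fraction * n_d))
  is_expert <- seq_len(n_d) %in% sample.int(n_d, n_exp)
  p_broker <- ifelse(is_expert, cfg$p_intended_broker_expert,
                     cfg$p_intended_broker_nonexpert)
  intended_broker <- stats::rbinom(n_d, 1, p_broker) == 1

  # disseminators follow the organization core; a configurable share
  # crosses the >=2-organization candidate threshold
  crosses <- stats::runif(n_d) < cfg$org_follow_share
  n_orgs_followed <- ifelse(
    crosses,
    pmin(cfg$n_orgs, 2L + stats::rbinom(n_d, max(cfg$n_orgs - 2L, 0L), 0.15)),
    stats::rbinom(n_d, 1, 0.5))
  d_org_edges <- lapply(seq_len(n_d), function(i) {
    k <- n_orgs_followed[i]
    if (k == 0) return(NULL)
    tibble::tibble(follower_id = diss_ids[i],
                   followee_id = org_ids[sample.int(cfg$n_orgs, k)])
  })

  # heavy-tailed popularity of disseminators
  w <- sample.int(n_d)^(-cfg$popularity_exponent)
  w <- w / sum(w)

  m <- cfg$n_followers
  if (m > 0) {
    fol_ids <- sprintf("f%06d", seq_len(m))
    counts <- as.vector(stats::rmultinom(1, m, w))
    counts <- enforce_min_counts(counts, cfg$min_followers_per_account, m)
    primary <- rep.int(seq_len(n_d), counts)
    p_ins <- ifelse(intended_broker[primary], cfg$homophily_peripheral,
                    cfg$homophily_insular)
    insular <- stats::runif(m) < p_ins

    w_bias <- w * ifelse(is_expert, cfg$expert_bias, 1) *
      ifelse(intended_broker, cfg$broker_extra_damp, 1)
    ins_idx <- which(insular)
    extra_edges <- NULL
    if (length(ins_idx) > 0) {
      k_extra <- 1L + stats::rpois(length(ins_idx),
                                   max(cfg$insular_extra_mean - 1, 0))
      draws <- sample.int(n_d, sum(k_extra), replace = TRUE, prob = w_bias)
      extra_edges <- tibble::tibble(
        follower = rep.int(ins_idx, k_extra),
        followee = draws
      )
      extra_edges <- extra_edges[extra_edges$followee !=
                                   primary[extra_edges$follower], ]
      extra_edges <- dplyr::distinct(extra_edges)
    }
    f_edges <- tibble::tibble(
      follower_id = c(fol_ids, fol_ids[extra_edges$follower]),
      followee_id = diss_ids[c(primary, extra_edges$followee)]
    )
    follows_org <- which(stats::runif(m) < cfg$p_follower_org)
    f_org_edges <- if (length(follows_org) > 0) {
      tibble::tibble(
        follower_id = fol_ids[follows_org],
        followee_id = org_ids[sample.int(cfg$n_orgs, length(follows_org),
                                         replace = TRUE)])
    } else NULL
    follower_type <- ifelse(insular, "insular", "peripheral")
  } else {
    fol_ids <- character(0)
    f_edges <- NULL
    f_org_edges <- NULL
    follower_type <- character(0)
  }

  edges <- dplyr::distinct(dplyr::bind_rows(d_org_edges, f_edges, f_org_edges))
  accounts <- dplyr::bind_rows(
    tibble::tibble(account_id = org_ids, handle = paste0("equity_org_", seq_len(cfg$n_orgs)),
                   profile_text = "Health equity organization. Screening access for all.",
                   is_org = TRUE, expert_label = "unlabeled"),
    tibble::tibble(account_id = diss_ids, handle = paste0("user_", diss_ids),
                   profile_text = ifelse(is_expert,
                                         "Physician. Gastroenterology, screening and prevention.",
                                         "Advocate. Sharing screening reminders and updates."),
                   is_org = FALSE,
                   expert_label = ifelse(is_expert, "expert", "nonexpert")),
    tibble::tibble(account_id = fol_ids, handle = paste0("user_", fol_ids),
                   profile_text = "", is_org = FALSE, expert_label = "unlabeled")
  )
  fcount <- table(edges$followee_id)
  accounts$follower_count <-
    as.integer(ifelse(is.na(fcount[accounts$account_id]), 0L,
                      fcount[accounts$account_id]))
  account_truth <- dplyr::bind_rows(
    tibble::tibble(account_id = org_ids, kind = "org", is_expert = NA,
                   intended_broker = NA, follower_type = NA_character_),
    tibble::tibble(account_id = diss_ids, kind = "disseminator",
                   is_expert = is_expert, intended_broker = intended_broker,
                   follower_type = NA_character_),
    tibble::tibble(account_id = fol_ids, kind = "follower", is_expert = NA,
                   intended_broker = NA, follower_type = follower_type)
  )
  list(accounts = accounts, edges = edges, account_truth = account_truth)
}

enforce_min_counts <- function(counts, minimum, total) {
  if (total < length(counts) * minimum) return(counts) # infeasible; leave as is
  while (any(counts < minimum)) {
    i <- which.min(counts)
    j <- which.max(counts)
    need <- minimum - counts[i]
    counts[i] <- counts[i] + need
    counts[j] <- counts[j] - need
  }
  counts
}

CRC_KEYWORD_FORMS <- c("colon cancer", "colorectal cancer", "#ColonCancer",
                       "#ColorectalCancer", "#coloncancer", "colorectalcancer")

CRC_TEMPLATES <- c(
  "New %s screening guidelines are out. Talk with your doctor about timing",
  "%s awareness month is here. Schedule that colonoscopy and remind a friend",
  "Early detection of %s saves lives. Know your screening options",
  "Our clinic posted an update on %s prevention and screening research",
  "Fresh data on %s outcomes presented at this week's oncology meeting",
  "A reminder that %s screening starts at age 45 for average-risk adults"
)

NOISE_TEMPLATES <- c(
  "Weekly wellness update from our team. New clinic hours posted",
  "Reminder that annual checkup scheduling opens today",
  "Grateful for our volunteers at the health fair this weekend",
  "New episode of our prevention podcast is live now",
  "Study enrollment for the nutrition trial continues through spring"
)

EQUITY_PHRASES <- list(
  people_of_color = c("in communities of color", "for people of color",
                      "where racial disparities persist"),
  black = c("among Black patients", "for African American communities",
            "with Black communities facing higher risk"),
  hispanic_latino = c("among Hispanic patients", "for Latino families",
                      "in Latinx communities"),
  indigenous = c("in Indigenous communities",
                 "among Native American patients"),
  asian = c("among Asian American patients", "for Asian communities")
)

# equity phrasing that relies only on high-recall ambiguous dictionary terms
AMBIGUOUS_EQUITY_PHRASES <- list(
  people_of_color = c("wearing colored ribbons for the cause"),
  black = c("encourage your brother and your sister to get screened")
)

# the same ambiguous tokens in a clearly non-racial reading (false-positive
# pressure for the dictionary when ambiguous_term_rate > 0)
AMBIGUOUS_NOISE_PHRASES <- c(
  "thanks to Dr Brown for presenting",
  "the brown bag seminar series returns",
  "my sister in medicine presented the data"
)

EQUITY_CATEGORY_WEIGHTS <- c(people_of_color = 0.20, black = 0.45,
                             hispanic_latino = 0.20, indigenous = 0.08,
                             asian = 0.07)

#' Generate tweets for a synthetic account layer
#'
#' Per-disseminator unique CRC tweet counts are overdispersed (shifted
#' negative binomial, minimum one); each CRC tweet's text is built from a
#' template guaranteeing a CRC keyword, equity phrases are inserted at the
#' account's role-specific rate, and retweet events duplicate existing CRC
#' tweets. Every original text carries a unique numeric reference token so
#' that deduplication collapses exactly the retweets.
#'
#' @param config A [sim_config()].
#' @param network Result of [generate_network()].
#' @return List with `tweets` (tibble) and `tweet_truth` (`tweet_id`,
#'   `author_id`, `intended_crc`, `intended_equity`, `intended_category`,
#'   `is_retweet`).
#' @export
generate_tweets <- function(config, network) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, generate_tweets_impl(config, network))
}

generate_tweets_impl <- function(cfg, network) {
  truth <- network$account_truth
  diss <- truth[truth$kind == "disseminator", ]
  n_d <- nrow(diss)
  handles <- stats::setNames(network$accounts$handle,
                             network$accounts$account_id)

  n_crc <- 1L + stats::rnbinom(n_d, mu = cfg$crc_tweet_mean - 1,
                               size = cfg$crc_tweet_size)
  n_noise <- stats::rpois(n_d, cfg$noise_tweet_mean)

  author <- c(rep.int(diss$account_id, n_crc), rep.int(diss$account_id, n_noise))
  is_crc <- c(rep(TRUE, sum(n_crc)), rep(FALSE, sum(n_noise)))
  n_tot <- length(author)
  author_expert <- c(rep.int(diss$is_expert, n_crc),
                     rep.int(diss$is_expert, n_noise))
  eq_rate <- ifelse(author_expert, cfg$equity_rate_expert,
                    cfg$equity_rate_nonexpert)
  is_equity <- is_crc & stats::runif(n_tot) < eq_rate

  category <- rep(NA_character_, n_tot)
  category[is_equity] <- sample(names(EQUITY_CATEGORY_WEIGHTS),
                                sum(is_equity), replace = TRUE,
                                prob = EQUITY_CATEGORY_WEIGHTS)
  use_ambiguous <- stats::runif(n_tot) < cfg$ambiguous_term_rate
  # ambiguous-only phrasing exists for two categories; remap the rest
  amb_eq <- is_equity & use_ambiguous
  category[amb_eq] <- sample(names(AMBIGUOUS_EQUITY_PHRASES), sum(amb_eq),
                             replace = TRUE)

  text <- character(n_tot)
  kw <- sample(CRC_KEYWORD_FORMS, n_tot, replace = TRUE)
  tmpl <- sample(CRC_TEMPLATES, n_tot, replace = TRUE)
  text[is_crc] <- sprintf(tmpl[is_crc], kw[is_crc])
  text[!is_crc] <- sample(NOISE_TEMPLATES, sum(!is_crc), replace = TRUE)

  pick <- function(choices_list, keys) {
    vapply(keys, function(k) {
      ph <- choices_list[[k]]
      ph[sample.int(length(ph), 1)]
    }, character(1))
  }
  plain_eq <- which(is_equity & !use_ambiguous)
  if (length(plain_eq) > 0) {
    text[plain_eq] <- paste(text[plain_eq],
                            pick(EQUITY_PHRASES, category[plain_eq]))
  }
  amb_eq_i <- which(amb_eq)
  if (length(amb_eq_i) > 0) {
    text[amb_eq_i] <- paste(text[amb_eq_i],
                            pick(AMBIGUOUS_EQUITY_PHRASES, category[amb_eq_i]))
  }
  # non-equity CRC tweets that nonetheless contain an ambiguous term
  amb_noise_i <- which(is_crc & !is_equity & use_ambiguous)
  if (length(amb_noise_i) > 0) {
    text[amb_noise_i] <- paste(
      text[amb_noise_i],
      sample(AMBIGUOUS_NOISE_PHRASES, length(amb_noise_i), replace = TRUE))
  }
  text <- paste0(text, " ref ", sprintf("%07d", seq_len(n_tot)))

  t0 <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
  t1 <- as.POSIXct("2021-12-31 23:59:59", tz = "UTC")
  ts <- t0 + round(stats::runif(n_tot) * as.numeric(difftime(t1, t0, units = "secs")))

  ids <- sprintf("t%07d", seq_len(n_tot))
  tweets <- tibble::tibble(
    tweet_id = ids, author_id = author, text = text, timestamp = ts,
    is_retweet = FALSE, source_tweet_id = NA_character_
  )
  tweet_truth <- tibble::tibble(
    tweet_id = ids, author_id = author, intended_crc = is_crc,
    intended_equity = is_equity, intended_category = category,
    is_retweet = FALSE
  )

  # retweet events duplicate existing CRC tweets
  crc_pool <- which(is_crc)
  n_rt <- round(cfg$retweet_rate / (1 - cfg$retweet_rate) * length(crc_pool))
  if (n_rt > 0 && length(crc_pool) > 0) {
    src <- crc_pool[sample.int(length(crc_pool), n_rt, replace = TRUE)]
    rt_author <- diss$account_id[sample.int(n_d, n_rt, replace = TRUE)]
    rt_ids <- sprintf("t%07d", n_tot + seq_len(n_rt))
    rt_ts <- ts[src] + round(stats::runif(n_rt, 3600, 30 * 86400))
    rt <- tibble::tibble(
      tweet_id = rt_ids, author_id = rt_author,
      text = paste0("RT @", unname(handles[author[src]]), ": ", text[src]),
      timestamp = rt_ts, is_retweet = TRUE, source_tweet_id = ids[src]
    )
    tweets <- dplyr::bind_rows(tweets, rt)
    tweet_truth <- dplyr::bind_rows(tweet_truth, tibble::tibble(
      tweet_id = rt_ids, author_id = rt_author, intended_crc = TRUE,
      intended_equity = is_equity[src], intended_category = category[src],
      is_retweet = TRUE
    ))
  }
  list(tweets = tweets, tweet_truth = tweet_truth)
}

#' Generate a full synthetic corpus
#'
#' Composes [generate_network()] and [generate_tweets()]; optionally writes
#' the corpus, ground truth, and a manifest to disk. The same seed always
#' yields an identical corpus.
#'
#' @param config A [sim_config()] (or the result of [sim_preset()]).
#' @param dir Optional output directory; when given, writes
#'   `accounts.csv`, `edges.csv`, `tweets.csv`, `account_truth.csv`,
#'   `tweet_truth.csv`, and `manifest.json` (JSON-lines output is available
#'   through [write_corpus()]).
#' @return An object of class `equityreach_sim`: list with `corpus`
#'   (an `equityreach_corpus`), `account_truth`, `tweet_truth`, `config`.
#' @export
generate_corpus <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  network <- generate_network(config)
  tw <- generate_tweets(config, network)
  corp <- corpus(network$accounts, network$edges, tw$tweets)
  out <- structure(
    list(corpus = corp, account_truth = network$account_truth,
         tweet_truth = tw$tweet_truth, config = config),
    class = "equityreach_sim"
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_corpus(corp, dir, format = "csv")
    write_table(network$account_truth, file.path(dir, "account_truth.csv"), "csv")
    write_table(tw$tweet_truth, file.path(dir, "tweet_truth.csv"), "csv")
    manifest <- list(
      package = "equityreach",
      version = as.character(utils::packageVersion("equityreach")),
      config = unclass(config)
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.equityreach_sim <- function(x, ...) {
  cat(sprintf("<synthetic corpus (seed %d)>\n", x$config$seed))
  print(x$corpus)
  invisible(x)
}
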