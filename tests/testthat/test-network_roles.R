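test_that("candidate selection thresholds organization co-following", {
  edges <- mk_edges(
    c("u1", "O1"), c("u1", "O2"),      # follows 2 orgs -> candidate
    c("u2", "O1"),                      # follows 1 org  -> excluded
    c("u3", "O1"), c("u3", "O2"), c("u3", "O3"),
    c("O2", "O1")                       # orgs never candidates
  )
  g <- follow_graph(edges)
  expect_equal(select_candidates(g, c("O1", "O2", "O3"), min_orgs = 2),
               c("u1", "u3"))
  # relaxed threshold: membership
  expect_equal(select_candidates(g, c("O1", "O2", "O3"), min_orgs = 1),
               c("u1", "u2", "u3"))
  expect_error(select_candidates(g, c("O1", "Onot")), "Onot",
               class = "equityreach_integrity_error")
})

test_that("candidate sets shrink monotonically in min_orgs", {
  rg <- random_role_graph(21, n_accounts = 30, n_followers = 300)
  g <- follow_graph(rg$edges)
  orgs <- rg$disseminators[1:5]
  c2 <- select_candidates(g, orgs, min_orgs = 2)
  c3 <- select_candidates(g, orgs, min_orgs = 3)
  expect_true(all(c3 %in% c2))
})

test_that("disseminators are candidates with at least one CRC tweet", {
  tweets <- mk_tweets(c("u1", "u2", "u2", "u3", "u4"),
                      c("colon cancer update",
                        "nothing to see", "still nothing",
                        "#coloncancer awareness", "hello"))
  tags <- tag_tweets(tweets, compile_lexicon(default_lexicon()))
  cands <- c("u1", "u2", "u3")
  expect_equal(identify_disseminators(cands, tags, tweets), c("u1", "u3"))
  # u4 tweets CRC? no - and not a candidate anyway
  expect_equal(identify_disseminators(character(0), tags, tweets), character(0))
})

test_that("broker rule: strict majority of otherwise-unexposed followers", {
  # expert A: f2 also follows expert E2; f1, f3 follow only A -> 2/3 broker
  edges <- mk_edges(c("f1", "A"), c("f2", "A"), c("f3", "A"), c("f2", "E2"))
  res <- classify_brokers(c("A", "E2"), follow_graph(edges), c("A", "E2"))
  a <- res[res$account_id == "A", ]
  expect_equal(a$n_unexposed, 2)
  expect_equal(a$n_followers, 3)
  expect_true(a$is_broker)

  # nonexpert B: both followers also follow expert E1 -> 0/2 non-broker
  edges2 <- mk_edges(c("g1", "B"), c("g2", "B"), c("g1", "E1"), c("g2", "E1"),
                     c("x", "E1"))
  res2 <- classify_brokers(c("B", "E1"), follow_graph(edges2), "E1")
  expect_false(res2$is_broker[res2$account_id == "B"])

  # exactly half unexposed -> non-broker (strict threshold)
  edges3 <- mk_edges(c("h1", "C"), c("h2", "C"), c("h2", "E1"), c("y", "E1"))
  res3 <- classify_brokers(c("C", "E1"), follow_graph(edges3), "E1")
  expect_equal(res3$frac_unexposed[res3$account_id == "C"], 0.5)
  expect_false(res3$is_broker[res3$account_id == "C"])
})

test_that("zero-follower disseminators are non-brokers", {
  edges <- mk_edges(c("Z", "O1"), c("f", "D"))
  res <- classify_brokers(c("Z", "D"), follow_graph(edges), character(0))
  expect_false(res$is_broker[res$account_id == "Z"])
  expect_equal(res$n_followers[res$account_id == "Z"], 0)
  expect_true(res$is_broker[res$account_id == "D"])
})

test_that("classify_brokers errors on experts outside the disseminator set or unknown ids", {
  edges <- mk_edges(c("f", "A"))
  expect_error(classify_brokers("A", follow_graph(edges), "E9"),
               class = "equityreach_integrity_error")
  expect_error(classify_brokers(c("A", "ghost"), follow_graph(edges),
                                character(0)),
               "ghost", class = "equityreach_integrity_error")
})

test_that("broker classification equals exhaustive per-follower recount", {
  for (seed in 1:8) {
    rg <- random_role_graph(seed)
    got <- classify_brokers(rg$disseminators, follow_graph(rg$edges),
                            rg$experts)
    want <- oracle_brokers(rg$edges, rg$disseminators, rg$experts)
    expect_equal(stats::setNames(got$is_broker, got$account_id),
                 want[got$account_id])
  }
})

test_that("every disseminator is exactly one of broker/non-broker", {
  rg <- random_role_graph(99)
  got <- classify_brokers(rg$disseminators, follow_graph(rg$edges), rg$experts)
  expect_equal(sort(got$account_id), sort(rg$disseminators))
  expect_false(any(is.na(got$is_broker)))
})

test_that("adding an expert can only demote brokers, never promote", {
  rg <- random_role_graph(31)
  g <- follow_graph(rg$edges)
  non_experts <- setdiff(rg$disseminators, rg$experts)
  before <- classify_brokers(rg$disseminators, g, rg$experts)
  after <- classify_brokers(rg$disseminators, g,
                            c(rg$experts, non_experts[1]))
  expect_true(all(after$is_broker <= before$is_broker))
})

test_that("an expert with no co-followed experts classifies the same with or without itself in expert_ids", {
  # A's followers follow no expert other than A
  edges <- mk_edges(c("f1", "A"), c("f2", "A"), c("f1", "B"))
  g <- follow_graph(edges)
  with_self <- classify_brokers(c("A", "B"), g, c("A"))
  without <- classify_brokers(c("A", "B"), g, character(0))
  expect_equal(with_self$is_broker[with_self$account_id == "A"],
               without$is_broker[without$account_id == "A"])
})

test_that("role summary cross-tabulates expertise and brokerage", {
  roles <- tibble::tibble(
    account_id = sprintf("d%d", 1:6),
    is_disseminator = TRUE,
    is_expert = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    is_broker = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  )
  s <- summarize_roles(roles)
  expect_equal(s$n[s$stratum == "expert_brokers"], 2)
  expect_equal(s$pct[s$stratum == "expert_brokers"], 50) # 2 of 4 experts
  # disjoint broker/expert sets -> zero expert-brokers
  roles$is_broker <- !roles$is_expert
  s2 <- summarize_roles(roles)
  expect_equal(s2$n[s2$stratum == "expert_brokers"], 0)
})

test_that("assign_roles composes selection, labeling, brokerage, and counts", {
  accounts <- mk_accounts(c("O1", "O2", "D1", "D2", "D3"),
                          orgs = c("O1", "O2"),
                          experts = "D1", nonexperts = c("D2", "D3"))
  edges <- mk_edges(
    c("D1", "O1"), c("D1", "O2"), c("D2", "O1"), c("D2", "O2"),
    c("D3", "O1"), c("D3", "O2"),
    c("f1", "D1"), c("f2", "D1"), c("f2", "D2"), c("f3", "D2")
  )
  tweets <- mk_tweets(
    c("D1", "D1", "D2", "D3"),
    c("colon cancer risk among Black patients ref 1",
      "RT @h_D1: colon cancer risk among Black patients ref 1",
      "colorectal cancer screening update ref 2",
      "unrelated post ref 3"),
    is_retweet = c(FALSE, TRUE, FALSE, FALSE),
    source = c(NA, "t001", NA, NA))
  corp <- corpus(accounts, edges, tweets)
  tags <- tag_tweets(corp$tweets, compile_lexicon(default_lexicon()))
  roles <- assign_roles(corp, tags)

  expect_equal(roles$account_id[roles$is_candidate], c("D1", "D2", "D3"))
  # D3 has no CRC tweet -> candidate but not disseminator
  expect_equal(roles$account_id[roles$is_disseminator], c("D1", "D2"))
  expect_true(roles$is_expert[roles$account_id == "D1"])
  expect_true(is.na(roles$is_broker[roles$account_id == "D3"]))
  # counts: D1 one unique equity CRC tweet, two nonunique
  d1 <- roles[roles$account_id == "D1", ]
  expect_equal(d1$n_crc_tweets_unique, 1)
  expect_equal(d1$n_crc_tweets_nonunique, 2)
  expect_equal(d1$n_equity_tweets_unique, 1)
  expect_equal(d1$n_equity_tweets_nonunique, 2)
  expect_equal(d1$n_followers, 2)
  # expert-broker identity
  d <- roles[roles$is_disseminator, ]
  expect_equal(d$is_expert_broker, d$is_expert & d$is_broker)
})

test_that("assign_roles insists on expert labels for disseminators", {
  accounts <- mk_accounts(c("O1", "O2", "D1"), orgs = c("O1", "O2"))
  edges <- mk_edges(c("D1", "O1"), c("D1", "O2"))
  tweets <- mk_tweets("D1", "colon cancer note")
  corp <- corpus(accounts, edges, tweets)
  tags <- tag_tweets(corp$tweets, compile_lexicon(default_lexicon()))
  expect_error(assign_roles(corp, tags), "label",
               class = "equityreach_integrity_error")
})
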