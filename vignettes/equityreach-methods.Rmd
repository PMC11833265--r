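---
title: "Methods: tagging, brokerage, exposure, and the synthetic corpus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tagging, brokerage, exposure, and the synthetic corpus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equityreach)
```

`equityreach` studies how racial health-equity content about colorectal
cancer (CRC) travels on a follower network. This vignette records the model
and the design decisions behind each stage, including the places where a
choice had to be made among several defensible options.

## The pipeline model

The unit of observation is a corpus of three tables: accounts, directed
follow edges (follower → followee), and tweets. Four derived layers sit on
top:

* **Content tags.** A tweet is *CRC-related* if it matches any of four
  topic keywords (`coloncancer`, `colorectalcancer`, and the two-token
  phrases `colon cancer`, `colorectal cancer`), and an *equity tweet* if it
  is CRC-related **and** matches at least one of five racial/ethnic-group
  dictionary categories. Categories are not mutually exclusive.
* **Roles.** *Candidates* follow at least `min_orgs` (default 2) of the
  equity-organization core accounts — following a single organization is
  treated as incidental interest, co-following as topical commitment.
  *Disseminators* are candidates with at least one CRC tweet, originals and
  retweets alike. Expert/nonexpert labels are an input: profile-based
  classification is human work and deliberately outside the package.
* **Brokerage.** For disseminator $a$ with follower set $F(a)$ and expert
  set $E$ (the expert-labeled disseminators), a follower $f$ is *otherwise
  unexposed* when $|\{e \in E \setminus \{a\} : f \text{ follows } e\}| = 0$.
  $a$ is a broker iff the otherwise-unexposed share strictly exceeds 0.5.
  Excluding the focal account from $E$ means an expert is judged by what
  its audience would see *without it*.
* **Exposure.** Follow-implies-see: a follower's potential exposure is the
  sum of posting-event counts over followed disseminators. Exposure uses
  *non-unique* counts (a retweet is a second chance to see the content);
  content analyses use the deduplicated corpus. An account's
  *unique-source fraction* is the share of its followers for whom it is
  the only followed equity-posting account.

## Tokenization and dictionary matching

Text is lowercased, URLs are blanked out (offsets preserved for audit),
and tokens are maximal alphanumeric runs. This strips `#` and `@` sigils
while keeping hashtag/mention bodies as single tokens; compound hashtags
are *not* word-segmented, so `#blackhealth` matches only through the
wildcard entry `black*`. Non-wildcard entries require whole-token equality
(`poc` never matches `pocket`); a terminal `*` matches any — possibly
empty — alphanumeric suffix of one token; phrases match consecutive tokens
and may carry a wildcard on their final token (`african american*`).

Two deliberate recall-over-precision choices:

* Ambiguous dictionary terms (`brown`, `colored`, `sister`, ...) are kept.
  The intended workflow is high-recall tagging followed by human review;
  every tag carries a `matched_terms` audit trail (category, pattern,
  matched token/phrase) to support adjudication.
* Mention bodies are tokenized and matchable by default (an organization
  name inside `@…` can legitimately signal the topic); passing
  `exclude_mentions = TRUE` removes them before matching.

Date windows and region restrictions are properties of the input data, so
they are exposed as an explicit filter (`filter_tweets()`) rather than
hard-coded.

## Deduplication

"Unique" tweets are equivalence classes of normalized text: lowercased,
URLs stripped, a leading `rt @handle:` prefix removed, whitespace
collapsed. This makes a retweet collapse onto its source while leaving
genuinely distinct wordings apart, which is the behaviour implied by the
gap between posting events and unique tweets in corpora of this kind. The
class representative is the earliest timestamp, ties broken by smallest
`tweet_id`, so deduplication is deterministic. Timestamps are parsed as
UTC; malformed timestamps reject the row (with a logged count) rather than
silently becoming missing.

Whether a disseminator's retweet of someone else's content counts toward
its own activity is resolved per analysis: yes for exposure (non-unique
counts), collapsed for content (unique counts attribute the text to the
earliest poster).

## Numerical and statistical choices

* **Two-proportion test.** The pooled-variance z form,
  $z = (\hat p_1 - \hat p_2)/\sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}$, was
  chosen because it reproduces the study's printed statistic exactly from
  the printed counts; it equals the uncorrected chi-squared test
  ($z^2 = X^2$), which the tests use as an independent cross-check, along
  with a seeded permutation test. A pooled proportion of 0 or 1 raises a
  degenerate-variance error rather than returning `NaN`.
* **Pairwise category comparisons** are flagged at a per-comparison
  α = 0.05 with no multiplicity correction, matching common reporting in
  this literature; a Holm option exists but is off by default.
* **Regression.** `ols_simple()` wraps `stats::lm`; standard errors are
  kept at full precision internally and only rounded at display time.
  Plain OLS is a known limitation: errors are not clustered by account.
* **Quartiles** use linear interpolation (`quantile` type 7). IQR
  endpoints are convention-sensitive, so both endpoints are reported.
* **Percent display**: `pct(n, d, digits)`; stratified content tables use
  2 decimals, prose shares 0–1 decimals. Values are numeric on the 0–100
  scale.
* **Edge cases**: zero-follower accounts are non-brokers (a broker must
  reach someone; this resolves the 0/0 share conservatively); the broker
  threshold is a strict `> 0.5` exposed as a parameter; empty strata yield
  `NA` summary rows rather than being dropped.

All role and exposure computations are joins and grouped aggregations over
the edge table — no dense follower × account matrix is formed — so the
pipeline runs in memory at 10^5-follower scale. The shipped presets are
`demo` (5 organizations, 50 disseminators, 2,000 followers; the scale used
throughout the test suite and the acceptance script), `study-scale-lite`
(7/798/20,000), and `study-scale` (7/798/100,000).

## The synthetic-data generator

The generator emulates the structure the analysis assumes, with defaults
pinned to the observed study population wherever a value was published:

| parameter | default | meaning |
|---|---|---|
| `n_orgs` | 7 | organization core accounts |
| `n_disseminators` | 798 | disseminator layer |
| `expert_fraction` | 479/798 | expert share among disseminators |
| `p_intended_broker_expert` | 254/479 | intended broker rate, experts |
| `p_intended_broker_nonexpert` | 246/319 | intended broker rate, nonexperts |
| `crc_tweet_mean` | 19559/798 | mean unique CRC tweets per account (min 1) |
| `equity_rate_expert` | 0.087 | equity probability per expert CRC tweet |
| `equity_rate_nonexpert` | 0.037 | equity probability per nonexpert CRC tweet |
| `retweet_rate` | 1 − 19559/25093 | retweet share of CRC posting events |
| `popularity_exponent` | 0.8 | power-law skew of follower counts |

Values without a published anchor were chosen once on plausibility
grounds and not tuned: `crc_tweet_size = 0.6` (strong overdispersion —
a few prolific accounts, many occasional ones), `noise_tweet_mean = 5`
non-CRC tweets per account, `insular_extra_mean = 2` extra followees for
insular followers, `expert_bias = 8` (insular audiences skew heavily
toward experts), `min_followers_per_account = 3`.

**Follower mixture and homophily.** Every follower picks one *primary*
disseminator proportional to heavy-tailed popularity weights. It is then
*insular* (follows `1 + Poisson` additional accounts with expert-biased,
popularity-weighted choice) or *peripheral* (follows exactly its primary).
A single global insularity weight cannot simultaneously produce both
broker strata at realistic rates *and* account-level ground truth, so the
mixture weight is role-conditional: followers of intended non-brokers are
insular with probability `homophily_insular = 0.85`, followers of intended
brokers with probability `homophily_peripheral = 0.15`. The convenience
argument `homophily =` sets both to one value, recovering the global
mixture as a special case: at `homophily = 1` every follower is insular
and brokerage vanishes; at `homophily = 0` every follower is
single-followee and every followed account is a broker. Additionally,
insular followers' extra follows are damped onto intended brokers
(`broker_extra_damp = 0.05`): the dense co-following core forms around
non-brokers, which is what *makes* the brokers brokers. The real
follower-overlap structure among disseminators is unknown; this mixture
model is an assumption, not an estimate.

**Tweets.** Texts are synthesized from neutral templates (no real user
content) that guarantee a CRC keyword in various surface forms (phrase,
hashtag, concatenation); equity tweets append a category-specific phrase
built from dictionary terms; each original carries a unique numeric
reference token so that deduplication collapses exactly the retweets.
`ambiguous_term_rate` controls a stress mode in which equity tweets use
only ambiguous terms and non-equity CRC tweets contain the same tokens in
non-racial readings ("Dr Brown", "brown bag seminar"); at its default of
0, lexicon tags equal ground truth exactly, which the tests assert.

**What passing tests do and do not show.** The generator produces clean
separations: template text (no misspellings, sarcasm, or code-switching),
a two-type follower mixture, no disseminator-to-disseminator edges, no
temporal posting dynamics, no bots. Recovery of ground-truth broker labels
at ≥ 95% accuracy therefore validates the *implementation* of the
classification rule under the assumed structure — it says nothing about
how noisy real profile data or feed algorithms would blur these roles.
Follower-scale quantities (mean exposure, regression slopes) depend on the
corpus scale and are not comparable to values measured on a multi-million
follower graph; only their signs, orderings, and internal consistency
(conservation of total exposure; agreement with brute-force recounts) are
asserted.

## Determinism

Every stochastic step draws from the single configuration seed
(`withr::with_seed`; the tweet stage derives `seed + 1` so the two stages
are individually reproducible). The same seed yields byte-identical
corpora and pipeline artifacts, which the test suite checks literally.

## Known limitations

* Exposure is *potential* exposure: follow-implies-see ignores feed
  ranking, activity timing, and actual reading behaviour, and is therefore
  an upper bound with unknown slack per follower.
* Expert labels are consumed, not produced; label errors propagate
  directly into brokerage (the expert set defines "otherwise unexposed").
* The dictionary is English-only, high-recall, and unsegmented on
  compound hashtags; precision on real text requires the human-review pass
  the audit trail is designed for.
* OLS standard errors assume independent observations; followers sharing
  followees violate this, so reported p-values for the exposure
  regressions are optimistic.
* No diffusion modeling: retweet cascades, quote tweets, and
  cross-platform spillover are out of scope.
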