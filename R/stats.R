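#' @title Comparison statistics
#' @description
#' The reporting statistics used throughout the analysis: the pooled
#' two-proportion z-test for comparing shares between account strata,
#' simple least-squares regression for exposure and unique-source
#' comparisons, and the stratified proportion table with pairwise
#' significance flags.
#' @name reach_stats
NULL

#' Percentage of a count over a denominator
#'
#' Reporting convention helper: `pct(641, 1134, 2)` is `56.53`,
#' `pct(254, 479, 0)` is `53`. Stratified content tables conventionally use
#' 2 decimals; prose shares 0-1 decimals.
#'
#' @param n Numerator count(s).
#' @param d Denominator count(s).
#' @param digits Decimal places (default 1).
#' @return Numeric percentage(s) on the 0-100 scale.
#' @export
pct <- function(n, d, digits = 1) {
  round(100 * n / d, digits)
}

#' Pooled two-proportion z-test
#'
#' Tests `H0: p1 == p2` using the pooled estimate
#' `p = (k1 + k2) / (n1 + n2)`:
#' `z = (p1_hat - p2_hat) / sqrt(p (1 - p) (1/n1 + 1/n2))`,
#' with a two-sided p-value from the standard normal. Equivalent to the
#' chi-squared test without continuity correction (`z^2 == X^2`).
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A list of class `two_prop_ztest`: `z`, `p_two_sided`, `p1_hat`,
#'   `p2_hat`, `p_pooled`, `n1`, `n2`.
#' @examples
#' two_prop_ztest(716, 8210, 418, 11349)$z # 14.88
#' @export
two_prop_ztest <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  p <- (k1 + k2) / (n1 + n2)
  if (p <= 0 || p >= 1) {
    rlang::abort("pooled proportion is 0 or 1: the z statistic is undefined",
                 class = "equityreach_degenerate_error")
  }
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  structure(
    list(z = z, p_two_sided = 2 * stats::pnorm(-abs(z)),
         p1_hat = p1, p2_hat = p2, p_pooled = p, n1 = n1, n2 = n2),
    class = "two_prop_ztest"
  )
}

#' @export
print.two_prop_ztest <- function(x, ...) {
  cat(sprintf(
    "two-proportion z-test (pooled): z = %.2f, p = %.3g\n  p1 = %.4f (n1 = %d), p2 = %.4f (n2 = %d)\n",
    x$z, x$p_two_sided, x$p1_hat, x$n1, x$p2_hat, x$n2))
  invisible(x)
}

#' Simple ordinary least squares
#'
#' One-predictor OLS with normal-theory standard error and p-value. With a
#' binary 0/1 predictor the slope equals the difference of group means.
#'
#' @param y Response vector.
#' @param x Predictor vector (same length, at least 3, non-constant).
#' @return A list of class `ols_simple`: `beta`, `se`, `p`, `intercept`, `n`.
#' @export
ols_simple <- function(y, x) {
  stopifnot(length(y) == length(x), length(y) >= 3)
  keep <- stats::complete.cases(y, x)
  y <- y[keep]; x <- x[keep]
  if (length(unique(x)) < 2) {
    rlang::abort("predictor is constant: slope is not identified",
                 class = "equityreach_degenerate_error")
  }
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  structure(
    list(beta = unname(cf["x", "Estimate"]),
         se = unname(cf["x", "Std. Error"]),
         p = unname(cf["x", "Pr(>|t|)"]),
         intercept = unname(cf["(Intercept)", "Estimate"]),
         n = length(y)),
    class = "ols_simple"
  )
}

#' @export
print.ols_simple <- function(x, ...) {
  cat(sprintf("simple OLS: beta = %.4g (SE %.4g), p = %.3g, n = %d\n",
              x$beta, x$se, x$p, x$n))
  invisible(x)
}

#' Stratified proportion table with pairwise comparisons
#'
#' For each content category, the count and percentage of unique equity
#' tweets in each account stratum (overall, expert, nonexpert, broker,
#' nonbroker, expert-broker, expert-nonbroker), with pairwise
#' two-proportion z-tests between expert/nonexpert, broker/nonbroker, and
#' expert-broker/expert-nonbroker.
#'
#' @param tags Tag table over the *unique* (deduplicated) tweets; needs
#'   `tweet_id`, `is_equity`, `equity_categories`, and `author_id` (join
#'   with the tweet table beforehand, or pass `tweets`).
#' @param roles Role table from [assign_roles()].
#' @param category_assignments Optional tibble `tweet_id`, `category` with
#'   external (e.g. manually coded) non-exclusive content labels. When
#'   absent, the lexicon's racial/ethnic group categories are used.
#' @param tweets Optional tweet tibble used to attach `author_id` to `tags`.
#' @param digits Decimal places for percentages (default 2, the stratified
#'   table convention).
#' @param alpha Per-comparison significance level (default 0.05).
#' @param adjust `"none"` (default; per-comparison flags) or `"holm"` for a
#'   Holm correction across categories within each pair of strata.
#' @return Tibble: one row per category with `n_<stratum>`,
#'   `pct_<stratum>` columns, and `p_` / `sig_` columns per compared pair.
#' @export
proportion_table <- function(tags, roles, category_assignments = NULL,
                             tweets = NULL, digits = 2, alpha = 0.05,
                             adjust = c("none", "holm")) {
  adjust <- rlang::arg_match(adjust)
  if (!"author_id" %in% names(tags)) {
    if (is.null(tweets)) {
      abort_schema("tags must carry author_id (or supply tweets= to join)")
    }
    tags <- dplyr::inner_join(tags, tweets[c("tweet_id", "author_id")],
                              by = "tweet_id")
  }
  eq <- tags[tags$is_equity, ]
  if (is.null(category_assignments)) {
    category_assignments <- tidyr::unnest(
      tibble::tibble(tweet_id = eq$tweet_id, category = eq$equity_categories),
      "category")
  }
  eq <- dplyr::left_join(
    eq,
    roles[c("account_id", "is_expert", "is_broker")],
    by = c(author_id = "account_id"))
  strata <- list(
    overall = rep(TRUE, nrow(eq)),
    expert = eq$is_expert %in% TRUE,
    nonexpert = eq$is_expert %in% FALSE,
    broker = eq$is_broker %in% TRUE,
    nonbroker = eq$is_broker %in% FALSE,
    expert_broker = eq$is_expert %in% TRUE & eq$is_broker %in% TRUE,
    expert_nonbroker = eq$is_expert %in% TRUE & eq$is_broker %in% FALSE
  )
  cats <- sort(unique(category_assignments$category))
  out <- tibble::tibble(category = cats)
  denom <- vapply(strata, sum, integer(1))
  for (s in names(strata)) {
    ids <- eq$tweet_id[strata[[s]]]
    k <- vapply(cats, function(cc) {
      sum(category_assignments$tweet_id[category_assignments$category == cc]
          %in% ids)
    }, integer(1), USE.NAMES = FALSE)
    out[[paste0("n_", s)]] <- k
    out[[paste0("pct_", s)]] <-
      if (denom[[s]] > 0) pct(k, denom[[s]], digits) else NA_real_
  }
  pairs <- list(
    expert_vs_nonexpert = c("expert", "nonexpert"),
    broker_vs_nonbroker = c("broker", "nonbroker"),
    expert_broker_vs_expert_nonbroker = c("expert_broker", "expert_nonbroker")
  )
  for (pn in names(pairs)) {
    a <- pairs[[pn]][1]; b <- pairs[[pn]][2]
    pvals <- vapply(seq_along(cats), function(i) {
      k1 <- out[[paste0("n_", a)]][i]; k2 <- out[[paste0("n_", b)]][i]
      n1 <- denom[[a]]; n2 <- denom[[b]]
      if (n1 == 0 || n2 == 0) return(NA_real_)
      tryCatch(two_prop_ztest(k1, n1, k2, n2)$p_two_sided,
               equityreach_degenerate_error = function(e) NA_real_)
    }, numeric(1))
    if (adjust == "holm") pvals <- stats::p.adjust(pvals, method = "holm")
    out[[paste0("p_", pn)]] <- pvals
    out[[paste0("sig_", pn)]] <- !is.na(pvals) & pvals < alpha
  }
  out
}
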