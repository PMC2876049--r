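#' Scoring rules for the categorical pass/fail assessment
#'
#' @param stop_as_fail Count age-relevant items that were never reached
#'   because of the stopping rule (`not_administered`) as failures in the
#'   categorical score. They contribute 0 to the continuous score either way.
#' @param dont_know_as_fail Count "don't know" outcomes as failures; the
#'   default treats them as missing (excluded from numerator and denominator).
#' @param overall_rule `"all_domains"`: the child passes overall iff every
#'   domain passes (each domain tolerating one failure); `"no_failures"`: the
#'   child passes overall iff there is no failed age-relevant item anywhere.
#' @return A list of class `scoring_rules`.
#' @export
scoring_rules <- function(stop_as_fail = TRUE,
                          dont_know_as_fail = FALSE,
                          overall_rule = c("all_domains", "no_failures")) {
  structure(list(stop_as_fail = isTRUE(stop_as_fail),
                 dont_know_as_fail = isTRUE(dont_know_as_fail),
                 overall_rule = match.arg(overall_rule)),
            class = "scoring_rules")
}

#' Age-relevant items for a child
#'
#' An item is age-relevant when the age at which 90% of the reference
#' population passes it lies strictly below the child's chronological age
#' (a child exactly at an item's 90% attainment age is not yet expected to
#' pass it). Items whose 90% age was extrapolated are included but flagged.
#'
#' @param norm_table A norm table with `age90` and `ex90`.
#' @param decimal_age The child's chronological age in years.
#' @return The age-relevant subset of the norm table.
#' @export
age_relevant_items <- function(norm_table, decimal_age) {
  norm_table[norm_table$age90 < decimal_age, , drop = FALSE]
}

#' Score children against a normative reference table
#'
#' Categorical rule (Denver-II style): within each domain, count failures
#' among the age-relevant items (90% attainment age strictly below the child's
#' age); a domain is failed with two or more failures, and the child fails the
#' test when any domain is failed (see [scoring_rules()] for the stricter
#' overall variant). Continuous scores count the items passed per domain and
#' in total, regardless of age relevance.
#'
#' @param responses Long response data frame for a single session.
#' @param norm_table Norm table (see [fit_norms()]).
#' @param children Child records with `child_id` and `decimal_age`.
#' @param rules A [scoring_rules()].
#' @return Data frame with one row per child: per-domain
#'   `<domain>_n_relevant`, `<domain>_n_failed`, `<domain>_pass`,
#'   `<domain>_assessable`, `<domain>_score`, plus `overall_pass`,
#'   `overall_assessable`, and `total_score`.
#' @export
score_children <- function(responses, norm_table, children,
                           rules = scoring_rules()) {
  assert_columns(responses, c("child_id", "item_id", "outcome"), "responses")
  assert_columns(children, c("child_id", "decimal_age"), "children")
  r <- responses[responses$item_id %in% norm_table$item_id, , drop = FALSE]
  mi <- match(r$item_id, norm_table$item_id)
  r$domain <- norm_table$domain[mi]
  age90 <- norm_table$age90[mi]
  age <- children$decimal_age[match(r$child_id, children$child_id)]
  relevant <- age90 < age
  dk <- r$outcome == "dont_know"
  scoreable <- relevant & (!dk | rules$dont_know_as_fail)
  failed <- scoreable &
    (r$outcome == "fail" |
       (rules$stop_as_fail & r$outcome == "not_administered") |
       (rules$dont_know_as_fail & dk))
  passed <- r$outcome == "pass"

  child_f <- factor(r$child_id, levels = children$child_id)
  domains <- unique(norm_table$domain)
  dom_f <- factor(r$domain, levels = domains)
  agg <- function(v) {
    t <- tapply(as.numeric(v), list(child_f, dom_f), sum, default = 0)
    t[is.na(t)] <- 0
    t
  }
  n_rel <- agg(scoreable)
  n_fail <- agg(failed)
  score <- agg(passed)

  out <- data.frame(child_id = children$child_id,
                    decimal_age = children$decimal_age,
                    stringsAsFactors = FALSE)
  for (d in domains) {
    out[[paste0(d, "_n_relevant")]] <- as.integer(n_rel[, d])
    out[[paste0(d, "_n_failed")]] <- as.integer(n_fail[, d])
    out[[paste0(d, "_pass")]] <- n_fail[, d] <= 1
    out[[paste0(d, "_assessable")]] <- n_rel[, d] > 0
    out[[paste0(d, "_score")]] <- as.integer(score[, d])
  }
  pass_mat <- n_fail <= 1
  if (rules$overall_rule == "all_domains") {
    out$overall_pass <- apply(pass_mat, 1, all)
  } else {
    out$overall_pass <- rowSums(n_fail) == 0
  }
  out$overall_assessable <- rowSums(n_rel) > 0
  out$total_score <- as.integer(rowSums(score))
  rownames(out) <- NULL
  out
}

#' Continuous milestone scores
#'
#' Number of items passed per domain and in total for each child;
#' not-administered and "don't know" outcomes contribute zero.
#'
#' @param responses Long response data frame for a single session.
#' @param item_bank Item metadata giving each item's domain.
#' @return Data frame with `child_id`, one `<domain>_score` column per domain,
#'   and `total_score`.
#' @export
score_continuous <- function(responses, item_bank) {
  r <- responses[responses$item_id %in% item_bank$item_id, , drop = FALSE]
  domains <- unique(item_bank$domain)
  dom_f <- factor(item_bank$domain[match(r$item_id, item_bank$item_id)],
                  levels = domains)
  child_f <- factor(r$child_id)
  t <- tapply(as.numeric(r$outcome == "pass"), list(child_f, dom_f), sum,
              default = 0)
  t[is.na(t)] <- 0
  out <- data.frame(child_id = rownames(t), stringsAsFactors = FALSE)
  for (d in domains) out[[paste0(d, "_score")]] <- as.integer(t[, d])
  out$total_score <- as.integer(rowSums(t))
  rownames(out) <- NULL
  out
}
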