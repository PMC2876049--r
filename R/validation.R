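#' Randomly select sex- and age-matched controls
#'
#' For each case, eligible controls share the case's sex and have the same age
#' rounded to one decimal place; one is chosen uniformly at random without
#' replacement (each control used at most once). Unmatched cases are reported,
#' not fatal.
#'
#' @param cases Data frame of case children (`child_id`, `decimal_age`,
#'   `sex`).
#' @param control_pool Data frame of candidate controls, disjoint from cases.
#' @param seed Integer seed; the pairing is reproducible.
#' @return List with `pairs` (data frame `case_id`, `control_id`, `sex`,
#'   `age_key`) and `unmatched` (character vector of case ids).
#' @export
select_matched_controls <- function(cases, control_pool, seed = 1L) {
  assert_columns(cases, c("child_id", "decimal_age", "sex"), "cases")
  assert_columns(control_pool, c("child_id", "decimal_age", "sex"),
                 "control_pool")
  if (any(cases$child_id %in% control_pool$child_id)) {
    stop("control pool must be disjoint from cases")
  }
  set.seed(derive_seed(seed, 701L))
  pool_key <- paste(control_pool$sex, sprintf("%.1f", control_pool$decimal_age))
  used <- logical(nrow(control_pool))
  pairs <- list()
  unmatched <- character(0)
  for (i in sample.int(nrow(cases))) {
    key <- paste(cases$sex[i], sprintf("%.1f", cases$decimal_age[i]))
    avail <- which(pool_key == key & !used)
    if (!length(avail)) {
      unmatched <- c(unmatched, cases$child_id[i])
      next
    }
    pick <- avail[sample.int(length(avail), 1L)]
    used[pick] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      case_id = cases$child_id[i],
      control_id = control_pool$child_id[pick],
      sex = cases$sex[i],
      age_key = sprintf("%.1f", cases$decimal_age[i]),
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else {
    data.frame(case_id = character(0), control_id = character(0),
               sex = character(0), age_key = character(0),
               stringsAsFactors = FALSE)
  }
  pairs <- pairs[order(pairs$case_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched = sort(unmatched))
}

#' McNemar's test on matched pass/fail pairs
#'
#' Discordant counts b (case passes, control fails) and c (case fails,
#' control passes) give chi-square = (b - c)^2 / (b + c) on one degree of
#' freedom, without continuity correction. With no discordant pairs p = 1.
#' When b + c < 25 an exact binomial p-value is reported alongside.
#'
#' @param case_pass,control_pass Logical vectors over the matched pairs.
#' @return List: `b`, `c`, `statistic`, `p_value`, `exact_p` (NA unless
#'   b + c < 25).
#' @export
mcnemar_paired <- function(case_pass, control_pass) {
  ok <- !is.na(case_pass) & !is.na(control_pass)
  b <- sum(case_pass[ok] & !control_pass[ok])
  cc <- sum(!case_pass[ok] & control_pass[ok])
  if (b + cc == 0) {
    return(list(b = b, c = cc, statistic = 0, p_value = 1, exact_p = 1))
  }
  stat <- (b - cc)^2 / (b + cc)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  exact <- NA_real_
  if (b + cc < 25) {
    exact <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
  }
  list(b = b, c = cc, statistic = stat, p_value = p, exact_p = exact)
}

#' Paired t test on matched continuous scores
#'
#' The mean difference is reported as control minus case. Zero variance of the
#' differences makes the p-value not assessable (NA).
#'
#' @param case_scores,control_scores Numeric vectors over the matched pairs.
#' @return List: `t`, `df`, `p_value`, `mean_difference` (control - case),
#'   `n`.
#' @export
paired_t <- function(case_scores, control_scores) {
  ok <- !is.na(case_scores) & !is.na(control_scores)
  x <- control_scores[ok]
  y <- case_scores[ok]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  d <- x - y
  if (stats::var(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else NA_real_,
                df = length(d) - 1L, p_value = NA_real_,
                mean_difference = mean(d), n = length(d)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate),
       n = length(d))
}

#' Wilson score confidence interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n <= 0) stop("n must be positive")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Sensitivity and specificity of the pass/fail rule
#'
#' Cases are children who by definition should fail the screen; sensitivity is
#' the proportion of cases failing and specificity the proportion of controls
#' passing, each with a 95% Wilson score interval (Clopper-Pearson exact
#' intervals available via `method = "exact"`).
#'
#' @param cases_failed,n_cases Failing cases over cases assessed.
#' @param controls_failed,n_controls Failing controls over controls assessed.
#' @param method `"wilson"` (default) or `"exact"`.
#' @return List of class `diagnostic_accuracy`: `sensitivity`, `specificity`,
#'   their CIs, and the underlying counts.
#' @export
diagnostic_accuracy <- function(cases_failed, n_cases,
                                controls_failed, n_controls,
                                method = c("wilson", "exact")) {
  method <- match.arg(method)
  if (n_cases <= 0 || n_controls <= 0) stop("zero denominator")
  sens <- cases_failed / n_cases
  spec <- (n_controls - controls_failed) / n_controls
  ci <- function(x, n) {
    if (method == "wilson") {
      wilson_ci(x, n)
    } else {
      bt <- stats::binom.test(x, n)
      c(lower = bt$conf.int[1], upper = bt$conf.int[2])
    }
  }
  structure(list(sensitivity = sens,
                 sensitivity_ci = ci(cases_failed, n_cases),
                 specificity = spec,
                 specificity_ci = ci(n_controls - controls_failed, n_controls),
                 cases_failed = cases_failed, n_cases = n_cases,
                 controls_failed = controls_failed, n_controls = n_controls),
            class = "diagnostic_accuracy")
}

#' Construct-validity comparison table
#'
#' For each domain and for the overall test: numbers passing in each group,
#' McNemar p-value on the matched pass/fail outcomes, group means (SD) of the
#' continuous scores with the paired-t p-value, and (optionally) sensitivity
#' and specificity with 95% CIs. A pair contributes to a domain only when both
#' members are assessable there (at least one age-relevant scoreable item), so
#' per-domain denominators may differ. The report's printed sensitivity and
#' specificity are internally consistent with its printed counts by
#' construction, and this is re-checked on every call.
#'
#' @param case_scores,control_scores Score tables from [score_children()].
#' @param pairs Matched pairs from [select_matched_controls()].
#' @param domains Domain names scored.
#' @param include_accuracy Add sensitivity/specificity columns (used for the
#'   neurodisability comparison).
#' @return Data frame with one row per domain plus `all_domains`.
#' @export
validation_report <- function(case_scores, control_scores, pairs,
                              domains = milestone_domains(),
                              include_accuracy = TRUE) {
  ca <- case_scores[match(pairs$case_id, case_scores$child_id), , drop = FALSE]
  co <- control_scores[match(pairs$control_id, control_scores$child_id), ,
                       drop = FALSE]
  if (any(is.na(ca$child_id)) || any(is.na(co$child_id))) {
    stop("pairs reference children missing from the score tables")
  }
  one <- function(label, case_pass, ctrl_pass, case_sc, ctrl_sc, usable) {
    case_pass <- case_pass[usable]
    ctrl_pass <- ctrl_pass[usable]
    case_sc <- case_sc[usable]
    ctrl_sc <- ctrl_sc[usable]
    n <- sum(usable)
    mc <- mcnemar_paired(case_pass, ctrl_pass)
    tt <- if (n >= 2 && (stats::var(ctrl_sc - case_sc) > 0)) {
      paired_t(case_sc, ctrl_sc)
    } else {
      list(p_value = NA_real_, mean_difference = mean(ctrl_sc - case_sc))
    }
    row <- data.frame(domain = label,
                      n_pairs = n,
                      cases_passing = sum(case_pass),
                      controls_passing = sum(ctrl_pass),
                      cases_passing_pct = round(100 * mean(case_pass)),
                      controls_passing_pct = round(100 * mean(ctrl_pass)),
                      mcnemar_statistic = mc$statistic,
                      mcnemar_p = mc$p_value,
                      case_mean = mean(case_sc), case_sd = stats::sd(case_sc),
                      control_mean = mean(ctrl_sc),
                      control_sd = stats::sd(ctrl_sc),
                      mean_difference = tt$mean_difference,
                      paired_t_p = tt$p_value,
                      stringsAsFactors = FALSE)
    if (include_accuracy) {
      acc <- diagnostic_accuracy(n - sum(case_pass), n,
                                 n - sum(ctrl_pass), n)
      stopifnot(abs(acc$sensitivity - acc$cases_failed / acc$n_cases) < 1e-12,
                abs(acc$specificity -
                      (acc$n_controls - acc$controls_failed) /
                      acc$n_controls) < 1e-12)
      row$sensitivity <- acc$sensitivity
      row$sensitivity_lo <- acc$sensitivity_ci[["lower"]]
      row$sensitivity_hi <- acc$sensitivity_ci[["upper"]]
      row$specificity <- acc$specificity
      row$specificity_lo <- acc$specificity_ci[["lower"]]
      row$specificity_hi <- acc$specificity_ci[["upper"]]
    }
    row
  }
  rows <- lapply(domains, function(d) {
    usable <- ca[[paste0(d, "_assessable")]] & co[[paste0(d, "_assessable")]]
    one(d, ca[[paste0(d, "_pass")]], co[[paste0(d, "_pass")]],
        ca[[paste0(d, "_score")]], co[[paste0(d, "_score")]], usable)
  })
  usable <- ca$overall_assessable & co$overall_assessable
  rows <- c(rows, list(one("all_domains", ca$overall_pass, co$overall_pass,
                           ca$total_score, co$total_score, usable)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
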