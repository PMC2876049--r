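#' Exploratory covariate effect on one item
#'
#' Adds a single explanatory variable to the age-only logistic model,
#' logit P(pass) = a + b * age + c * covariate, and Wald-tests c = 0 at the 5%
#' level. One covariate at a time, mirroring exploratory item screening; no
#' multiple-testing correction is applied.
#'
#' @param outcome Character outcomes; only pass/fail rows are used.
#' @param age Decimal ages.
#' @param covariate Numeric covariate values (sex should be coded 0/1).
#' @param name Covariate label (`"sex"`, `"ses"`, `"haz"`, `"waz"`, ...).
#' @param item_id Optional item identifier.
#' @param alpha Significance level.
#' @return One-row data frame: `item_id`, `covariate`, `coefficient`, `se`,
#'   `p_value`, `significant`, `assessable`.
#' @export
test_covariate_effect <- function(outcome, age, covariate, name,
                                  item_id = NA_character_, alpha = 0.05) {
  keep <- outcome %in% c("pass", "fail") & !is.na(covariate)
  y <- outcome[keep] == "pass"
  x <- age[keep]
  v <- covariate[keep]
  not_assessable <- data.frame(item_id = item_id, covariate = name,
                               coefficient = NA_real_, se = NA_real_,
                               p_value = NA_real_, significant = FALSE,
                               assessable = FALSE, stringsAsFactors = FALSE)
  if (length(unique(v)) < 2) {
    warning(sprintf("covariate '%s' is constant: effect not assessable", name))
    return(not_assessable)
  }
  if (length(y) == 0 || all(y) || !any(y)) return(not_assessable)
  fit <- suppressWarnings(stats::glm(y ~ x + v, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  if (!"v" %in% rownames(sm)) return(not_assessable)
  data.frame(item_id = item_id, covariate = name,
             coefficient = sm["v", "Estimate"],
             se = sm["v", "Std. Error"],
             p_value = sm["v", "Pr(>|z|)"],
             significant = sm["v", "Pr(>|z|)"] < alpha,
             assessable = TRUE,
             stringsAsFactors = FALSE)
}

#' Screen all items for sex, SES, HAZ, and WAZ effects
#'
#' @param responses Long response data frame.
#' @param children Child records with `sex`, `ses_quintile`, `haz`, `waz`.
#' @param item_bank Item metadata restricting and ordering the items screened.
#' @param alpha Significance level.
#' @return Data frame with one row per item x covariate.
#' @export
screen_covariates <- function(responses, children, item_bank, alpha = 0.05) {
  assert_columns(children, c("child_id", "decimal_age", "sex", "ses_quintile",
                             "haz", "waz"), "children")
  resp <- responses[responses$outcome %in% c("pass", "fail"), , drop = FALSE]
  m <- match(resp$child_id, children$child_id)
  resp$age <- children$decimal_age[m]
  covs <- list(sex = as.numeric(children$sex[m] == "male"),
               ses = as.numeric(children$ses_quintile[m]),
               haz = children$haz[m],
               waz = children$waz[m])
  rows <- lapply(intersect(item_bank$item_id, unique(resp$item_id)),
                 function(id) {
    sel <- resp$item_id == id
    do.call(rbind, lapply(names(covs), function(nm) {
      suppressWarnings(
        test_covariate_effect(resp$outcome[sel], resp$age[sel],
                              covs[[nm]][sel], nm, item_id = id,
                              alpha = alpha))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Domain-by-covariate summary of item screening
#'
#' Counts (and whole-percent shares) of items per domain with a significant
#' effect of each covariate, merged with the poor-goodness-of-fit counts, plus
#' a totals row - the shape of the classic item-performance summary table.
#'
#' @param effects Data frame from [screen_covariates()].
#' @param item_bank Item metadata (`item_id`, `domain`).
#' @param gof Optional per-item data frame with `poor_fit_single` (the
#'   single-fit screen that triggers refitting).
#' @return Data frame with one row per domain and a `total` row; columns
#'   `n_items`, then `<covariate>_n` and `<covariate>_pct`, and when `gof` is
#'   supplied `poor_fit_n` / `poor_fit_pct`.
#' @export
summarize_covariate_effects <- function(effects, item_bank, gof = NULL) {
  domains <- unique(item_bank$domain)
  dom_of <- function(ids) item_bank$domain[match(ids, item_bank$item_id)]
  items <- unique(effects$item_id)
  covs <- unique(effects$covariate)
  one_row <- function(ids, label) {
    row <- data.frame(domain = label, n_items = length(ids),
                      stringsAsFactors = FALSE)
    if (!is.null(gof)) {
      pf <- sum(gof$poor_fit_single[gof$item_id %in% ids], na.rm = TRUE)
      row$poor_fit_n <- pf
      row$poor_fit_pct <- round(100 * pf / length(ids))
    }
    for (cv in covs) {
      sel <- effects$item_id %in% ids & effects$covariate == cv
      k <- sum(effects$significant[sel], na.rm = TRUE)
      row[[paste0(cv, "_n")]] <- k
      row[[paste0(cv, "_pct")]] <- round(100 * k / length(ids))
    }
    row
  }
  rows <- lapply(domains, function(d) one_row(items[dom_of(items) == d], d))
  rows <- c(rows, list(one_row(items, "total")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
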