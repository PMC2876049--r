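#' Consensus flagging of items for removal
#'
#' Applies the rule-based part of a consensus item review. Reasons:
#' * `poor_fit` - the goodness of fit is still poor after any spline refit;
#' * `poor_reliability` - kappa at or below `kappa_threshold` in any design
#'   (good-to-excellent reliability requires kappa > 0.6);
#' * `gender_effect` - a significant sex effect in the age-adjusted model;
#' * `duplicate_age_range` - another item in the same domain has all four
#'   attainment ages equal within `duplicate_tol` years;
#' * `ceiling_not_reached` - the 90% attainment age exceeds `ceiling_age`
#'   years or was extrapolated beyond the observed ages;
#' * `subjective` - only ever set from the external annotations, never
#'   computed.
#'
#' Items with no reliability rows have that reason recorded as not assessable
#' in the `reliability_missing` column rather than flagged.
#'
#' @param norm_table Norm table including `poor_fit` and extrapolation flags.
#' @param kappas Per-item agreement rows from [item_kappas()] (any designs).
#' @param covariate_effects Data frame from [screen_covariates()].
#' @param annotations Optional data frame (`item_id`, `subjective_note`).
#' @param duplicate_tol Tolerance (years) for "exactly the same" age ranges.
#' @param kappa_threshold Kappa at or below this flags poor reliability.
#' @param ceiling_age Age (years) by which 90% attainment must be reached.
#' @return Data frame with one row per item: logical reason columns,
#'   `reasons` (comma-separated), `n_reasons`, `recommend_removal`.
#' @export
flag_items <- function(norm_table, kappas = NULL, covariate_effects = NULL,
                       annotations = NULL, duplicate_tol = 0.05,
                       kappa_threshold = 0.6, ceiling_age = 7) {
  ids <- norm_table$item_id
  out <- data.frame(item_id = ids, domain = norm_table$domain,
                    stringsAsFactors = FALSE)
  out$poor_fit <- if (is.null(norm_table$poor_fit)) {
    rep(FALSE, length(ids))
  } else {
    isTRUE_vec(norm_table$poor_fit)
  }
  out$poor_reliability <- FALSE
  out$reliability_missing <- TRUE
  if (!is.null(kappas) && nrow(kappas)) {
    bad <- tapply(kappas$kappa <= kappa_threshold, kappas$item_id,
                  function(v) any(v, na.rm = TRUE))
    out$poor_reliability <- isTRUE_vec(bad[match(ids, names(bad))])
    out$reliability_missing <- !(ids %in% kappas$item_id)
  }
  out$gender_effect <- FALSE
  if (!is.null(covariate_effects)) {
    sx <- covariate_effects[covariate_effects$covariate == "sex", , drop = FALSE]
    out$gender_effect <- isTRUE_vec(sx$significant[match(ids, sx$item_id)])
  }
  ages <- as.matrix(norm_table[, c("age25", "age50", "age75", "age90")])
  out$duplicate_age_range <- vapply(seq_along(ids), function(i) {
    same_dom <- which(norm_table$domain == norm_table$domain[i])
    same_dom <- setdiff(same_dom, i)
    if (!length(same_dom)) return(FALSE)
    any(apply(abs(ages[same_dom, , drop = FALSE] -
                    rep(ages[i, ], each = length(same_dom))) <= duplicate_tol,
              1, all))
  }, logical(1))
  out$ceiling_not_reached <- norm_table$age90 > ceiling_age |
    isTRUE_vec(norm_table$ex90)
  out$subjective <- FALSE
  if (!is.null(annotations) && nrow(annotations)) {
    out$subjective <- ids %in% annotations$item_id
  }
  reason_cols <- c("poor_reliability", "poor_fit", "gender_effect",
                   "duplicate_age_range", "ceiling_not_reached", "subjective")
  reason_mat <- as.matrix(out[, reason_cols])
  out$n_reasons <- rowSums(reason_mat)
  out$reasons <- apply(reason_mat, 1, function(v) {
    paste(reason_cols[v], collapse = ",")
  })
  out$recommend_removal <- out$n_reasons > 0
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(v) !is.na(v) & as.logical(v)

#' Removal-candidate report for the consensus meeting
#'
#' Ranks flagged items within each domain by number of reasons and then by a
#' fixed severity order (poor reliability > poor fit > gender effect >
#' duplicate age range > ceiling not reached > subjective). When a target item
#' count per domain is given, the list is truncated to the surplus, but the
#' report only nominates: it never deletes data - final removal is a human
#' decision.
#'
#' @param flags Data frame from [flag_items()].
#' @param target_per_domain Optional desired final item count per domain.
#' @return Data frame of removal candidates, ranked within domain.
#' @export
consensus_report <- function(flags, target_per_domain = NULL) {
  severity <- c("poor_reliability", "poor_fit", "gender_effect",
                "duplicate_age_range", "ceiling_not_reached", "subjective")
  cand <- flags[flags$recommend_removal, , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(domain = character(0), item_id = character(0),
                      rank = integer(0), n_reasons = integer(0),
                      reasons = character(0), stringsAsFactors = FALSE))
  }
  cand$severity_rank <- vapply(seq_len(nrow(cand)), function(i) {
    present <- severity[as.logical(cand[i, severity])]
    if (!length(present)) return(length(severity) + 1L)
    min(match(present, severity))
  }, integer(1))
  rows <- lapply(split(cand, cand$domain), function(d) {
    d <- d[order(-d$n_reasons, d$severity_rank, d$item_id), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    if (!is.null(target_per_domain)) {
      n_current <- sum(flags$domain == d$domain[1])
      surplus <- n_current - target_per_domain
      if (surplus < 0) {
        stop("target count exceeds available items in domain ", d$domain[1])
      }
      d <- d[seq_len(min(surplus, nrow(d))), , drop = FALSE]
    }
    d
  })
  out <- do.call(rbind, rows)
  out <- out[, c("domain", "item_id", "rank", "n_reasons", "reasons")]
  rownames(out) <- NULL
  out
}
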