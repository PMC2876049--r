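#' Cohen's kappa from a 2x2 agreement table
#'
#' po is the observed agreement proportion, pe the chance agreement from the
#' marginals, and kappa = (po - pe) / (1 - pe). When both observers are
#' constant (pe = 1) kappa is undefined and the item is reported not
#' assessable, with po still returned.
#'
#' @param tab 2x2 matrix of non-negative integer counts; rows are observer 1,
#'   columns observer 2, in the same category order.
#' @return List of class `kappa_result`: `po`, `pe`, `kappa`,
#'   `percent_agreement` (= 100 po), `n`, `assessable`.
#' @export
kappa_from_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("agreement counts must be non-negative")
  n <- sum(tab)
  if (n < 1) stop("agreement table must contain at least one observation")
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  assessable <- pe < 1 - 1e-12
  kappa <- if (assessable) (po - pe) / (1 - pe) else NA_real_
  structure(list(po = po, pe = pe, kappa = kappa,
                 percent_agreement = 100 * po, n = n,
                 assessable = assessable),
            class = "kappa_result")
}

#' Band a kappa value
#'
#' Two banding schemes: the Landis-Koch scale (poor, fair, moderate, good,
#' very good, with intervals closed on the upper end) and the three-level
#' reporting scale (excellent > 0.75, fair-to-good 0.4-0.75 inclusive of both
#' endpoints, poor < 0.4).
#'
#' @param kappa A kappa value (NA allowed).
#' @return List with `kappa_band` and `report_band` (NA for NA input).
#' @export
band_kappa <- function(kappa) {
  if (is.na(kappa)) {
    return(list(kappa_band = NA_character_, report_band = NA_character_))
  }
  kappa_band <- if (kappa <= 0.2) "poor"
  else if (kappa <= 0.4) "fair"
  else if (kappa <= 0.6) "moderate"
  else if (kappa <= 0.8) "good"
  else "very_good"
  report_band <- if (kappa > 0.75) "excellent"
  else if (kappa >= 0.4) "fair_to_good"
  else "poor"
  list(kappa_band = kappa_band, report_band = report_band)
}

agreement_band <- function(pct) {
  if (is.na(pct)) return(NA_character_)
  if (pct > 95) "gt95" else if (pct >= 85) "b85_95" else "lt85"
}

#' Per-item observer agreement from paired sessions
#'
#' Pairs the two sessions on (child, item) and computes kappa and percent
#' agreement per item over the observations where both sessions recorded a
#' pass or a fail (items administered in both sessions). Items with no such
#' pair are skipped with a warning.
#'
#' @param session_a,session_b Long response data frames of the two sessions.
#' @param item_bank Item metadata giving each item's domain.
#' @param design Label stored on every row.
#' @return Data frame with one row per item: agreement statistics and bands.
#' @export
item_kappas <- function(session_a, session_b, item_bank, design = "design") {
  key_a <- paste(session_a$child_id, session_a$item_id)
  key_b <- paste(session_b$child_id, session_b$item_id)
  m <- match(key_a, key_b)
  a_out <- session_a$outcome
  b_out <- session_b$outcome[m]
  ok <- !is.na(m) & a_out %in% c("pass", "fail") & b_out %in% c("pass", "fail")
  ids <- intersect(item_bank$item_id, unique(session_a$item_id))
  rows <- lapply(ids, function(id) {
    sel <- ok & session_a$item_id == id
    n <- sum(sel)
    if (n == 0) return(NULL)
    tab <- table(factor(a_out[sel], levels = c("pass", "fail")),
                 factor(b_out[sel], levels = c("pass", "fail")))
    k <- kappa_from_table(tab)
    bands <- band_kappa(k$kappa)
    data.frame(item_id = id,
               domain = item_bank$domain[item_bank$item_id == id],
               design = design,
               n_pairs = n,
               po = k$po, pe = k$pe, kappa = k$kappa,
               percent_agreement = k$percent_agreement,
               kappa_band = bands$kappa_band,
               report_band = bands$report_band,
               agreement_band = agreement_band(k$percent_agreement),
               assessable = k$assessable,
               stringsAsFactors = FALSE)
  })
  skipped <- setdiff(ids, unlist(lapply(rows, function(r) r$item_id)))
  if (length(skipped)) {
    warning(sprintf("%d item(s) without paired observations were skipped",
                    length(skipped)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reliability summary by domain and design
#'
#' Counts (and percentages) of items per domain x design falling in each
#' kappa reporting band (excellent / fair-to-good / poor) and each
#' percent-agreement band (>95 / 85-95 / <85), with a totals row per design.
#' Items whose kappa is not assessable (both observers constant) are counted
#' separately.
#'
#' @param kappas Data frame of per-item agreement rows from [item_kappas()],
#'   possibly concatenated over designs.
#' @return Data frame, one row per domain x design plus totals.
#' @export
reliability_summary <- function(kappas) {
  one <- function(d, label, design) {
    n <- nrow(d)
    cnt <- function(v, lv) sum(v == lv, na.rm = TRUE)
    data.frame(domain = label, design = design, n_items = n,
               excellent_n = cnt(d$report_band, "excellent"),
               excellent_pct = round(100 * cnt(d$report_band, "excellent") / n),
               fair_to_good_n = cnt(d$report_band, "fair_to_good"),
               fair_to_good_pct = round(100 * cnt(d$report_band, "fair_to_good") / n),
               poor_n = cnt(d$report_band, "poor"),
               poor_pct = round(100 * cnt(d$report_band, "poor") / n),
               not_assessable_n = sum(!d$assessable),
               agree_gt95_n = cnt(d$agreement_band, "gt95"),
               agree_85_95_n = cnt(d$agreement_band, "b85_95"),
               agree_lt85_n = cnt(d$agreement_band, "lt85"),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (des in unique(kappas$design)) {
    kd <- kappas[kappas$design == des, , drop = FALSE]
    for (dom in unique(kd$domain)) {
      rows[[paste(des, dom)]] <- one(kd[kd$domain == dom, , drop = FALSE],
                                     dom, des)
    }
    rows[[paste(des, "total")]] <- one(kd, "total", des)
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}
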