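#' Apply the study eligibility screen
#'
#' A child is excluded if weight-for-height Z < -2 (acute malnutrition by WHO
#' criteria), gestation at or below 32 weeks (boundary inclusive), a flagged
#' significant medical problem, or a flagged neurodisability. Exactly one
#' reason is recorded per excluded child, the first matching rule in that
#' order. Children with a missing WHZ cannot be screened and are routed to a
#' separate not-assessable list, never silently included.
#'
#' @param children Data frame with at least `child_id`, `whz`,
#'   `gestation_weeks`; optional logical columns `medical_problem` and
#'   `neurodisability` (absent columns are treated as all-FALSE).
#' @return List with `eligible` (data frame), `exclusions` (data frame of
#'   `child_id`, `reason`), and `not_assessable` (data frame).
#' @export
apply_eligibility <- function(children) {
  assert_columns(children, c("child_id", "whz", "gestation_weeks"), "children")
  medical <- children$medical_problem %||% rep(FALSE, nrow(children))
  neuro <- children$neurodisability %||% rep(FALSE, nrow(children))
  na_whz <- is.na(children$whz)
  reason <- rep(NA_character_, nrow(children))
  reason[is.na(reason) & !na_whz & children$whz < -2] <- "malnutrition_whz"
  reason[is.na(reason) & children$gestation_weeks <= 32] <- "prematurity"
  reason[is.na(reason) & medical %in% TRUE] <- "medical_problem"
  reason[is.na(reason) & neuro %in% TRUE] <- "neurodisability"
  excluded <- !is.na(reason) & !na_whz
  list(eligible = children[!excluded & !na_whz, , drop = FALSE],
       exclusions = data.frame(child_id = children$child_id[excluded],
                               reason = reason[excluded],
                               stringsAsFactors = FALSE),
       not_assessable = children[na_whz, , drop = FALSE])
}

#' Wealth quintiles from household assets by principal components
#'
#' Filmer-Pritchett style wealth index: assets are standardised and projected
#' onto the first principal component of their correlation matrix. The sign of
#' the score is fixed so that a designated wealth-positive asset loads
#' positively. Quintiles are cut at the 20/40/60/80th percentiles of the
#' score, labelled 1 (poorest) to 5 (wealthiest); a score exactly at a cut
#' goes to the lower quintile.
#'
#' @param assets Numeric matrix or data frame of asset indicators (children in
#'   rows). Columns without variance are dropped with a warning.
#' @param wealth_positive Column (index or name) whose loading anchors the
#'   sign of the index.
#' @return Data frame with columns `score` and `quintile`.
#' @export
compute_wealth_quintiles <- function(assets, wealth_positive = 1L) {
  assets <- as.matrix(assets)
  if (nrow(assets) < 5) stop("need at least 5 children to form quintiles")
  vars <- apply(assets, 2, stats::var)
  if (all(vars == 0)) stop("constant asset matrix: no variance to summarise")
  if (any(vars == 0)) {
    warning(sprintf("dropping %d constant asset column(s)", sum(vars == 0)))
    assets <- assets[, vars > 0, drop = FALSE]
  }
  if (ncol(assets) < 2) stop("need at least 2 asset columns with variance")
  if (is.character(wealth_positive)) {
    wealth_positive <- match(wealth_positive, colnames(assets))
  }
  if (is.na(wealth_positive) || wealth_positive > ncol(assets)) {
    stop("wealth_positive column not found among varying assets")
  }
  pca <- stats::prcomp(assets, center = TRUE, scale. = TRUE)
  score <- pca$x[, 1]
  if (pca$rotation[wealth_positive, 1] < 0) score <- -score
  cuts <- stats::quantile(score, probs = c(0.2, 0.4, 0.6, 0.8))
  quintile <- 1L + rowSums(outer(score, cuts, ">"))
  data.frame(score = score, quintile = as.integer(quintile))
}

#' Default quota table: equal-width age groups with equal targets
#'
#' @param n_groups Number of age groups.
#' @param age_range Overall age interval (years), split into equal widths.
#' @param target Target number of children per group.
#' @return Data frame with `age_min`, `age_max` (interval `(age_min, age_max]`)
#'   and `target`.
#' @export
default_quota <- function(n_groups = 34L, age_range = c(0, 6), target = 45L) {
  edges <- seq(age_range[1], age_range[2], length.out = n_groups + 1)
  data.frame(age_min = edges[-length(edges)],
             age_max = edges[-1],
             target = as.integer(target))
}

#' Quota sampling of children within age groups
#'
#' Within each quota age group, children are drawn uniformly at random without
#' replacement until the target or the pool is exhausted; under-filled groups
#' are reported, never fatal.
#'
#' @param children Pool of child records with `decimal_age`.
#' @param quota_table Data frame of non-overlapping `(age_min, age_max]`
#'   intervals with a `target` count each.
#' @param seed Integer seed; the sample is reproducible for a fixed seed.
#' @return List with `sample` (data frame of sampled children) and `report`
#'   (per-group `target`, `available`, `sampled`, `shortfall`).
#' @export
quota_sample <- function(children, quota_table = default_quota(), seed = 1L) {
  assert_columns(children, c("child_id", "decimal_age"), "children")
  assert_columns(quota_table, c("age_min", "age_max", "target"), "quota_table")
  q <- quota_table[order(quota_table$age_min), , drop = FALSE]
  if (any(q$age_min >= q$age_max)) stop("quota intervals must have age_min < age_max")
  if (nrow(q) > 1 && any(q$age_min[-1] < q$age_max[-nrow(q)])) {
    stop("quota age intervals overlap")
  }
  set.seed(derive_seed(seed, 601L))
  picked <- integer(0)
  report <- q
  report$available <- 0L
  report$sampled <- 0L
  for (i in seq_len(nrow(q))) {
    in_grp <- which(children$decimal_age > q$age_min[i] &
                      children$decimal_age <= q$age_max[i])
    k <- min(q$target[i], length(in_grp))
    report$available[i] <- length(in_grp)
    report$sampled[i] <- k
    if (k > 0) picked <- c(picked, in_grp[sample.int(length(in_grp), k)])
  }
  report$shortfall <- report$target - report$sampled
  list(sample = children[sort(picked), , drop = FALSE], report = report)
}
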