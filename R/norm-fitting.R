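#' Fit a single logistic age-of-attainment curve for one item
#'
#' Maximum-likelihood logistic regression of pass/fail on decimal age,
#' P(pass) = 1 / (1 + exp(-(a + b * age))). "Don't know" and not-administered
#' outcomes are dropped before fitting. Non-convergence or (quasi-)complete
#' separation is reported through `converged = FALSE`, never as a silent
#' estimate.
#'
#' @param outcome Character vector of outcomes; only `"pass"`/`"fail"` rows
#'   enter the fit.
#' @param age Decimal ages (years), same length as `outcome`.
#' @param item_id Optional item identifier carried on the result.
#' @return An object of class `item_curve` with fields `item_id`,
#'   `curve_kind = "single"`, `regions` (one row: `lo`, `hi`, `a`, `b`,
#'   `fallback`, `n`), `cut_ages`, `n_used`, `converged`, `deviance`.
#' @export
fit_item_logistic <- function(outcome, age, item_id = NA_character_) {
  keep <- outcome %in% c("pass", "fail")
  y <- outcome[keep] == "pass"
  x <- age[keep]
  if (length(y) == 0 || all(y) || !any(y)) {
    stop(sprintf("degenerate item%s: needs at least one pass and one fail",
                 if (is.na(item_id)) "" else paste0(" '", item_id, "'")),
         call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  converged <- isTRUE(fit$converged) && !separation && all(abs(cf) < 50)
  structure(list(item_id = item_id,
                 curve_kind = "single",
                 regions = data.frame(lo = -Inf, hi = Inf,
                                      a = unname(cf[1]), b = unname(cf[2]),
                                      fallback = FALSE, n = length(y)),
                 cut_ages = NULL,
                 n_used = length(y),
                 converged = converged,
                 deviance = unname(fit$deviance)),
            class = "item_curve")
}

#' Fitted pass probability of an item curve
#'
#' For a triple-split spline curve, each age is evaluated on the regional
#' logistic covering it (regions partition the age axis at the cut ages).
#'
#' @param curve An `item_curve`.
#' @param age Numeric vector of decimal ages.
#' @return Numeric vector of fitted pass probabilities.
#' @export
predict_curve <- function(curve, age) {
  r <- curve$regions
  idx <- rep(1L, length(age))
  if (nrow(r) > 1) {
    for (k in 2:nrow(r)) idx[age > r$lo[k]] <- k
  }
  stats::plogis(r$a[idx] + r$b[idx] * age)
}

#' Deviance (-2 log-likelihood) of an item curve on given data
#'
#' @inheritParams fit_item_logistic
#' @param curve An `item_curve`.
#' @return The deviance of the curve's predictions for the pass/fail rows.
#' @export
curve_deviance <- function(curve, outcome, age) {
  keep <- outcome %in% c("pass", "fail")
  y <- outcome[keep] == "pass"
  p <- predict_curve(curve, age[keep])
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(ifelse(y, log(p), log(1 - p)))
}

# Hosmer-Lemeshow chi-square on one set of fitted probabilities, grouping by
# deciles of fitted probability (ties merged). Returns NULL if fewer than
# min_groups groups remain.
hl_statistic <- function(p, y, g = 10L, min_groups = 3L) {
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1)))
  if (length(breaks) < 2) return(NULL)
  grp <- cut(p, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  O <- tapply(y, grp, sum)
  E <- tapply(p, grp, sum)
  n <- tapply(rep(1, length(y)), grp, sum)
  denom <- E * (1 - E / n)
  ok <- denom > 1e-10
  if (sum(ok) < min_groups) return(NULL)
  list(statistic = sum((O[ok] - E[ok])^2 / denom[ok]), g = sum(ok))
}

#' Hosmer-Lemeshow goodness of fit of an item curve
#'
#' Observations are grouped by deciles of fitted probability (tied deciles
#' merged, the group count reduced accordingly) and the chi-square statistic
#' sum((O - E)^2 / (E (1 - E/n))) is referred to a chi-square distribution on
#' g - 2 degrees of freedom. For a triple-split spline curve the statistic is
#' computed within each region and pooled (statistics and degrees of freedom
#' summed), which tests the piecewise model as fitted. Fewer than 3 usable
#' groups makes the test not assessable (`poor_fit = FALSE`, with a flag).
#'
#' @param curve An `item_curve` with `converged = TRUE`.
#' @param outcome,age Pass/fail outcomes and decimal ages.
#' @param g Number of probability groups per (regional) test.
#' @param alpha Significance level declaring a poor fit.
#' @return List of class `gof_result`: `item_id`, `statistic`, `g`, `df`,
#'   `p_value`, `poor_fit`, `assessable`.
#' @export
goodness_of_fit <- function(curve, outcome, age, g = 10L, alpha = 0.05) {
  stopifnot(inherits(curve, "item_curve"))
  keep <- outcome %in% c("pass", "fail")
  y <- outcome[keep] == "pass"
  x <- age[keep]
  regions <- curve$regions
  stat <- 0
  g_tot <- 0L
  df_tot <- 0L
  for (k in seq_len(nrow(regions))) {
    in_r <- x > regions$lo[k] & x <= regions$hi[k]
    if (!any(in_r)) next
    p <- predict_curve(curve, x[in_r])
    h <- hl_statistic(p, y[in_r], g = g)
    if (is.null(h) || h$g < 3) next
    stat <- stat + h$statistic
    g_tot <- g_tot + h$g
    df_tot <- df_tot + (h$g - 2L)
  }
  if (df_tot < 1) {
    return(structure(list(item_id = curve$item_id, statistic = NA_real_,
                          g = g_tot, df = df_tot, p_value = NA_real_,
                          poor_fit = FALSE, assessable = FALSE),
                     class = "gof_result"))
  }
  p_value <- stats::pchisq(stat, df = df_tot, lower.tail = FALSE)
  structure(list(item_id = curve$item_id, statistic = stat, g = g_tot,
                 df = df_tot, p_value = p_value,
                 poor_fit = p_value < alpha, assessable = TRUE),
            class = "gof_result")
}

#' Triple-split spline refit of a poorly fitting item
#'
#' The ages at which the original single fit predicts 35% and 65% attainment,
#' t35 = (logit(0.35) - a)/b and t65 = (logit(0.65) - a)/b, cut the age axis
#' into three regions; an independent logistic curve is fitted on each (no
#' continuity constraint at the cuts). A region with fewer than `min_region_n`
#' pass/fail observations, a single outcome class, or a non-converged fit
#' falls back to the original curve on that region and is flagged.
#'
#' @param outcome,age Pass/fail outcomes and decimal ages.
#' @param original_curve The converged single `item_curve`.
#' @param min_region_n Minimum observations required per region.
#' @return An `item_curve` with `curve_kind = "spline3"`, three regions, and
#'   `cut_ages = c(t35, t65)`.
#' @export
refit_spline <- function(outcome, age, original_curve, min_region_n = 15L) {
  stopifnot(inherits(original_curve, "item_curve"),
            original_curve$curve_kind == "single")
  a <- original_curve$regions$a[1]
  b <- original_curve$regions$b[1]
  if (b <= 0) {
    stop("non-monotone original fit (slope <= 0): refusing spline refit",
         call. = FALSE)
  }
  t35 <- (stats::qlogis(0.35) - a) / b
  t65 <- (stats::qlogis(0.65) - a) / b
  keep <- outcome %in% c("pass", "fail")
  y <- outcome[keep] == "pass"
  x <- age[keep]
  lo <- c(-Inf, t35, t65)
  hi <- c(t35, t65, Inf)
  regions <- data.frame(lo = lo, hi = hi, a = a, b = b,
                        fallback = TRUE, n = 0L)
  deviance <- 0
  for (k in 1:3) {
    in_r <- x > lo[k] & x <= hi[k]
    regions$n[k] <- sum(in_r)
    yr <- y[in_r]
    if (sum(in_r) >= min_region_n && any(yr) && !all(yr)) {
      separation <- FALSE
      fit <- withCallingHandlers(
        stats::glm(yr ~ x[in_r], family = stats::binomial()),
        warning = function(w) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        })
      cf <- stats::coef(fit)
      if (isTRUE(fit$converged) && !separation && all(abs(cf) < 50)) {
        regions$a[k] <- unname(cf[1])
        regions$b[k] <- unname(cf[2])
        regions$fallback[k] <- FALSE
        deviance <- deviance + fit$deviance
        next
      }
    }
    # fallback: deviance of the parent curve on this region
    if (any(in_r)) {
      p <- pmin(pmax(stats::plogis(a + b * x[in_r]), 1e-12), 1 - 1e-12)
      deviance <- deviance - 2 * sum(ifelse(yr, log(p), log(1 - p)))
    }
  }
  structure(list(item_id = original_curve$item_id,
                 curve_kind = "spline3",
                 regions = regions,
                 cut_ages = c(t35 = t35, t65 = t65),
                 n_used = length(y),
                 converged = TRUE,
                 deviance = deviance),
            class = "item_curve")
}

#' Invert a fitted curve to normative attainment ages
#'
#' For a single curve, the age at attainment probability p is
#' (logit(p) - a)/b. For a triple-split spline each region's curve is solved
#' on its own interval; when several regions contain a solution the earliest
#' age is taken, and when none does the solution from the outer region whose
#' candidate lies closest to its own interval is used and flagged
#' `extrapolated`. Ages outside the observed age range are also flagged.
#'
#' @param curve A converged `item_curve`.
#' @param probs Attainment probabilities to invert (defaults 25/50/75/90%).
#' @param age_range Observed age support `c(min, max)`; solutions outside it
#'   are flagged extrapolated. `NULL` disables the range check.
#' @return List of class `reference_range`: `item_id`, `ages` (named numeric,
#'   `age25` etc.), `extrapolated` (named logical).
#' @export
invert_percentiles <- function(curve, probs = c(0.25, 0.50, 0.75, 0.90),
                               age_range = NULL) {
  stopifnot(inherits(curve, "item_curve"))
  r <- curve$regions
  if (all(r$b <= 0)) stop("non-monotone item: no region with positive slope",
                          call. = FALSE)
  ages <- numeric(length(probs))
  extra <- logical(length(probs))
  for (i in seq_along(probs)) {
    target <- stats::qlogis(probs[i])
    cand <- (target - r$a) / r$b
    cand[r$b <= 0] <- NA_real_
    inside <- !is.na(cand) & cand > r$lo & cand <= r$hi
    if (any(inside)) {
      ages[i] <- min(cand[inside])
    } else {
      # distance from each candidate to its own region; nearest wins,
      # earliest age on ties
      dist <- pmax(r$lo - cand, cand - r$hi, 0)
      dist[is.na(cand)] <- Inf
      best <- which(dist == min(dist))
      ages[i] <- min(cand[best])
      extra[i] <- TRUE
    }
    if (!is.null(age_range) &&
        (ages[i] < age_range[1] || ages[i] > age_range[2])) {
      extra[i] <- TRUE
    }
  }
  labels <- sprintf("age%02d", round(100 * probs))
  structure(list(item_id = curve$item_id,
                 ages = stats::setNames(ages, labels),
                 extrapolated = stats::setNames(extra, labels)),
            class = "reference_range")
}

#' Assemble a normative reference table
#'
#' One row per item with the 25/50/75/90% attainment ages, extrapolation
#' flags, curve kind, and goodness-of-fit results, sorted by median attainment
#' age within domain.
#'
#' @param curves Named list of `item_curve` objects (final fits).
#' @param ranges Named list of `reference_range` objects.
#' @param item_bank Data frame with `item_id`, `domain`, `order_index`.
#' @param gof Optional data frame with per-item `gof_p` and `poor_fit`
#'   (final-stage values) and `refitted`.
#' @return Data frame (the norm table).
#' @export
build_norm_table <- function(curves, ranges, item_bank, gof = NULL) {
  ids <- names(ranges)
  missing <- setdiff(ids, item_bank$item_id)
  if (length(missing)) {
    stop("items absent from item bank: ", paste(missing, collapse = ", "))
  }
  rows <- lapply(ids, function(id) {
    rg <- ranges[[id]]
    cv <- curves[[id]]
    bank <- item_bank[item_bank$item_id == id, , drop = FALSE]
    data.frame(item_id = id,
               domain = bank$domain,
               order_index = bank$order_index,
               curve_kind = cv$curve_kind,
               age25 = rg$ages[["age25"]],
               age50 = rg$ages[["age50"]],
               age75 = rg$ages[["age75"]],
               age90 = rg$ages[["age90"]],
               ex25 = rg$extrapolated[["age25"]],
               ex50 = rg$extrapolated[["age50"]],
               ex75 = rg$extrapolated[["age75"]],
               ex90 = rg$extrapolated[["age90"]],
               n_used = cv$n_used,
               converged = cv$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(gof)) {
    out <- merge(out, gof, by = "item_id", all.x = TRUE, sort = FALSE)
  }
  out <- out[order(match(out$domain, unique(item_bank$domain)), out$age50), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit normative curves for every item of an instrument
#'
#' Per item: single logistic fit, Hosmer-Lemeshow screen at `gof_alpha`,
#' triple-split spline refit of poorly fitting items with a regionwise
#' goodness-of-fit re-check, and inversion to 25/50/75/90% attainment ages.
#' Items that are degenerate (all pass or all fail among administered
#' responses) or whose fit does not converge are reported in `dropped` and
#' excluded from the norm table.
#'
#' @param responses Long response data frame (`child_id`, `item_id`,
#'   `outcome`).
#' @param children Child records supplying `decimal_age`.
#' @param item_bank Item metadata (`item_id`, `domain`, `order_index`).
#' @param gof_alpha Significance level of the goodness-of-fit screen.
#' @param min_region_n Minimum pass/fail observations per spline region.
#' @param g Hosmer-Lemeshow group count.
#' @return List of class `norm_fit`: `curves` (named list of final curves),
#'   `gof` (per-item data frame with single-fit and final-stage results),
#'   `norm_table`, `dropped` (data frame of item_id, status).
#' @export
fit_norms <- function(responses, children, item_bank, gof_alpha = 0.05,
                      min_region_n = 15L, g = 10L) {
  assert_columns(responses, c("child_id", "item_id", "outcome"), "responses")
  assert_columns(children, c("child_id", "decimal_age"), "children")
  resp <- responses[responses$outcome %in% c("pass", "fail"), , drop = FALSE]
  resp$age <- children$decimal_age[match(resp$child_id, children$child_id)]
  age_range <- c(0, max(children$decimal_age))
  by_item <- split(resp[c("outcome", "age")], resp$item_id)
  curves <- list()
  ranges <- list()
  gof_rows <- list()
  dropped <- list()
  for (id in item_bank$item_id) {
    d <- by_item[[id]]
    if (is.null(d) || nrow(d) == 0) {
      dropped[[id]] <- data.frame(item_id = id,
                                  status = "no scoreable responses",
                                  stringsAsFactors = FALSE)
      next
    }
    single <- tryCatch(fit_item_logistic(d$outcome, d$age, item_id = id),
                       error = function(e) conditionMessage(e))
    if (is.character(single)) {
      dropped[[id]] <- data.frame(item_id = id, status = single,
                                  stringsAsFactors = FALSE)
      next
    }
    if (!single$converged) {
      dropped[[id]] <- data.frame(item_id = id, status = "not converged",
                                  stringsAsFactors = FALSE)
      next
    }
    g1 <- goodness_of_fit(single, d$outcome, d$age, g = g, alpha = gof_alpha)
    final <- single
    gf <- g1
    refitted <- FALSE
    if (isTRUE(g1$poor_fit) && single$regions$b[1] > 0) {
      spline <- tryCatch(refit_spline(d$outcome, d$age, single,
                                      min_region_n = min_region_n),
                         error = function(e) NULL)
      if (!is.null(spline)) {
        final <- spline
        gf <- goodness_of_fit(spline, d$outcome, d$age, g = g,
                              alpha = gof_alpha)
        refitted <- TRUE
      }
    }
    rng <- tryCatch(invert_percentiles(final, age_range = age_range),
                    error = function(e) NULL)
    if (is.null(rng)) {
      dropped[[id]] <- data.frame(item_id = id, status = "non-monotone",
                                  stringsAsFactors = FALSE)
      next
    }
    curves[[id]] <- final
    ranges[[id]] <- rng
    gof_rows[[id]] <- data.frame(item_id = id,
                                 gof_p_single = g1$p_value,
                                 poor_fit_single = g1$poor_fit,
                                 refitted = refitted,
                                 gof_p = gf$p_value,
                                 poor_fit = isTRUE(gf$poor_fit),
                                 gof_assessable = gf$assessable,
                                 stringsAsFactors = FALSE)
  }
  gof <- do.call(rbind, unname(gof_rows))
  norm_table <- build_norm_table(curves, ranges, item_bank, gof = gof)
  structure(list(curves = curves,
                 ranges = ranges,
                 gof = gof,
                 norm_table = norm_table,
                 dropped = if (length(dropped)) {
                   do.call(rbind, unname(dropped))
                 } else {
                   data.frame(item_id = character(0), status = character(0))
                 }),
            class = "norm_fit")
}

#' Chart data for milestone box charts
#'
#' One box per item spanning the 25% to 90% attainment ages with ticks at the
#' median and 75% ages, grouped by domain and ordered by median age - the
#' standard box-type milestone chart of age-norm instruments.
#'
#' @param norm_table A norm table from [build_norm_table()] / [fit_norms()].
#' @return A list, one element per domain, each a list of item boxes.
#' @export
chart_data <- function(norm_table) {
  by_dom <- split(norm_table, norm_table$domain)
  lapply(by_dom, function(d) {
    d <- d[order(d$age50), , drop = FALSE]
    lapply(seq_len(nrow(d)), function(i) {
      list(item_id = d$item_id[i],
           lo = d$age25[i], median = d$age50[i],
           q75 = d$age75[i], hi = d$age90[i],
           extrapolated = any(d$ex25[i], d$ex50[i], d$ex75[i], d$ex90[i]))
    })
  })
}

#' Write and read chart data as JSON
#'
#' @param x Chart data from [chart_data()].
#' @param path Output JSON file.
#' @return `write_chart_data` returns `path` invisibly; `read_chart_data`
#'   returns the chart-data list.
#' @export
write_chart_data <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chart_data
#' @export
read_chart_data <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
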