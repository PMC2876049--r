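test_that("logistic fit recovers generating parameters and flags degeneracy", {
  d <- logistic_data(2000, a = -6, b = 3, seed = 41)
  cv <- fit_item_logistic(d$outcome, d$age, item_id = "walks_well")
  expect_true(cv$converged)
  age50 <- -cv$regions$a / cv$regions$b
  expect_lt(abs(age50 - 2.0), 0.1)

  # symmetric toy data: pass fraction 0.3 at age 1, 0.7 at age 3 -> age50 = 2
  sym_out <- c(rep(c("pass", "fail"), c(3, 7)), rep(c("pass", "fail"), c(7, 3)))
  sym_age <- rep(c(1, 3), each = 10)
  sym <- fit_item_logistic(sym_out, sym_age)
  expect_equal(-sym$regions$a / sym$regions$b, 2, tolerance = 1e-6)

  expect_error(fit_item_logistic(rep("pass", 50), runif(50)), "degenerate")
  expect_error(fit_item_logistic(rep("fail", 50), runif(50)), "degenerate")

  # complete separation is reported, never a silent estimate
  sep <- fit_item_logistic(ifelse(1:40 > 20, "pass", "fail"),
                           seq(0, 6, length.out = 40))
  expect_false(sep$converged)
})

test_that("goodness of fit is exact on matched counts and detects misfit", {
  cv <- manual_curve(a = 0, b = 1)
  # five probability groups whose observed counts equal expectations exactly
  probs <- c(0.2, 0.4, 0.5, 0.6, 0.8)
  age <- rep(qlogis(probs), each = 10)
  outcome <- unlist(lapply(probs, function(p) {
    rep(c("pass", "fail"), c(round(10 * p), 10 - round(10 * p)))
  }))
  g <- goodness_of_fit(cv, outcome, age)
  expect_true(g$assessable)
  expect_equal(g$statistic, 0, tolerance = 1e-12)
  expect_equal(g$p_value, 1)
  expect_false(g$poor_fit)

  # grossly misspecified curve is rejected
  d <- logistic_data(1500, a = -6, b = 3, seed = 42)
  bad <- manual_curve(a = -2, b = 1)
  expect_true(goodness_of_fit(bad, d$outcome, d$age)$poor_fit)

  # too few distinct probabilities: not assessable, poor_fit stays FALSE
  flat <- goodness_of_fit(cv, rep(c("pass", "fail"), 10), rep(0, 20))
  expect_false(flat$assessable)
  expect_false(flat$poor_fit)
})

test_that("spline refit cuts at the 35%/65% attainment ages and fits regions", {
  d <- logistic_data(3000, a = -6, b = 3, seed = 43)
  single <- fit_item_logistic(d$outcome, d$age)
  sp <- refit_spline(d$outcome, d$age, single)
  # closed form at the true parameters: (qlogis(.35) + 6)/3 etc.
  a <- single$regions$a
  b <- single$regions$b
  expect_equal(unname(sp$cut_ages["t35"]), (qlogis(0.35) - a) / b)
  expect_equal(unname(sp$cut_ages["t65"]), (qlogis(0.65) - a) / b)
  expect_lt(abs(sp$cut_ages[["t35"]] - 1.7937), 0.12)
  expect_lt(abs(sp$cut_ages[["t65"]] - 2.2064), 0.12)
  expect_equal(sp$curve_kind, "spline3")
  expect_equal(nrow(sp$regions), 3)

  # each regional MLE can only improve on the parent curve regionwise
  expect_lte(curve_deviance(sp, d$outcome, d$age),
             curve_deviance(single, d$outcome, d$age) + 1e-8)

  # refusal on a non-monotone original fit
  flipped <- manual_curve(a = 6, b = -3)
  expect_error(refit_spline(d$outcome, d$age, flipped), "non-monotone")

  # sparse regions fall back to the parent curve and are flagged
  tiny <- logistic_data(40, a = -6, b = 3, seed = 44)
  single_tiny <- fit_item_logistic(tiny$outcome, tiny$age)
  sp_tiny <- refit_spline(tiny$outcome, tiny$age, single_tiny,
                          min_region_n = 50)
  expect_true(all(sp_tiny$regions$fallback))
  expect_equal(sp_tiny$regions$a, rep(single_tiny$regions$a, 3))
})

test_that("percentile inversion satisfies the logistic identities", {
  c1 <- manual_curve(a = 0, b = 1)
  r1 <- invert_percentiles(c1)
  expect_equal(unname(r1$ages["age50"]), 0)
  expect_equal(unname(r1$ages["age90"]), log(9), tolerance = 1e-12)

  c2 <- manual_curve(a = -6, b = 3)
  r2 <- invert_percentiles(c2)
  expect_equal(unname(r2$ages["age90"]), (qlogis(0.9) + 6) / 3)
  expect_equal(unname(r2$ages["age90"]), 2.7324, tolerance = 1e-4)

  # single-curve symmetry: age25 + age75 = 2 * age50, monotone percentiles
  for (s in 1:5) {
    set.seed(s)
    cv <- manual_curve(a = runif(1, -8, 0), b = runif(1, 0.5, 5))
    r <- invert_percentiles(cv)
    expect_equal(r$ages[["age25"]] + r$ages[["age75"]], 2 * r$ages[["age50"]],
                 tolerance = 1e-10)
    expect_true(all(diff(r$ages) >= 0))
  }

  # out-of-range solutions are flagged extrapolated
  r3 <- invert_percentiles(manual_curve(a = -18, b = 3), age_range = c(0, 6))
  expect_true(r3$extrapolated[["age90"]])

  expect_error(invert_percentiles(manual_curve(a = 2, b = -1)),
               "non-monotone")
})

test_that("fit_norms produces a complete, ordered norm table", {
  bank <- small_bank(items_per_domain = 8)
  pop <- generate_population(cohort_config(n = 1200), seed = 45)
  resp <- administer_assessment(pop, bank, protocol_config(), seed = 45)
  nf <- fit_norms(resp, pop, bank)
  expect_s3_class(nf$norm_table, "data.frame")
  expect_equal(nrow(nf$norm_table) + nrow(nf$dropped), nrow(bank))
  # sorted by median age within domain
  for (d in unique(nf$norm_table$domain)) {
    a50 <- nf$norm_table$age50[nf$norm_table$domain == d]
    expect_equal(a50, sort(a50))
  }
  # GOF decision depends only on outcomes and fitted probabilities: rerunning
  # on the same data reproduces it exactly (all fits are deterministic)
  nf2 <- fit_norms(resp, pop, bank)
  expect_identical(nf$norm_table, nf2$norm_table)

  # chart data round-trips through JSON
  cd <- chart_data(nf$norm_table)
  expect_equal(sum(lengths(cd)), nrow(nf$norm_table))
  path <- tempfile(fileext = ".json")
  write_chart_data(cd, path)
  back <- read_chart_data(path)
  expect_equal(back, cd, tolerance = 1e-12)

  # a degenerate all-pass item is reported, not silently normed
  resp_deg <- resp
  resp_deg$outcome[resp_deg$item_id == bank$item_id[1] &
                     resp_deg$outcome != "not_administered"] <- "pass"
  nf3 <- fit_norms(resp_deg, pop, bank)
  expect_true(bank$item_id[1] %in% nf3$dropped$item_id)
  expect_false(bank$item_id[1] %in% nf3$norm_table$item_id)
})
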