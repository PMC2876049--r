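test_that("matched-control selection respects sex and one-decimal age", {
  cases <- data.frame(child_id = c("c1", "c2", "c3"),
                      decimal_age = c(2.34, 4.00, 1.20),
                      sex = c("female", "male", "female"),
                      stringsAsFactors = FALSE)
  pool <- data.frame(child_id = sprintf("p%d", 1:6),
                     decimal_age = c(2.31, 2.26, 2.37, 4.01, 1.21, 1.18),
                     sex = c("female", "female", "female", "male", "male",
                             "female"),
                     stringsAsFactors = FALSE)
  res <- select_matched_controls(cases, pool, seed = 3)
  pr <- res$pairs
  # c1 (age key 2.3) can only match p1 or p2, never p3 (2.4)
  expect_true(pr$control_id[pr$case_id == "c1"] %in% c("p1", "p2"))
  # matching never crosses sex: c3 (female, 1.2) must take p6, not p5
  expect_equal(pr$control_id[pr$case_id == "c3"], "p6")
  expect_equal(pr$control_id[pr$case_id == "c2"], "p4")
  # bijection on the matched subsets
  expect_equal(anyDuplicated(pr$control_id), 0)
  expect_equal(anyDuplicated(pr$case_id), 0)
  # deterministic rerun
  expect_identical(select_matched_controls(cases, pool, seed = 3)$pairs, pr)

  # exact duplicate pool: every case matched; shortfalls reported, not fatal
  dup_pool <- transform(cases, child_id = paste0("x", child_id))
  expect_equal(nrow(select_matched_controls(cases, dup_pool, seed = 1)$pairs),
               3)
  lone <- select_matched_controls(cases, pool[4, , drop = FALSE], seed = 1)
  expect_setequal(lone$unmatched, c("c1", "c3"))

  expect_error(select_matched_controls(cases, cases, seed = 1), "disjoint")
})

test_that("McNemar on discordant pairs matches the closed form and stats", {
  # b = 2, c = 8 -> chi-square (2-8)^2/10 = 3.6
  case_pass <- c(rep(TRUE, 2), rep(FALSE, 8), rep(TRUE, 30), rep(FALSE, 10))
  ctrl_pass <- c(rep(FALSE, 2), rep(TRUE, 8), rep(TRUE, 30), rep(FALSE, 10))
  mc <- mcnemar_paired(case_pass, ctrl_pass)
  expect_equal(mc$b, 2)
  expect_equal(mc$c, 8)
  expect_equal(mc$statistic, 3.6)
  oracle <- mcnemar.test(table(case_pass, ctrl_pass), correct = FALSE)
  expect_equal(mc$statistic, unname(oracle$statistic))
  expect_equal(mc$p_value, oracle$p.value)

  # balanced discordance: no signal
  eq <- mcnemar_paired(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # no discordant pairs at all
  expect_equal(mcnemar_paired(c(TRUE, TRUE), c(TRUE, TRUE))$p_value, 1)
  # one-sided discordance: exact binomial tail reported alongside
  ex <- mcnemar_paired(rep(FALSE, 20), rep(TRUE, 20))
  expect_equal(ex$exact_p, 2 * 0.5^20)
  expect_equal(ex$exact_p,
               binom.test(0, 20, 0.5)$p.value, tolerance = 1e-12)
})

test_that("paired t matches a brute-force computation", {
  set.seed(81)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    case <- rnorm(n, 10, 3)
    ctrl <- case + rnorm(n, 2, 1)
    res_t <- paired_t(case, ctrl)
    d <- ctrl - case
    t_oracle <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(res_t$t, t_oracle, tolerance = 1e-10)
    expect_equal(res_t$p_value, 2 * pt(-abs(t_oracle), n - 1), tolerance = 1e-10)
    expect_equal(res_t$mean_difference, mean(d))
  }
  # identical vectors: zero difference, p not assessable
  same <- paired_t(1:5, 1:5)
  expect_equal(same$t, 0)
  expect_equal(same$mean_difference, 0)
  expect_true(is.na(same$p_value))
  # constant difference with tiny noise recovers the shift
  shifted <- paired_t(1:20, 1:20 + 3 + rnorm(20, 0, 1e-6))
  expect_equal(shifted$mean_difference, 3, tolerance = 1e-3)
  expect_error(paired_t(1, 2), "pairs")
})

test_that("diagnostic accuracy reproduces printed-style counts and CIs", {
  # 4 of 80 cases passing, 79 of 80 controls passing
  acc <- diagnostic_accuracy(76, 80, 1, 80)
  expect_equal(acc$sensitivity, 0.95)
  expect_equal(round(acc$specificity, 2), 0.99)
  # Wilson interval equals prop.test without continuity correction
  ci <- prop.test(76, 80, correct = FALSE)$conf.int
  expect_equal(unname(acc$sensitivity_ci), c(ci[1], ci[2]), tolerance = 1e-10)
  # degenerate corner: no cases failing
  none <- diagnostic_accuracy(0, 50, 0, 50)
  expect_equal(none$sensitivity, 0)
  expect_equal(unname(none$sensitivity_ci["lower"]), 0)
  expect_error(diagnostic_accuracy(1, 0, 1, 10), "denominator")
})

test_that("the validation report is internally consistent", {
  bank <- small_bank(items_per_domain = 8)
  pop <- generate_population(cohort_config(n = 500), seed = 82)
  resp <- administer_assessment(pop, bank, protocol_config(), seed = 82)
  nf <- fit_norms(resp, pop, bank)
  scores <- score_children(resp, nf$norm_table, pop)
  clin <- generate_clinical_groups(bank, clinical_config(
    n_neurodisability = 40L, n_marasmus = 40L), seed = 82)
  cscores <- score_children(clin$responses, nf$norm_table, clin$children)
  cases <- clin$children[clin$children$clinical_group == "neurodisability", ]
  pairs <- select_matched_controls(cases, pop, seed = 82)$pairs
  rep5 <- validation_report(cscores, scores, pairs)
  expect_equal(rep5$domain, c(milestone_domains(), "all_domains"))
  # printed sensitivity/specificity equal the report's own printed counts
  expect_equal(rep5$sensitivity,
               (rep5$n_pairs - rep5$cases_passing) / rep5$n_pairs)
  expect_equal(rep5$specificity, rep5$controls_passing / rep5$n_pairs)
  expect_true(all(rep5$cases_passing <= rep5$n_pairs))

  # identical groups: every McNemar statistic is zero
  self <- validation_report(scores, scores,
                            data.frame(case_id = scores$child_id[1:50],
                                       control_id = scores$child_id[1:50]),
                            include_accuracy = FALSE)
  expect_true(all(self$mcnemar_statistic == 0))
  expect_true(all(self$mean_difference == 0))
})
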