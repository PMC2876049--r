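test_that("item bank has the configured structure and is reproducible", {
  bank <- generate_item_bank(seed = 3)
  expect_equal(nrow(bank), 136)
  expect_equal(unname(table(bank$domain)[milestone_domains()]),
               rep(34L, 4), ignore_attr = TRUE)
  # order_index unique within domain, median ages sorted along it
  for (d in milestone_domains()) {
    sub <- bank[bank$domain == d, ]
    expect_equal(sort(sub$order_index), 1:34)
    expect_equal(sub$age50_true, sort(sub$age50_true))
  }
  expect_true(all(bank$slope > 0) && all(bank$plateau_slope > 0))

  single_only <- generate_item_bank(item_bank_config(piecewise_fraction = 0),
                                    seed = 3)
  expect_true(all(single_only$curve_kind == "single"))

  expect_identical(generate_item_bank(seed = 3), bank)
  expect_error(item_bank_config(age50_span = c(3, 3)), "span")
  expect_error(item_bank_config(slope_range = c(-1, 2)), "positive")
})

test_that("population emulates the target cohort composition", {
  pop <- generate_population(seed = 4)
  expect_equal(nrow(pop), 1513)
  # stunting prevalence near the field-study value of 38%
  expect_lt(abs(mean(pop$haz < -2) - 0.38), 0.05)
  expect_true(all(pop$ses_quintile %in% 1:5))
  expect_true(all(is.finite(pop$haz) & is.finite(pop$waz) &
                    is.finite(pop$whz)))
  expect_true(all(pop$decimal_age >= 0 & pop$decimal_age <= 6))

  one <- generate_population(cohort_config(n = 1), seed = 4)
  expect_equal(nrow(one), 1)
  expect_false(anyNA(one))
  expect_error(cohort_config(n = 0), "positive")
})

test_that("stopping rule truncates per domain after seven consecutive fails", {
  bank <- small_bank(items_per_domain = 34)
  protocol <- protocol_config(dont_know_prob = 0)
  kid <- data.frame(child_id = "K1", decimal_age = 3, performance_age = 3,
                    sex = "male", ses_quintile = 3L, haz = 0, waz = 0,
                    stringsAsFactors = FALSE)

  # pass probability ~1 everywhere: every item administered
  easy <- bank
  easy$age50_true <- -20
  easy$t1 <- ifelse(is.na(easy$t1), NA, -21)
  easy$t2 <- ifelse(is.na(easy$t2), NA, -19)
  r <- administer_assessment(kid, easy, protocol, seed = 1)
  expect_equal(sum(r$outcome == "not_administered"), 0)
  expect_equal(sum(r$outcome == "pass"), nrow(easy))

  # pass probability ~0 everywhere: exactly 7 fails then 27 unreached per domain
  hard <- bank
  hard$age50_true <- 100
  r <- administer_assessment(kid, hard, protocol, seed = 1)
  by_dom <- split(r, bank$domain[match(r$item_id, bank$item_id)])
  for (d in by_dom) {
    expect_equal(sum(d$outcome == "fail"), 7)
    expect_equal(sum(d$outcome == "not_administered"), 27)
  }

  # failing out of gross motor does not truncate fine motor
  mixed <- bank
  mixed$age50_true <- ifelse(mixed$domain == "gross_motor", 100, -20)
  r <- administer_assessment(kid, mixed, protocol, seed = 1)
  dom <- bank$domain[match(r$item_id, bank$item_id)]
  expect_equal(sum(r$outcome == "not_administered" & dom == "fine_motor"), 0)
  expect_equal(sum(r$outcome == "fail" & dom == "gross_motor"), 7)

  expect_error(protocol_config(stop_run_length = 0), "stop_run_length")
})

test_that("responses are exhaustive and consistent with replaying the stop rule", {
  bank <- small_bank(items_per_domain = 10)
  pop <- small_pop(n = 50)
  r <- administer_assessment(pop, bank, protocol_config(), seed = 9)
  expect_equal(nrow(r), nrow(pop) * nrow(bank))
  expect_true(all(r$outcome %in% c("pass", "fail", "dont_know",
                                   "not_administered")))
  # replay: within each child x domain, not_administered is exactly the tail
  # after the 7th consecutive fail
  r$domain <- bank$domain[match(r$item_id, bank$item_id)]
  r$ord <- bank$order_index[match(r$item_id, bank$item_id)]
  for (key in split(r, list(r$child_id, r$domain))) {
    key <- key[order(key$ord), ]
    consec <- 0
    stopped_at <- NA
    for (i in seq_len(nrow(key))) {
      if (!is.na(stopped_at)) break
      if (key$outcome[i] == "fail") consec <- consec + 1
      else if (key$outcome[i] == "pass") consec <- 0
      if (consec >= 7) stopped_at <- i
    }
    if (is.na(stopped_at)) {
      expect_true(all(key$outcome != "not_administered"))
    } else {
      expect_true(all(key$outcome[seq_len(stopped_at)] != "not_administered"))
      if (stopped_at < nrow(key)) {
        expect_true(all(key$outcome[(stopped_at + 1):nrow(key)] ==
                          "not_administered"))
      }
    }
  }
})

test_that("empirical pass fractions converge to the true curves", {
  bank <- small_bank(items_per_domain = 4)
  pop <- generate_population(cohort_config(n = 5000), seed = 13)
  r <- administer_assessment(pop, bank, protocol_config(dont_know_prob = 0),
                             seed = 13)
  r$age <- pop$decimal_age[match(r$child_id, pop$child_id)]
  bins <- seq(0, 6, by = 0.5)
  for (id in sample(bank$item_id, 6)) {
    item <- bank[bank$item_id == id, ]
    sub <- r[r$item_id == id & r$outcome %in% c("pass", "fail"), ]
    grp <- cut(sub$age, bins)
    emp <- tapply(sub$outcome == "pass", grp, mean)
    n_bin <- tapply(sub$age, grp, length)
    mid <- (bins[-length(bins)] + bins[-1]) / 2
    usable <- !is.na(emp) & n_bin >= 150
    expect_true(all(abs(emp[usable] -
                          true_pass_probability(item, mid[usable])) < 0.08))
  }
})

test_that("reliability sessions agree perfectly at flip probability zero and
           decorrelate at one half", {
  bank <- small_bank(items_per_domain = 8)
  pop <- small_pop(n = 200)
  perfect <- agreement_config(flip_prob = c(inter_immediate = 0,
                                            inter_delayed = 0,
                                            intra_delayed = 0))
  s <- generate_reliability_sessions(pop, bank, "inter_immediate", perfect,
                                     seed = 2)
  expect_identical(s$session_a$outcome, s$session_b$outcome)
  k <- suppressWarnings(item_kappas(s$session_a, s$session_b, bank,
                                    "inter_immediate"))
  expect_true(all(k$kappa[k$assessable] == 1))
  expect_true(all(k$percent_agreement == 100))

  coin <- agreement_config(flip_prob = c(inter_immediate = 0.5,
                                         inter_delayed = 0.5,
                                         intra_delayed = 0.5),
                           n_children = c(inter_immediate = 124L,
                                          inter_delayed = 124L,
                                          intra_delayed = 124L))
  s2 <- generate_reliability_sessions(pop, bank, "intra_delayed", coin,
                                      seed = 2)
  k2 <- suppressWarnings(item_kappas(s2$session_a, s2$session_b, bank,
                                     "intra_delayed"))
  expect_lt(abs(mean(k2$kappa[k2$assessable], na.rm = TRUE)), 0.1)
  expect_error(generate_reliability_sessions(pop, bank, "bogus"), "arg")
})

test_that("clinical groups have the configured sizes and shifts", {
  bank <- small_bank(items_per_domain = 5)
  clin <- generate_clinical_groups(bank, seed = 5)
  expect_equal(sum(clin$children$clinical_group == "neurodisability"), 80)
  expect_equal(sum(clin$children$clinical_group == "marasmus"), 120)
  nd <- clin$children[clin$children$clinical_group == "neurodisability", ]
  ma <- clin$children[clin$children$clinical_group == "marasmus", ]
  expect_equal(nd$performance_age, 0.35 * nd$decimal_age)
  expect_equal(ma$performance_age, pmax(0, ma$decimal_age - 0.75))
  expect_equal(nrow(clin$responses), nrow(clin$children) * nrow(bank))

  # zero shift leaves performance age at chronological age
  none <- generate_clinical_groups(bank,
                                   clinical_config(nd_age_factor = 1,
                                                   marasmus_age_offset = 0),
                                   seed = 5)
  expect_equal(none$children$performance_age, none$children$decimal_age)
  expect_error(clinical_config(nd_age_factor = -0.1), "non-negative")
})
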