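# Small generator configurations shared across tests.

no_covariates <- function() list(sex = 0, ses = 0, haz = 0, waz = 0)

small_bank <- function(seed = 1, items_per_domain = 5, ...) {
  generate_item_bank(item_bank_config(items_per_domain = items_per_domain,
                                      piecewise_fraction = 0,
                                      covariate_prevalence = no_covariates(),
                                      ...),
                     seed = seed)
}

small_pop <- function(seed = 1, n = 200) {
  generate_population(cohort_config(n = n), seed = seed)
}

# Direct single-logistic item data, bypassing the administration machinery.
logistic_data <- function(n, a, b, seed, age_range = c(0, 6)) {
  set.seed(seed)
  age <- runif(n, age_range[1], age_range[2])
  outcome <- ifelse(runif(n) < plogis(a + b * age), "pass", "fail")
  list(outcome = outcome, age = age)
}

# A hand-built single item_curve (the documented structure).
manual_curve <- function(a, b, item_id = "item") {
  structure(list(item_id = item_id, curve_kind = "single",
                 regions = data.frame(lo = -Inf, hi = Inf, a = a, b = b,
                                      fallback = FALSE, n = 0L),
                 cut_ages = NULL, n_used = 0L, converged = TRUE,
                 deviance = NA_real_),
            class = "item_curve")
}

# A minimal norm table for scoring tests.
toy_norm_table <- function() {
  data.frame(item_id = c("gm_1", "gm_2", "gm_3", "fm_1", "fm_2", "fm_3"),
             domain = rep(c("gross_motor", "fine_motor"), each = 3),
             age25 = c(0.5, 1.0, 1.5, 0.4, 0.9, 1.4),
             age50 = c(0.7, 1.2, 1.7, 0.6, 1.1, 1.6),
             age75 = c(0.9, 1.4, 1.9, 0.8, 1.3, 1.8),
             age90 = c(1.1, 1.6, 2.1, 1.0, 1.5, 2.0),
             ex25 = FALSE, ex50 = FALSE, ex75 = FALSE, ex90 = FALSE,
             stringsAsFactors = FALSE)
}

toy_responses <- function(child_id, outcomes) {
  data.frame(child_id = child_id,
             item_id = c("gm_1", "gm_2", "gm_3", "fm_1", "fm_2", "fm_3"),
             session_id = "s1",
             outcome = outcomes,
             stringsAsFactors = FALSE)
}
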