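#' Configuration of the full norming-and-validation pipeline
#'
#' Defaults reproduce a study-shaped run: roughly 1,500 recruited children, a
#' 136-item bank, reliability subsamples of 56/52/124 children, and clinical
#' comparison groups of 80 (neurodisability) and 120 (marasmus).
#'
#' @param seed Run seed; all randomness derives from it.
#' @param out_dir Output directory for the stage CSVs and manifest.
#' @param cohort A [cohort_config()].
#' @param items An [item_bank_config()].
#' @param protocol A [protocol_config()].
#' @param agreement An [agreement_config()].
#' @param clinical A [clinical_config()].
#' @param quota_target Per-group quota target (34 equal-width age groups).
#' @param gof_alpha Goodness-of-fit significance level.
#' @param min_region_n Minimum observations per spline region.
#' @param duplicate_tol Duplicate-age-range tolerance (years).
#' @param rules A [scoring_rules()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("milenorm_run_"),
                            cohort = cohort_config(),
                            items = item_bank_config(),
                            protocol = protocol_config(),
                            agreement = agreement_config(),
                            clinical = clinical_config(),
                            quota_target = 45L,
                            gof_alpha = 0.05,
                            min_region_n = 15L,
                            duplicate_tol = 0.05,
                            rules = scoring_rules()) {
  structure(as.list(environment()), class = "pipeline_config")
}

log_line <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, sprintf(fmt, ...)))
}

write_stage <- function(df, out_dir, name) {
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

#' Run the full norming-and-validation pipeline
#'
#' Sequences simulate, prepare (eligibility, wealth quintiles, quota),
#' fit-norms, screen-covariates, score, reliability, flag-items, and validate.
#' Every stage writes its CSV artifacts to `config$out_dir`, and a manifest
#' records the seed, a configuration hash, and the stage counts, so two runs
#' with the same configuration and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- simulate ---------------------------------------------------------------
  bank <- run_stage("simulate", generate_item_bank(config$items,
                                                   seed = derive_seed(seed, 1L)))
  recruited <- run_stage("simulate", generate_population(config$cohort,
                                                         seed = derive_seed(seed, 2L)))
  log_line("simulate", "%d items, %d children recruited",
           nrow(bank), nrow(recruited))
  write_stage(bank, out_dir, "items.csv")

  # -- prepare ----------------------------------------------------------------
  elig <- run_stage("prepare", apply_eligibility(recruited))
  quota <- run_stage("prepare", quota_sample(
    elig$eligible,
    default_quota(config$cohort$n_age_groups, config$cohort$age_range,
                  config$quota_target),
    seed = derive_seed(seed, 3L)))
  cohort <- quota$sample
  asset_cols <- grep("^asset_", names(cohort), value = TRUE)
  wealth <- run_stage("prepare",
                      compute_wealth_quintiles(cohort[, asset_cols]))
  cohort$ses_quintile <- wealth$quintile
  log_line("prepare", "%d eligible, %d excluded, %d analyzed",
           nrow(elig$eligible), nrow(elig$exclusions), nrow(cohort))
  write_stage(cohort, out_dir, "children.csv")
  write_stage(elig$exclusions, out_dir, "exclusions.csv")
  write_stage(quota$report, out_dir, "quota_report.csv")

  # -- administer -------------------------------------------------------------
  responses <- run_stage("administer",
                         administer_assessment(cohort, bank, config$protocol,
                                               seed = derive_seed(seed, 4L)))
  write_stage(responses[, c("child_id", "item_id", "session_id", "outcome")],
              out_dir, "responses.csv")
  log_line("administer", "%d response records", nrow(responses))

  # -- fit-norms --------------------------------------------------------------
  norms <- run_stage("fit-norms",
                     fit_norms(responses, cohort, bank,
                               gof_alpha = config$gof_alpha,
                               min_region_n = config$min_region_n))
  write_stage(norms$norm_table, out_dir, "norms.csv")
  write_chart_data(chart_data(norms$norm_table),
                   file.path(out_dir, "chart_data.json"))
  log_line("fit-norms", "%d items fitted, %d dropped, %d refitted",
           nrow(norms$norm_table), nrow(norms$dropped),
           sum(norms$gof$refitted))

  # -- screen-covariates ------------------------------------------------------
  effects <- run_stage("screen-covariates",
                       screen_covariates(responses, cohort, bank))
  table2 <- summarize_covariate_effects(effects, bank, gof = norms$gof)
  write_stage(effects, out_dir, "covariate_effects.csv")
  write_stage(table2, out_dir, "table2_summary.csv")
  log_line("screen-covariates", "%d effects tested", nrow(effects))

  # -- score ------------------------------------------------------------------
  scores <- run_stage("score",
                      score_children(responses, norms$norm_table, cohort,
                                     rules = config$rules))
  write_stage(scores, out_dir, "scores.csv")
  log_line("score", "%d children scored, %.1f%% failing overall",
           nrow(scores), 100 * mean(!scores$overall_pass))

  # -- reliability ------------------------------------------------------------
  designs <- c("inter_immediate", "inter_delayed", "intra_delayed")
  kappas <- do.call(rbind, lapply(seq_along(designs), function(i) {
    s <- run_stage("reliability",
                   generate_reliability_sessions(cohort, bank, designs[i],
                                                 config$agreement,
                                                 config$protocol,
                                                 seed = derive_seed(seed, 10L + i)))
    suppressWarnings(item_kappas(s$session_a, s$session_b, bank,
                                 design = designs[i]))
  }))
  table3 <- reliability_summary(kappas)
  write_stage(kappas, out_dir, "reliability.csv")
  write_stage(table3, out_dir, "table3_summary.csv")
  log_line("reliability", "%d item x design agreement rows", nrow(kappas))

  # -- flag-items -------------------------------------------------------------
  flags <- run_stage("flag-items",
                     flag_items(norms$norm_table, kappas, effects,
                                duplicate_tol = config$duplicate_tol))
  report <- consensus_report(flags)
  write_stage(flags, out_dir, "flags.csv")
  write_stage(report, out_dir, "consensus_report.csv")
  log_line("flag-items", "%d removal candidates", nrow(report))

  # -- validate ---------------------------------------------------------------
  clin <- run_stage("validate",
                    generate_clinical_groups(bank, config$clinical,
                                             config$protocol,
                                             seed = derive_seed(seed, 20L),
                                             cohort = config$cohort))
  clin_scores <- score_children(clin$responses, norms$norm_table,
                                clin$children, rules = config$rules)
  validations <- list()
  for (grp in c("neurodisability", "marasmus")) {
    cases <- clin$children[clin$children$clinical_group == grp, , drop = FALSE]
    matched <- select_matched_controls(cases, cohort,
                                       seed = derive_seed(seed, 30L +
                                                            (grp == "marasmus")))
    rep_grp <- validation_report(
      clin_scores, scores, matched$pairs,
      include_accuracy = (grp == "neurodisability"))
    rep_grp$group <- grp
    validations[[grp]] <- list(pairs = matched, report = rep_grp)
    write_stage(rep_grp, out_dir, sprintf("table5_%s.csv", grp))
    log_line("validate", "%s: %d pairs matched, %d unmatched", grp,
             nrow(matched$pairs), length(matched$unmatched))
  }

  manifest <- list(
    package = "milenorm",
    version = as.character(utils::packageVersion("milenorm")),
    seed = seed,
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    counts = list(recruited = nrow(recruited),
                  excluded = nrow(elig$exclusions),
                  analyzed = nrow(cohort),
                  items = nrow(bank),
                  items_fitted = nrow(norms$norm_table),
                  neurodisability = config$clinical$n_neurodisability,
                  marasmus = config$clinical$n_marasmus))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(item_bank = bank, recruited = recruited, eligibility = elig,
                 cohort = cohort, responses = responses, norms = norms,
                 effects = effects, table2 = table2, scores = scores,
                 kappas = kappas, table3 = table3, flags = flags,
                 consensus = report, clinical = clin,
                 clinical_scores = clin_scores,
                 validation = validations, manifest = manifest))
}
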