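#' Configuration for a synthetic milestone item bank
#'
#' Describes the true (generating) item bank: four domains of binary milestone
#' items whose pass probability rises with decimal age along a logistic curve
#' on the logit scale, optionally with a three-region piecewise-linear logit
#' (a mid-curve plateau), and with optional covariate effects (sex,
#' socioeconomic quintile, height-for-age and weight-for-age Z-scores) that
#' enter additively on the logit scale.
#'
#' Defaults emulate a 136-item instrument (34 items per domain) whose median
#' attainment ages span early infancy to the sixth year, with the per-domain
#' fractions of piecewise (plateaued) items and covariate-effect prevalences
#' chosen to resemble a field-normed screening tool: no plateaued gross-motor
#' items, roughly 40-55% plateaued items elsewhere, rare sex effects, and
#' nutritional-status effects on about half of the items.
#'
#' @param items_per_domain Number of items in each domain.
#' @param domains Character vector of domain names.
#' @param age50_span Range (years) over which true median attainment ages are
#'   spread, in administration order.
#' @param slope_range Range of the logit-per-year slope outside any plateau.
#' @param piecewise_fraction Fraction of items per domain (scalar or named per
#'   domain) generated with a three-region plateaued logit.
#' @param plateau_factor Multiplier (< 1) applied to the slope in the middle
#'   region of plateaued items; the plateau spans pass probabilities 0.35-0.65.
#' @param covariate_prevalence Named list (sex, ses, haz, waz) of per-domain
#'   probabilities that an item carries that covariate effect.
#' @param effect_sizes Named vector of logit effect magnitudes: sex contrast
#'   (male vs female, random sign per item), per-quintile SES step, and per
#'   Z-score-unit HAZ/WAZ slopes.
#' @return A list of class `item_bank_config`.
#' @export
item_bank_config <- function(items_per_domain = 34L,
                             domains = milestone_domains(),
                             age50_span = c(0.15, 5.5),
                             slope_range = c(1.5, 4.5),
                             piecewise_fraction = c(gross_motor = 0,
                                                    fine_motor = 14 / 34,
                                                    language = 19 / 34,
                                                    social = 17 / 34),
                             plateau_factor = 1 / 3,
                             covariate_prevalence = list(
                               sex = c(gross_motor = 1, fine_motor = 2,
                                       language = 0, social = 5) / 34,
                               ses = c(gross_motor = 3, fine_motor = 5,
                                       language = 7, social = 9) / 34,
                               haz = c(gross_motor = 17, fine_motor = 18,
                                       language = 22, social = 16) / 34,
                               waz = c(gross_motor = 18, fine_motor = 17,
                                       language = 19, social = 13) / 34),
                             effect_sizes = c(sex = 0.6, ses = 0.2,
                                              haz = 0.45, waz = 0.45)) {
  if (items_per_domain < 1) stop("items_per_domain must be >= 1")
  if (length(age50_span) != 2 || age50_span[1] >= age50_span[2]) {
    stop("invalid age50_span: min must be < max")
  }
  if (any(slope_range <= 0)) stop("slopes must be positive")
  if (plateau_factor <= 0 || plateau_factor > 1) {
    stop("plateau_factor must be in (0, 1]")
  }
  pw <- per_domain(piecewise_fraction, domains, "piecewise_fraction")
  if (any(pw < 0 | pw > 1)) stop("piecewise_fraction must be in [0, 1]")
  prev <- lapply(covariate_prevalence, per_domain, domains = domains,
                 what = "covariate_prevalence")
  structure(list(items_per_domain = as.integer(items_per_domain),
                 domains = domains,
                 age50_span = age50_span,
                 slope_range = slope_range,
                 piecewise_fraction = pw,
                 plateau_factor = plateau_factor,
                 covariate_prevalence = prev,
                 effect_sizes = effect_sizes),
            class = "item_bank_config")
}

#' Generate a synthetic item bank with known true curves
#'
#' True median attainment ages are laid out on a jittered grid over
#' `age50_span` and sorted, so administration order (`order_index`) follows
#' increasing difficulty. Plateaued items have a continuous piecewise-linear
#' logit: full slope up to the age of 35% attainment, `plateau_factor` times
#' the slope between 35% and 65%, and full slope beyond.
#'
#' @param config An [item_bank_config()].
#' @param seed Integer seed; the bank is reproducible for a fixed seed.
#' @return A data frame with one row per item: `item_id`, `domain`,
#'   `order_index`, `curve_kind` (`"single"`/`"piecewise3"`), true parameters
#'   `age50_true`, `slope`, `plateau_slope`, `t1`, `t2`, and covariate
#'   coefficients `beta_sex`, `beta_ses`, `beta_haz`, `beta_waz`.
#' @export
generate_item_bank <- function(config = item_bank_config(), seed = 1L) {
  stopifnot(inherits(config, "item_bank_config"))
  set.seed(derive_seed(seed, 101L))
  m <- config$items_per_domain
  rows <- lapply(config$domains, function(dom) {
    grid <- seq(config$age50_span[1], config$age50_span[2], length.out = m)
    jitter_sd <- diff(config$age50_span) / (4 * m)
    age50 <- sort(grid + stats::rnorm(m, 0, jitter_sd))
    age50 <- pmax(age50, 0.02)
    slope <- stats::runif(m, config$slope_range[1], config$slope_range[2])
    n_pw <- round(config$piecewise_fraction[[dom]] * m)
    pw <- rep(FALSE, m)
    if (n_pw > 0) pw[sample.int(m, n_pw)] <- TRUE
    plateau_slope <- ifelse(pw, slope * config$plateau_factor, slope)
    # plateau spans pass probabilities 0.35-0.65 around the median age
    half <- stats::qlogis(0.65) / plateau_slope
    t1 <- ifelse(pw, age50 - half, NA_real_)
    t2 <- ifelse(pw, age50 + half, NA_real_)
    eff <- function(cov) {
      p <- config$covariate_prevalence[[cov]][[dom]]
      has <- stats::runif(m) < p
      size <- config$effect_sizes[[cov]]
      if (cov == "sex") {
        ifelse(has, size * sample(c(-1, 1), m, replace = TRUE), 0)
      } else {
        ifelse(has, size, 0)
      }
    }
    data.frame(item_id = sprintf("%s_%02d", dom, seq_len(m)),
               domain = dom,
               order_index = seq_len(m),
               curve_kind = ifelse(pw, "piecewise3", "single"),
               age50_true = age50,
               slope = slope,
               plateau_slope = plateau_slope,
               t1 = t1, t2 = t2,
               beta_sex = eff("sex"),
               beta_ses = eff("ses"),
               beta_haz = eff("haz"),
               beta_waz = eff("waz"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' True pass-probability logit of bank items at given ages
#'
#' Evaluates the generating (true) logit of one item-bank row at a vector of
#' performance ages, before any covariate adjustment.
#'
#' @param item One row of an item bank from [generate_item_bank()].
#' @param age Numeric vector of decimal ages (years).
#' @return Numeric vector of logits.
#' @export
true_item_logit <- function(item, age) {
  if (item$curve_kind == "single") {
    return(item$slope * (age - item$age50_true))
  }
  lo <- stats::qlogis(0.35)
  hi <- stats::qlogis(0.65)
  ifelse(age <= item$t1, lo + item$slope * (age - item$t1),
         ifelse(age <= item$t2, lo + item$plateau_slope * (age - item$t1),
                hi + item$slope * (age - item$t2)))
}

#' True pass probability of bank items at given ages
#'
#' @inheritParams true_item_logit
#' @return Numeric vector of pass probabilities.
#' @export
true_pass_probability <- function(item, age) {
  stats::plogis(true_item_logit(item, age))
}

#' True population attainment age of a bank item
#'
#' The age at which a given fraction of the population passes the item,
#' marginalised over the covariate distribution of a supplied child sample:
#' the root of mean(P(pass | age, covariates)) = p over age. For an item with
#' no covariate effects this equals the inverse of its true curve; for items
#' with covariate effects it is the population-level quantity that a normative
#' age curve estimates (marginalising flattens the individual-level curve).
#'
#' @param item One row of an item bank.
#' @param p Target pass fraction (scalar in (0, 1)).
#' @param children Child records supplying the covariate sample.
#' @param centers Covariate centring values (see [protocol_config()]).
#' @return The attainment age in decimal years.
#' @export
true_attainment_age <- function(item, p, children,
                                centers = c(haz = -1.55, waz = -0.96)) {
  stopifnot(length(p) == 1, p > 0, p < 1)
  kids <- children
  f <- function(t) {
    kids$performance_age <- rep(t, nrow(kids))
    mean(stats::plogis(child_item_logit(item, kids, centers))) - p
  }
  stats::uniroot(f, lower = -5, upper = 15, tol = 1e-8)$root
}

#' Configuration for a synthetic reference population
#'
#' Defaults emulate a quota-recruited community sample of about 1,500 children
#' aged 0-6 years from a rural low-income setting: stunting is common (HAZ
#' mean -1.55, SD 1.15, giving roughly 35% below -2), underweight less so
#' (WAZ mean -0.96), weight-for-height is near the reference (so only a few
#' percent are excluded for acute malnutrition), and about 2.5% carry another
#' exclusion condition (prematurity at or below 32 weeks, a significant
#' medical problem, or neurodisability).
#'
#' @param n Number of children to generate (before eligibility screening).
#' @param age_range Age range in decimal years; ages are drawn uniformly
#'   within equal-width quota groups.
#' @param n_age_groups Number of equal-width recruitment age groups.
#' @param haz_mean,haz_sd Height-for-age Z-score distribution.
#' @param waz_mean,waz_sd Weight-for-age Z-score distribution.
#' @param hw_cor Correlation between HAZ and WAZ.
#' @param whz_mean,whz_sd Weight-for-height Z-score distribution.
#' @param n_assets Number of binary household asset indicators.
#' @param premature_prob Probability of gestation at or below 32 weeks.
#' @param medical_prob Probability of a significant medical problem.
#' @param neuro_prob Probability of a pre-identified neurodisability.
#' @param sites Recruitment site labels.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 1513L,
                          age_range = c(0, 6),
                          n_age_groups = 34L,
                          haz_mean = -1.55, haz_sd = 1.15,
                          waz_mean = -0.96, waz_sd = 1.0,
                          hw_cor = 0.5,
                          whz_mean = 0, whz_sd = 1.05,
                          n_assets = 8L,
                          premature_prob = 0.01,
                          medical_prob = 0.01,
                          neuro_prob = 0.005,
                          sites = c("site_a", "site_b", "site_c", "site_d")) {
  if (n <= 0) stop("n must be positive")
  if (age_range[1] < 0 || age_range[1] >= age_range[2]) {
    stop("invalid age_range")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic child population
#'
#' Children carry a latent wealth score that drives both the binary asset
#' indicators and the true SES quintile; HAZ and WAZ are correlated bivariate
#' normal; WHZ, gestation, and the exclusion-condition flags are independent.
#' `performance_age` equals chronological age for the normal population and is
#' shifted for clinical groups (see [generate_clinical_groups()]).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param id_prefix Prefix for child identifiers.
#' @return Data frame of child records: `child_id`, `decimal_age`,
#'   `performance_age`, `sex`, asset indicator columns `asset_1..k`,
#'   `ses_quintile`, `haz`, `waz`, `whz`, `gestation_weeks`,
#'   `medical_problem`, `neurodisability`, `clinical_group`, `site`.
#' @export
generate_population <- function(config = cohort_config(), seed = 1L,
                                id_prefix = "C") {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n <= 0) stop("n must be positive")
  set.seed(derive_seed(seed, 202L))
  n <- config$n
  # quota-style recruitment: cycle through equal-width age groups
  width <- diff(config$age_range) / config$n_age_groups
  grp <- sample(rep_len(seq_len(config$n_age_groups), n))
  age <- config$age_range[1] + (grp - 1 + stats::runif(n)) * width
  sex <- sample(c("male", "female"), n, replace = TRUE)
  wealth <- stats::rnorm(n)
  alpha <- seq(-1.5, 1.5, length.out = config$n_assets)
  assets <- matrix(vapply(seq_len(config$n_assets), function(j) {
    as.integer(stats::runif(n) < stats::plogis(wealth - alpha[j]))
  }, integer(n)), nrow = n)
  colnames(assets) <- sprintf("asset_%d", seq_len(config$n_assets))
  ses <- as.integer(1 + (5 * (rank(wealth, ties.method = "first") - 1)) %/% n)
  z1 <- stats::rnorm(n)
  z2 <- config$hw_cor * z1 + sqrt(1 - config$hw_cor^2) * stats::rnorm(n)
  haz <- config$haz_mean + config$haz_sd * z1
  waz <- config$waz_mean + config$waz_sd * z2
  whz <- config$whz_mean + config$whz_sd * stats::rnorm(n)
  premature <- stats::runif(n) < config$premature_prob
  gestation <- ifelse(premature,
                      round(stats::runif(n, 28, 32)),
                      pmax(33, round(stats::rnorm(n, 39, 1.5))))
  out <- data.frame(child_id = sprintf("%s%05d", id_prefix, seq_len(n)),
                    decimal_age = age,
                    performance_age = age,
                    sex = sex,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(assets))
  out$ses_quintile <- ses
  out$haz <- haz
  out$waz <- waz
  out$whz <- whz
  out$gestation_weeks <- gestation
  out$medical_problem <- stats::runif(n) < config$medical_prob
  out$neurodisability <- stats::runif(n) < config$neuro_prob
  out$clinical_group <- "normal"
  out$site <- sample(config$sites, n, replace = TRUE)
  out
}

#' Assessment protocol settings
#'
#' @param stop_run_length Number of consecutive failures within a domain after
#'   which remaining items in that domain are not administered.
#' @param dont_know_prob Probability that an administered item is recorded as
#'   "don't know" (uncooperative or unwell child) instead of pass/fail.
#' @param covariate_centers Reference values at which the HAZ and WAZ covariate
#'   effects are centred, so that the true curve parameters describe a child
#'   with population-typical anthropometry.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(stop_run_length = 7L,
                            dont_know_prob = 0.01,
                            covariate_centers = c(haz = -1.55, waz = -0.96)) {
  if (stop_run_length < 1) stop("stop_run_length must be >= 1")
  if (dont_know_prob < 0 || dont_know_prob > 1) {
    stop("dont_know_prob must be in [0, 1]")
  }
  structure(list(stop_run_length = as.integer(stop_run_length),
                 dont_know_prob = dont_know_prob,
                 covariate_centers = covariate_centers),
            class = "protocol_config")
}

# Logit of the pass probability for every child at one item, including
# centred covariate effects.
child_item_logit <- function(item, children, centers) {
  age <- children$performance_age %||% children$decimal_age
  l <- true_item_logit(item, age)
  l <- l + item$beta_sex * ((children$sex == "male") - 0.5)
  l <- l + item$beta_ses * (children$ses_quintile - 3)
  l <- l + item$beta_haz * (children$haz - centers[["haz"]])
  l + item$beta_waz * (children$waz - centers[["waz"]])
}

#' Administer an item bank to children under a stopping rule
#'
#' Within each domain items are presented in `order_index` order. Each
#' presented item is passed with the probability given by the item's true
#' curve evaluated at the child's performance age, with covariate effects
#' added on the logit scale. Once `stop_run_length` consecutive failures have
#' occurred in a domain, all later items in that domain are recorded as
#' `not_administered`; the rule is applied per domain. A "don't know" outcome
#' replaces pass/fail with probability `dont_know_prob` and neither extends
#' nor resets the failure run.
#'
#' @param children Data frame of child records (see [generate_population()]).
#' @param item_bank Data frame from [generate_item_bank()].
#' @param protocol A [protocol_config()].
#' @param seed Integer seed.
#' @param session_id Session label stored on every response.
#' @return Long data frame with columns `child_id`, `item_id`, `session_id`,
#'   `outcome`, exhaustive over children x items.
#' @export
administer_assessment <- function(children, item_bank,
                                  protocol = protocol_config(), seed = 1L,
                                  session_id = "s1") {
  stopifnot(inherits(protocol, "protocol_config"))
  assert_columns(children, c("child_id", "decimal_age", "sex", "ses_quintile",
                             "haz", "waz"), "children")
  assert_columns(item_bank, c("item_id", "domain", "order_index", "curve_kind",
                              "age50_true", "slope", "beta_sex"), "item_bank")
  if (protocol$stop_run_length < 1) stop("stop_run_length must be >= 1")
  set.seed(derive_seed(seed, 303L))
  n <- nrow(children)
  centers <- protocol$covariate_centers
  domain_blocks <- lapply(unique(item_bank$domain), function(dom) {
    items <- item_bank[item_bank$domain == dom, , drop = FALSE]
    items <- items[order(items$order_index), , drop = FALSE]
    m <- nrow(items)
    outcome <- matrix("not_administered", nrow = n, ncol = m)
    consec <- integer(n)
    stopped <- logical(n)
    for (j in seq_len(m)) {
      p <- stats::plogis(child_item_logit(items[j, ], children, centers))
      pass <- stats::runif(n) < p
      dk <- stats::runif(n) < protocol$dont_know_prob
      adm <- !stopped
      outcome[adm, j] <- ifelse(dk[adm], "dont_know",
                                ifelse(pass[adm], "pass", "fail"))
      scored <- adm & !dk
      consec[scored] <- ifelse(pass[scored], 0L, consec[scored] + 1L)
      stopped <- stopped | consec >= protocol$stop_run_length
    }
    data.frame(child_id = rep(children$child_id, times = m),
               item_id = rep(items$item_id, each = n),
               session_id = session_id,
               outcome = as.vector(outcome),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, domain_blocks)
  out <- out[order(out$child_id, out$item_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observer-agreement configuration for reliability sessions
#'
#' Per-design probabilities that the second session's pass/fail outcome flips,
#' and per-design child counts. Defaults give the expected agreement ordering
#' inter-observer immediate >= inter-observer delayed >= intra-observer
#' delayed (two weeks apart), with session sizes of 56, 52, and 124 children.
#'
#' @param flip_prob Named numeric vector of flip probabilities.
#' @param n_children Named integer vector of children per design.
#' @return A list of class `agreement_config`.
#' @export
agreement_config <- function(flip_prob = c(inter_immediate = 0.01,
                                           inter_delayed = 0.04,
                                           intra_delayed = 0.10),
                             n_children = c(inter_immediate = 56L,
                                            inter_delayed = 52L,
                                            intra_delayed = 124L)) {
  if (any(flip_prob < 0 | flip_prob > 1)) stop("flip_prob must be in [0, 1]")
  structure(list(flip_prob = flip_prob, n_children = n_children),
            class = "agreement_config")
}

#' Generate paired observer sessions for reliability testing
#'
#' A subsample of children is assessed once; the second observer's (or
#' occasion's) record is the first session with each administered pass/fail
#' outcome independently flipped with the design-specific probability.
#' "Don't know" and not-administered outcomes are carried over unchanged, so
#' both sessions cover the same administered items.
#'
#' @param children Pool of child records to subsample from.
#' @param item_bank Item bank data frame.
#' @param design One of `"inter_immediate"`, `"inter_delayed"`,
#'   `"intra_delayed"`.
#' @param agreement An [agreement_config()].
#' @param protocol A [protocol_config()].
#' @param seed Integer seed.
#' @return List with elements `design`, `session_a`, `session_b` (long
#'   response data frames with session ids `"s1"` and `"s2"`).
#' @export
generate_reliability_sessions <- function(children, item_bank, design,
                                          agreement = agreement_config(),
                                          protocol = protocol_config(),
                                          seed = 1L) {
  design <- match.arg(design,
                      c("inter_immediate", "inter_delayed", "intra_delayed"))
  n <- min(agreement$n_children[[design]], nrow(children))
  set.seed(derive_seed(seed, 404L))
  idx <- sample.int(nrow(children), n)
  sub <- children[idx, , drop = FALSE]
  a <- administer_assessment(sub, item_bank, protocol,
                             seed = derive_seed(seed, 405L),
                             session_id = "s1")
  set.seed(derive_seed(seed, 406L))
  b <- a
  b$session_id <- "s2"
  scored <- b$outcome %in% c("pass", "fail")
  flip <- scored & stats::runif(nrow(b)) < agreement$flip_prob[[design]]
  b$outcome[flip] <- ifelse(b$outcome[flip] == "pass", "fail", "pass")
  list(design = design, session_a = a, session_b = b)
}

#' Configuration of the clinical comparison groups
#'
#' Children with neurodisability perform at a fixed fraction of their
#' chronological age; children with marasmus (severe acute malnutrition)
#' perform at their chronological age minus a fixed offset, floored at zero.
#' These ability shifts are generator conventions chosen to reproduce the
#' severity ordering neurodisability >> marasmus > none.
#'
#' @param n_neurodisability,n_marasmus Group sizes.
#' @param nd_age_factor Performance age = `nd_age_factor` x chronological age.
#' @param marasmus_age_offset Performance age = chronological age minus this
#'   offset (years), floored at 0.
#' @param marasmus_whz_mean,marasmus_whz_sd WHZ distribution of the marasmus
#'   group (well below the acute-malnutrition threshold).
#' @return A list of class `clinical_config`.
#' @export
clinical_config <- function(n_neurodisability = 80L,
                            n_marasmus = 120L,
                            nd_age_factor = 0.35,
                            marasmus_age_offset = 0.75,
                            marasmus_whz_mean = -3.2,
                            marasmus_whz_sd = 0.5) {
  if (nd_age_factor < 0 || marasmus_age_offset < 0) {
    stop("ability shift parameters must be non-negative")
  }
  structure(as.list(environment()), class = "clinical_config")
}

#' Generate clinical comparison groups with shifted ability
#'
#' @param item_bank Item bank data frame.
#' @param config A [clinical_config()].
#' @param protocol A [protocol_config()].
#' @param seed Integer seed.
#' @param cohort A [cohort_config()] providing the covariate distributions.
#' @return List with `children` (labelled `clinical_group`, with shifted
#'   `performance_age`) and `responses` (from [administer_assessment()]).
#' @export
generate_clinical_groups <- function(item_bank, config = clinical_config(),
                                     protocol = protocol_config(), seed = 1L,
                                     cohort = cohort_config()) {
  stopifnot(inherits(config, "clinical_config"))
  nd_cfg <- cohort
  nd_cfg$n <- config$n_neurodisability
  nd <- generate_population(nd_cfg, seed = derive_seed(seed, 501L),
                            id_prefix = "ND")
  nd$clinical_group <- "neurodisability"
  nd$neurodisability <- TRUE
  nd$performance_age <- config$nd_age_factor * nd$decimal_age

  ma_cfg <- cohort
  ma_cfg$n <- config$n_marasmus
  ma_cfg$whz_mean <- config$marasmus_whz_mean
  ma_cfg$whz_sd <- config$marasmus_whz_sd
  ma <- generate_population(ma_cfg, seed = derive_seed(seed, 502L),
                            id_prefix = "MA")
  ma$clinical_group <- "marasmus"
  ma$performance_age <- pmax(0, ma$decimal_age - config$marasmus_age_offset)

  children <- rbind(nd, ma)
  responses <- administer_assessment(children, item_bank, protocol,
                                     seed = derive_seed(seed, 503L))
  list(children = children, responses = responses)
}
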