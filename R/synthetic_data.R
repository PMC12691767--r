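# Seeded generators for every input the pipeline needs: a 65+ starting
# population, a care-need survey, mortality and entry schedules, and the
# aggregate benefit statistics the model is aligned to.  All generators are
# pure functions of their configuration (including the seed).

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Education composition by birth cohort
#'
#' Piecewise-linear shares of low/medium/high education as a function of
#' birth year, constant outside the anchor range.  The default anchors
#' encode educational expansion: older cohorts are predominantly
#' low/medium educated, recent and future cohorts increasingly highly
#' educated.
#'
#' @param birth_year numeric vector.
#' @param anchors data.frame with columns `birth_year`, `low`, `high`
#'   (medium is the remainder); rows ordered by birth year.
#' @return matrix (n x 3) with columns `low`, `medium`, `high`, rows
#'   summing to 1.
#' @export
education_shares <- function(birth_year, anchors = education_anchors()) {
  lo <- stats::approx(anchors$birth_year, anchors$low, birth_year,
                      rule = 2)$y
  hi <- stats::approx(anchors$birth_year, anchors$high, birth_year,
                      rule = 2)$y
  cbind(low = lo, medium = 1 - lo - hi, high = hi)
}

#' @rdname education_shares
#' @export
education_anchors <- function() {
  data.frame(birth_year = c(1919, 1959, 2015),
             low  = c(0.60, 0.25, 0.10),
             high = c(0.06, 0.20, 0.45))
}

#' Configuration of the synthetic starting population
#'
#' Describes the 65+ population stock at the simulation base year: size,
#' age range (ages above the cap are pooled at the cap for all parameter
#' lookups), the female share by single year of age (rising with age
#' through excess male mortality), education composition by birth cohort,
#' and the age distribution (default: survivorship weights implied by the
#' default mortality schedule).
#'
#' @param n_individuals population size (> 0).
#' @param base_year calendar year of the stock.
#' @param age_range integer c(min, max); min >= 65.
#' @param female_share numeric vector over ages `age_range[1]:age_range[2]`
#'   (recycled if scalar).
#' @param education_anchors cohort anchors, see [education_shares()].
#' @param age_weights unnormalised age-distribution weights over the age
#'   range; default survivorship under [mortality_schedule()].
#' @param seed integer RNG seed.
#' @return list of class `"population_config"`.
#' @export
population_config <- function(n_individuals = 10000, base_year = 2025,
                              age_range = c(65, 105),
                              female_share = NULL,
                              education_anchors = ltcasim::education_anchors(),
                              age_weights = NULL,
                              seed = 1) {
  if (n_individuals <= 0) stop("n_individuals must be positive")
  if (age_range[1] < 65) stop("minimum age must be at least 65")
  if (age_range[2] < age_range[1]) stop("invalid age_range")
  ages <- age_range[1]:age_range[2]
  if (is.null(female_share))
    female_share <- stats::plogis(0.08 + (ages - 65) * 0.015)
  female_share <- rep_len(female_share, length(ages))
  if (any(female_share < 0 | female_share > 1))
    stop("female_share must lie in [0, 1]")
  sh <- education_shares(base_year - ages, education_anchors)
  if (any(sh < 0) || any(abs(rowSums(sh) - 1) > 1e-8))
    stop("education shares must be a proper composition per cohort")
  if (is.null(age_weights)) {
    ms <- mortality_schedule(ages = 65:max(ages))
    q <- rowMeans(ms$q_annual)           # sex-averaged annual risk
    surv <- cumprod(c(1, 1 - q[-length(q)]))
    age_weights <- surv[ages - 64]
  }
  age_weights <- rep_len(age_weights, length(ages))
  if (any(age_weights < 0) || sum(age_weights) <= 0)
    stop("age_weights must be non-negative with positive sum")
  structure(list(n_individuals = as.integer(n_individuals),
                 base_year = base_year, age_range = age_range,
                 ages = ages, female_share = female_share,
                 education_anchors = education_anchors,
                 age_weights = age_weights / sum(age_weights),
                 seed = seed),
            class = "population_config")
}

#' Generate the synthetic starting population
#'
#' Draws `n_individuals` persons with age in months (uniform within the
#' drawn single year of age), sex, and education from the configured
#' marginals.  Identical configuration (including seed) yields identical
#' output.
#'
#' @param config a [population_config()].
#' @return data.frame with columns `id`, `age_months`, `age`, `sex`,
#'   `education`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  with_seed(config$seed, {
    n <- config$n_individuals
    age <- config$ages[sample.int(length(config$ages), n, replace = TRUE,
                                  prob = config$age_weights)]
    age_months <- age * 12L + sample.int(12L, n, replace = TRUE) - 1L
    female <- stats::runif(n) < config$female_share[age - config$ages[1] + 1L]
    sh <- education_shares(config$base_year - age, config$education_anchors)
    u <- stats::runif(n)
    edu <- 1L + (u > sh[, 1]) + (u > sh[, 1] + sh[, 2])
    data.frame(id = seq_len(n), age_months = age_months, age = age,
               sex = factor(SEX_LEVELS[2L - !female], levels = SEX_LEVELS),
               education = factor(EDU_LEVELS[edu], levels = EDU_LEVELS))
  })
}

#' Configuration of the synthetic care-need survey
#'
#' Parameters of the data-generating process for a survey of assessed
#' monthly care-need hours among the 65+ population: logit coefficients
#' for any relevant need (> 65 h/month) and for severe need (>= 120 h,
#' conditional on > 65 h), within-band hour-bucket splits, qualitative
#' flag probabilities above 180 h, and an age-graded dementia probability.
#' Assessed hours already include the dementia premium where applicable.
#'
#' @param n_respondents sample size.
#' @param age_range survey age range (integer years).
#' @param eligibility_coefficients named vector in the fully interactive
#'   design basis (see [logit_design()]).
#' @param severity_coefficients named vector in the severity design basis.
#' @param degree age-polynomial degree of both equations.
#' @param level_split list with `lower` (2 probabilities: hour buckets
#'   65--95, 95--120) and `upper` (3 probabilities: 120--160, 160--180,
#'   180+), each summing to 1.
#' @param flag_probs named probabilities of each qualitative flag given
#'   hours > 180.
#' @param dementia_coefficients c(intercept, slope) of a logit in scaled
#'   age for the dementia indicator.
#' @param female_share,education_shares respondent marginals.
#' @param seed integer RNG seed.
#' @return list of class `"survey_config"`.
#' @export
survey_config <- function(n_respondents = 20000, age_range = c(65, 99),
                          eligibility_coefficients =
                            default_eligibility_coefficients(degree),
                          severity_coefficients =
                            default_severity_coefficients(degree),
                          degree = 2,
                          level_split = list(lower = c(0.60, 0.40),
                                             upper = c(0.45, 0.25, 0.30)),
                          flag_probs = c(extraordinary_care = 0.55,
                                         uncoordinated_day_night = 0.35,
                                         no_purposeful_movements = 0.15),
                          dementia_coefficients = c(-4.6, 1.1),
                          female_share = 0.55,
                          education_shares = c(low = 0.35, medium = 0.45,
                                               high = 0.20),
                          seed = 1) {
  stopifnot(n_respondents > 0)
  if (abs(sum(level_split$lower) - 1) > 1e-8 ||
      abs(sum(level_split$upper) - 1) > 1e-8)
    stop("level_split components must each sum to 1")
  if (any(unlist(level_split) < 0)) stop("level_split entries must be >= 0")
  if (any(flag_probs < 0 | flag_probs > 1))
    stop("flag_probs must lie in [0, 1]")
  if (female_share < 0 || female_share > 1)
    stop("female_share must lie in [0, 1]")
  if (abs(sum(education_shares) - 1) > 1e-8 || any(education_shares < 0))
    stop("education_shares must be a proper composition")
  structure(list(n_respondents = as.integer(n_respondents),
                 age_range = age_range,
                 eligibility_coefficients = eligibility_coefficients,
                 severity_coefficients = severity_coefficients,
                 degree = degree, level_split = level_split,
                 flag_probs = flag_probs,
                 dementia_coefficients = dementia_coefficients,
                 female_share = female_share,
                 education_shares = education_shares, seed = seed),
            class = "survey_config")
}

#' Generate the synthetic care-need survey
#'
#' Draws respondent covariates from the configured marginals and assessed
#' care hours from the two-stage logit process: any relevant need
#' (> 65 h/month), severity (>= 120 h given > 65 h), an hour bucket within
#' the band, and uniform hours within the bucket.  Qualitative flags are
#' drawn only above 180 h; the resulting benefit level is attached via
#' [classify_level()].
#'
#' @param config a [survey_config()].
#' @param rules an [ltca_rules()] table used to attach the realised level.
#' @return data.frame with columns `age`, `sex`, `education`,
#'   `assessed_hours` (premium included), `base_hours`, `dementia`, one
#'   logical column per qualitative flag, and `level`.
#' @export
generate_survey <- function(config, rules = ltca_rules()) {
  stopifnot(inherits(config, "survey_config"))
  with_seed(config$seed, {
    n <- config$n_respondents
    age_vals <- config$age_range[1]:config$age_range[2]
    age <- age_vals[sample.int(length(age_vals), n, replace = TRUE)]
    female <- stats::runif(n) < config$female_share
    sex <- factor(SEX_LEVELS[1L + female], levels = SEX_LEVELS)
    cs <- cumsum(config$education_shares)
    u <- stats::runif(n)
    edu <- factor(EDU_LEVELS[1L + (u > cs[1]) + (u > cs[2])],
                  levels = EDU_LEVELS)
    p_any <- stats::plogis(truth_linpred(config$eligibility_coefficients,
                                         age, sex, edu, "eligibility",
                                         config$degree))
    eligible <- stats::runif(n) < p_any
    p_sev <- stats::plogis(truth_linpred(config$severity_coefficients,
                                         age, sex, edu, "severity",
                                         config$degree))
    severe <- eligible & (stats::runif(n) < p_sev)
    # hour buckets: (0,65] | (65,95] (95,120] | (120,160] (160,180] (180,240]
    hours <- stats::runif(n, 20, 65)
    lowband <- eligible & !severe
    if (any(lowband)) {
      b <- 1L + (stats::runif(sum(lowband)) > config$level_split$lower[1])
      hours[lowband] <- ifelse(b == 1L,
                               stats::runif(sum(lowband), 65, 95),
                               stats::runif(sum(lowband), 95, 120))
    }
    if (any(severe)) {
      csu <- cumsum(config$level_split$upper)
      uu <- stats::runif(sum(severe))
      b <- 1L + (uu > csu[1]) + (uu > csu[2])
      lowr <- c(120, 160, 180)[b]; upr <- c(160, 180, 240)[b]
      hours[severe] <- stats::runif(sum(severe), lowr, upr)
    }
    flags <- matrix(FALSE, n, 3,
                    dimnames = list(NULL, ltca_flags()))
    over180 <- hours > 180
    for (f in ltca_flags())
      flags[over180, f] <- stats::runif(sum(over180)) <
        config$flag_probs[[f]]
    p_dem <- stats::plogis(config$dementia_coefficients[1] +
                             config$dementia_coefficients[2] * age_scale(age))
    dementia <- stats::runif(n) < p_dem
    flag_list <- lapply(seq_len(n), function(i) ltca_flags()[flags[i, ]])
    out <- data.frame(age = age, sex = sex, education = edu,
                      assessed_hours = hours,
                      base_hours = pmax(hours - ifelse(dementia, 40, 0), 0),
                      dementia = dementia)
    out <- cbind(out, as.data.frame(flags))
    out$level <- classify_level(hours, flag_list, rules)
    out
  })
}

#' Baseline mortality schedule with improvement and education gradients
#'
#' Gompertz-type annual death risks by single year of age and sex for the
#' base year, a proportional annual hazard-improvement factor, and
#' persistent relative risks by education (reference: medium).  The top
#' age of the schedule is treated as an open interval: older ages reuse
#' its hazard.
#'
#' @param ages integer ages covered (default 65:105).
#' @param base_year calendar year of the baseline.
#' @param gompertz c(log-hazard intercept at age 0, slope per year) for
#'   men; defaults give roughly 1.3% annual risk at 65 and 22% at 95.
#' @param female_factor multiplicative female hazard advantage.
#' @param annual_improvement multiplicative hazard factor per calendar
#'   year (in (0, 1]; 0.985 means hazards fall 1.5% per year).
#' @param education_rr named relative risks c(low, medium, high); medium
#'   must equal 1.
#' @return list of class `"mortality_schedule"` with `q_annual`
#'   (ages x sex matrix), `m_monthly`, `annual_improvement`,
#'   `education_rr`, `ages`, `base_year`.
#' @export
mortality_schedule <- function(ages = 65:105, base_year = 2025,
                               gompertz = c(-10.48, 0.0945),
                               female_factor = 0.65,
                               annual_improvement = 0.985,
                               education_rr = c(low = 1.3, medium = 1,
                                                high = 0.8)) {
  if (annual_improvement <= 0 || annual_improvement > 1)
    stop("annual_improvement must lie in (0, 1]")
  if (any(education_rr <= 0)) stop("education_rr must be positive")
  if (education_rr[["medium"]] != 1)
    stop("education_rr is relative to medium; medium must be 1")
  h <- exp(gompertz[1] + gompertz[2] * ages)
  q <- cbind(male = pmin(1 - exp(-h), 0.9),
             female = pmin(1 - exp(-h * female_factor), 0.9))
  rownames(q) <- ages
  structure(list(ages = ages, base_year = base_year, q_annual = q,
                 m_monthly = 1 - (1 - q)^(1 / 12),
                 annual_improvement = annual_improvement,
                 education_rr = education_rr[c("low", "medium", "high")]),
            class = "mortality_schedule")
}

#' Entry cohorts of new 65-year-olds
#'
#' Sizes and education composition of the cohorts entering the simulated
#' population at exact age 65 each January.  With educational expansion
#' the high-education share is non-decreasing over entry years (cohort
#' anchors extend the trend observed in the stock).
#'
#' @param years calendar years of entry.
#' @param base_size cohort size in the first entry year.
#' @param growth multiplicative annual growth of cohort size.
#' @param education_anchors cohort anchors, see [education_shares()].
#' @param expansion if `FALSE`, freeze the composition at the first entry
#'   cohort's values.
#' @return data.frame of class `"entry_schedule"` with columns `year`,
#'   `size`, `low`, `medium`, `high`.
#' @export
entry_schedule <- function(years, base_size, growth = 1.002,
                           education_anchors = ltcasim::education_anchors(),
                           expansion = TRUE) {
  size <- round(base_size * growth^(seq_along(years) - 1))
  if (any(size < 0)) stop("cohort sizes must be non-negative")
  sh <- education_shares(years - 65, education_anchors)
  if (!expansion) sh <- matrix(sh[1, ], nrow(sh), 3, byrow = TRUE,
                               dimnames = dimnames(sh))
  out <- data.frame(year = years, size = as.integer(size), sh)
  class(out) <- c("entry_schedule", "data.frame")
  out
}

#' Aggregate targets implied by the generating process
#'
#' Produces the two official-style aggregate inputs of the pipeline from
#' the generating truth, with no sampling: (a) a benefit prevalence table
#' P(level | age, sex) for the base year, obtained in closed form from the
#' survey-generating logits weighted by the cohort education composition;
#' and (b) expected deaths by age, sex, and calendar year, together with
#' expected person-months of exposure by education, from a deterministic
#' projection of the expected starting population under the mortality
#' schedule (improvement and education relative risks applied).
#'
#' @param pop a [population_config()].
#' @param mort a [mortality_schedule()].
#' @param entry an [entry_schedule()].
#' @param survey_truth a [survey_config()] holding the generating
#'   coefficients.
#' @param horizon last projected calendar year.
#' @return list of class `"ltca_targets"`: `prevalence` (data.frame age,
#'   sex, level, prevalence), `composition` (education shares by age at
#'   base year), `deaths` (age x sex x year array), `exposure`
#'   (age x sex x education x year person-months), `female_share_65`.
#' @export
generate_targets <- function(pop, mort, entry, survey_truth,
                             horizon = max(entry$year)) {
  stopifnot(inherits(pop, "population_config"),
            inherits(mort, "mortality_schedule"),
            inherits(survey_truth, "survey_config"))
  if (min(mort$ages) > 65 || max(mort$ages) < max(pop$ages))
    stop("age-range mismatch: mortality schedule must cover ages 65..",
         max(pop$ages))
  ages <- mort$ages
  comp <- education_shares(pop$base_year - ages, pop$education_anchors)
  rows <- vector("list", 2)
  for (s in 1:2) {
    P <- matrix(0, length(ages), 8)
    for (e in 1:3)
      P <- P + comp[, e] * level_probs_truth(survey_truth, ages, s, e)
    rows[[s]] <- data.frame(age = rep(ages, 7), sex = SEX_LEVELS[s],
                            level = rep(1:7, each = length(ages)),
                            prevalence = as.vector(P[, 2:8]))
  }
  prev <- do.call(rbind, rows)
  prev$sex <- factor(prev$sex, levels = SEX_LEVELS)
  proj <- expected_projection(pop, mort, entry, prevalence = NULL,
                              horizon = horizon)
  structure(list(prevalence = prev,
                 composition = data.frame(age = ages, comp),
                 deaths = proj$deaths, exposure = proj$exposure,
                 female_share_65 = pop$female_share[1],
                 base_year = pop$base_year, horizon = horizon),
            class = "ltca_targets")
}
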