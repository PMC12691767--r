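# Monthly Monte-Carlo engine: January cohort entry at age 65, monthly
# cross-sectional care imputation (no longitudinal persistence), deaths
# from aligned hazards, and scenario transformations.  Mortality, care
# and entry draws come from three named RNG substreams derived from one
# seed, so scenarios compared under the same seed share common random
# numbers.

#' Scenario configuration
#'
#' The four named presets: `S0` baseline (projected mortality, education
#' differentials on), `S1` no education differentials in benefit
#' prevalence, `S2` slower ageing (care age grows by a factor 0.8 per
#' calendar year), `S3` constant mortality at the first simulated year's
#' schedule.
#'
#' @param label `"S0"`, `"S1"`, `"S2"`, `"S3"` or `"custom"`.
#' @param education_differentials use education-specific prevalence.
#' @param care_age_factor years of care age per calendar year, in (0, 1].
#' @param mortality_mode `"projected"` or `"constant_base_year"`.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(label = c("S0", "S1", "S2", "S3", "custom"),
                            education_differentials = NULL,
                            care_age_factor = NULL,
                            mortality_mode = NULL) {
  label <- match.arg(label)
  preset <- switch(label,
    S0 = list(TRUE, 1.0, "projected"),
    S1 = list(FALSE, 1.0, "projected"),
    S2 = list(TRUE, 0.8, "projected"),
    S3 = list(TRUE, 1.0, "constant_base_year"),
    custom = list(TRUE, 1.0, "projected"))
  cfg <- list(label = label,
              education_differentials =
                if (is.null(education_differentials)) preset[[1]]
                else education_differentials,
              care_age_factor = if (is.null(care_age_factor)) preset[[2]]
                else care_age_factor,
              mortality_mode = if (is.null(mortality_mode)) preset[[3]]
                else mortality_mode)
  if (cfg$care_age_factor <= 0 || cfg$care_age_factor > 1)
    stop("care_age_factor must lie in (0, 1]")
  cfg$mortality_mode <- match.arg(cfg$mortality_mode,
                                  c("projected", "constant_base_year"))
  structure(cfg, class = "scenario_config")
}

#' Care age under the slower-ageing transformation
#'
#' Linear transformation of chronological age anchored at 65: with factor
#' f, care age is `65 + f * (age - 65)`, so with f = 0.8 people age by
#' four years every five calendar years (age 70 maps to care age 69, 90
#' to 85).  Identity at the anchor and for f = 1.
#'
#' @param age chronological age in years (>= 65, may be fractional).
#' @param factor care-age accrual per calendar year, in (0, 1].
#' @return care age in years (same length as `age`).
#' @examples
#' care_age(70, 0.8)  # 69
#' care_age(90, 0.8)  # 85
#' @export
care_age <- function(age, factor = 0.8) {
  if (any(age < 65)) stop("care age is defined for ages 65 and older")
  if (factor <= 0 || factor > 1) stop("factor must lie in (0, 1]")
  65 + factor * (age - 65)
}

new_rng_streams <- function(seed) {
  e <- new.env(parent = emptyenv())
  with_seed(seed, {
    sub <- sample.int(.Machine$integer.max - 1L, 3L)
    for (i in seq_along(c("mortality", "care", "entry"))) {
      set.seed(sub[i])
      assign(c("mortality", "care", "entry")[i],
             get(".Random.seed", globalenv()), envir = e)
    }
  })
  e
}

stream_runif <- function(streams, name, n) {
  if (n == 0L) return(numeric(0))
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  u <- stats::runif(n)
  assign(name, get(".Random.seed", globalenv()), envir = streams)
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  u
}

# Build the cumulative level-probability lookup used each month:
# rows indexed by (care age, sex[, education]), columns cumulative
# P(level <= k), k = 0..7.
prevalence_cum_lookup <- function(prevalence, ages, pooled) {
  n_ages <- length(ages)
  if (pooled) {
    grid <- expand.grid(age = ages, sex = 1:2)
    P <- predict(prevalence, data.frame(age = grid$age, sex = grid$sex),
                 pooled = TRUE)
  } else {
    grid <- expand.grid(age = ages, sex = 1:2, education = 1:3)
    P <- predict(prevalence, grid)
  }
  t(apply(P, 1, cumsum))
}

#' Initialise a simulation state
#'
#' Bundles the starting population, model inputs and scenario into a
#' mutable state advanced by [step_month()].  Mostly used through
#' [run_scenario()].
#'
#' @param population starting population (from [generate_population()]).
#' @param prevalence an [ltca_prevalence()] model.
#' @param hazards aligned hazards from [align_mortality()].
#' @param entry an [entry_schedule()].
#' @param scenario a [scenario_config()].
#' @param base_year first simulated calendar year (the stock's year).
#' @param horizon last simulated calendar year.
#' @param seed integer seed expanded into the three RNG substreams.
#' @param rules benefit rule table.
#' @param female_share_65 female share among entrants.
#' @param keep_panel store the full monthly (individual, level) panel.
#' @return an environment of class `"ltca_sim_state"`.
#' @export
new_sim_state <- function(population, prevalence, hazards, entry,
                          scenario = scenario_config("S0"),
                          base_year = 2025, horizon = 2080, seed = 1,
                          rules = ltca_rules(), female_share_65 = 0.52,
                          keep_panel = FALSE) {
  stopifnot(inherits(prevalence, "ltca_prevalence"),
            inherits(hazards, "ltca_hazards"),
            inherits(scenario, "scenario_config"))
  years <- base_year:horizon
  if (!all(years %in% hazards$years))
    stop("aligned hazards do not cover years ",
         paste(range(setdiff(years, hazards$years)), collapse = "-"))
  ages <- hazards$ages; cap <- max(ages)
  ey <- entry$year %in% years
  capacity <- nrow(population) + sum(entry$size[ey])
  st <- new.env(parent = emptyenv())
  st$n0 <- nrow(population); st$n_total <- nrow(population)
  st$age_m <- c(as.integer(population$age_months),
                integer(capacity - st$n0))
  st$sex <- c(as_sex_int(population$sex), integer(capacity - st$n0))
  st$edu <- c(as_edu_int(population$education), integer(capacity - st$n0))
  st$alive <- c(rep(TRUE, st$n0), rep(FALSE, capacity - st$n0))
  st$age_start <- st$age_m
  st$cum_cents <- numeric(capacity)
  st$entry_month <- integer(capacity)          # 0 = base-year stock
  st$death_month <- rep(NA_integer_, capacity)
  st$mi <- 0L; st$years <- years; st$cap <- cap; st$ages <- ages
  st$scenario <- scenario; st$entry <- entry
  st$hazards <- hazards
  st$cents <- payout_cents(rules)
  st$rules <- rules
  st$CUM <- prevalence_cum_lookup(prevalence, ages,
                                  !scenario$education_differentials)
  st$streams <- new_rng_streams(seed)
  st$seed <- seed
  st$female_share_65 <- female_share_65
  n_months <- 12L * length(years)
  st$monthly_levels <- matrix(0L, n_months, 8,
                              dimnames = list(NULL, paste0("level", 0:7)))
  st$dec <- array(0L, dim = c(length(ages), 2, 3, 8, length(years)),
                  dimnames = list(age = ages, sex = SEX_LEVELS,
                                  education = EDU_LEVELS,
                                  level = paste0("level", 0:7),
                                  year = years))
  st$ev_entries <- integer(n_months); st$ev_deaths <- integer(n_months)
  st$keep_panel <- keep_panel
  st$panel <- if (keep_panel) vector("list", n_months)
  class(st) <- "ltca_sim_state"
  st
}

#' Advance the simulation by one month
#'
#' Event order within a month: January cohort entry at exact age 65, care
#' imputation for everyone alive at month start (a fresh cross-sectional
#' level draw from the prevalence model at the care age, with the month's
#' payout credited -- decedents of the month are included), mortality
#' draws, then ageing by one month.
#'
#' @param st a state from [new_sim_state()] (modified in place).
#' @return the state, invisibly.
#' @export
step_month <- function(st) {
  st$mi <- st$mi + 1L
  yi <- (st$mi - 1L) %/% 12L + 1L
  m <- (st$mi - 1L) %% 12L + 1L
  year <- st$years[yi]
  n_ages <- length(st$ages)
  if (m == 1L) {
    ei <- match(year, st$entry$year)
    k <- if (is.na(ei)) 0L else st$entry$size[ei]
    if (k > 0L) {
      idx <- st$n_total + seq_len(k)
      u <- stream_runif(st$streams, "entry", 2L * k)
      st$sex[idx] <- 1L + (u[seq_len(k)] < st$female_share_65)
      sh <- cumsum(unlist(st$entry[ei, c("low", "medium", "high")]))
      ue <- u[k + seq_len(k)]
      st$edu[idx] <- 1L + (ue > sh[1]) + (ue > sh[2])
      st$age_m[idx] <- 65L * 12L
      st$age_start[idx] <- 65L * 12L
      st$alive[idx] <- TRUE
      st$entry_month[idx] <- st$mi
      st$n_total <- st$n_total + k
      st$ev_entries[st$mi] <- k
    }
  }
  aidx <- which(st$alive[seq_len(st$n_total)])
  nal <- length(aidx)
  if (nal) {
    age_m <- st$age_m[aidx]; sx <- st$sex[aidx]; ed <- st$edu[aidx]
    ca <- pmax(65L, pmin(st$cap,
      as.integer(floor(65 + st$scenario$care_age_factor *
                         (age_m / 12 - 65)))))
    cell <- (ca - 65L + 1L) + n_ages * (sx - 1L)
    if (st$scenario$education_differentials)
      cell <- cell + 2L * n_ages * (ed - 1L)
    u <- stream_runif(st$streams, "care", nal)
    lv <- integer(nal)
    for (k in 1:7) lv <- lv + (u > st$CUM[cell, k])
    st$cum_cents[aidx] <- st$cum_cents[aidx] + st$cents[lv + 1L]
    st$monthly_levels[st$mi, ] <- tabulate(lv + 1L, 8L)
    if (m == 12L) {
      ay <- pmin(age_m %/% 12L, st$cap)
      code <- (ay - 64L) + n_ages * ((sx - 1L) + 2L * (ed - 1L) + 6L * lv)
      st$dec[, , , , yi] <- st$dec[, , , , yi] +
        array(tabulate(code, n_ages * 48L), dim = c(n_ages, 2, 3, 8))
    }
    if (st$keep_panel)
      st$panel[[st$mi]] <- data.frame(month = st$mi, year = year,
                                      id = aidx, level = lv)
    ay <- pmin(age_m %/% 12L, st$cap)
    constant <- st$scenario$mortality_mode == "constant_base_year"
    hy <- if (constant) 1L else match(year, st$hazards$years)
    hidx <- (ay - 64L) + n_ages * (sx - 1L) + 2L * n_ages * (ed - 1L) +
      6L * n_ages * (hy - 1L)
    hz <- st$hazards$h[hidx]
    u2 <- stream_runif(st$streams, "mortality", nal)
    die <- u2 < hz
    if (any(die)) {
      st$death_month[aidx[die]] <- st$mi
      st$alive[aidx[die]] <- FALSE
      st$ev_deaths[st$mi] <- sum(die)
    }
    st$age_m[aidx[!die]] <- age_m[!die] + 1L
  }
  invisible(st)
}

#' Run one scenario of the microsimulation
#'
#' Simulates the 65+ population monthly from the base year through the
#' horizon year under the given scenario and returns the aggregated
#' outputs consumed by the accounting module.  Deterministic given the
#' seed; scenarios run with the same seed share common random numbers
#' across the mortality, care and entry substreams.
#'
#' @inheritParams new_sim_state
#' @return object of class `"ltca_sim"`: monthly recipient counts by
#'   level, December cross-sections by age, sex, education and level, a
#'   per-person summary (`persons`), a monthly event log (`events`), and
#'   the full panel when `keep_panel = TRUE`.
#' @examples
#' \donttest{
#' cfg <- ltca_config(n_individuals = 500, survey_n = 2000,
#'                    horizon = 2030)
#' inputs <- prepare_inputs(cfg)
#' sim <- run_scenario(inputs$population, inputs$model, inputs$hazards,
#'                     inputs$entry, scenario_config("S0"),
#'                     base_year = 2025, horizon = 2030, seed = 1)
#' sim
#' }
#' @export
run_scenario <- function(population, prevalence, hazards, entry,
                         scenario = scenario_config("S0"),
                         base_year = 2025, horizon = 2080, seed = 1,
                         rules = ltca_rules(), female_share_65 = 0.52,
                         keep_panel = FALSE) {
  st <- new_sim_state(population, prevalence, hazards, entry, scenario,
                      base_year, horizon, seed, rules, female_share_65,
                      keep_panel)
  n_months <- 12L * length(st$years)
  for (i in seq_len(n_months)) step_month(st)
  n <- st$n_total
  persons <- data.frame(
    id = seq_len(n),
    sex = factor(SEX_LEVELS[st$sex[seq_len(n)]], levels = SEX_LEVELS),
    education = factor(EDU_LEVELS[st$edu[seq_len(n)]],
                       levels = EDU_LEVELS),
    age_start_months = st$age_start[seq_len(n)],
    entry_month = st$entry_month[seq_len(n)],
    death_month = st$death_month[seq_len(n)],
    alive_end = st$alive[seq_len(n)],
    cum_payout_cents = st$cum_cents[seq_len(n)])
  events <- data.frame(month = seq_len(n_months),
                       year = rep(st$years, each = 12L),
                       entries = st$ev_entries, deaths = st$ev_deaths)
  structure(list(monthly_levels = st$monthly_levels, dec = st$dec,
                 persons = persons, events = events,
                 years = st$years, base_year = base_year,
                 scenario = scenario, seed = seed, rules = st$rules,
                 n_initial = st$n0,
                 panel = if (keep_panel) do.call(rbind, st$panel)),
            class = "ltca_sim")
}

#' @export
print.ltca_sim <- function(x, ...) {
  ny <- length(x$years)
  rec_last <- sum(x$monthly_levels[12L * ny, 2:8])
  cat("Care-allowance microsimulation run (", x$scenario$label, ")\n",
      sep = "")
  cat("  years ", min(x$years), "-", max(x$years), ", seed ", x$seed,
      "\n", sep = "")
  cat("  initial population ", x$n_initial, ", entries ",
      sum(x$events$entries), ", deaths ", sum(x$events$deaths), "\n",
      sep = "")
  cat("  recipients in final December:", rec_last, "\n")
  invisible(x)
}
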