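# Deterministic expectation engine: propagates expected person counts by
# month of age, sex, and education under the same monthly order of events
# as the Monte-Carlo engine (January entries, care imputation on the
# population alive at month start, deaths, ageing).  Serves three roles:
# generating aggregate mortality targets, supplying the exposure
# composition for mortality alignment, and acting as the sampling-free
# oracle against which Monte-Carlo runs are checked.

MAX_BIN_AGE <- 120  # months of age above this are pooled (absorbing bin)

hazard_lookup_ages <- function(bins, cap) pmin(bins %/% 12L, cap)

baseline_hazard_array <- function(mort, years) {
  ages <- mort$ages
  h <- array(0, dim = c(length(ages), 2, 3, length(years)),
             dimnames = list(age = ages, sex = SEX_LEVELS,
                             education = EDU_LEVELS, year = years))
  for (yi in seq_along(years)) {
    imp <- mort$annual_improvement^(years[yi] - mort$base_year)
    for (e in 1:3)
      h[, , e, yi] <- mort$m_monthly * mort$education_rr[e] * imp
  }
  pmin(h, 0.999)
}

#' Scale baseline hazards to aggregate death targets
#'
#' Core of mortality alignment: within each cell the baseline hazard is
#' scaled by a common factor so that expected deaths over the given
#' exposures equal the target, while the relative risks between education
#' groups are preserved exactly.
#'
#' @param m_base baseline (reference-group) hazard, scalar per cell.
#' @param rr relative risks per education group.
#' @param exposure person-time at risk per education group.
#' @param deaths target death count for the cell.
#' @return list with `scale`, `adjusted` (per-group hazards) and
#'   `baseline` (adjusted reference-group hazard).
#' @export
align_hazards <- function(m_base, rr, exposure, deaths) {
  stopifnot(length(rr) == length(exposure))
  denom <- sum(exposure * m_base * rr)
  if (deaths > sum(exposure) + 1e-9)
    stop("target deaths (", deaths, ") exceed the cell population at risk")
  s <- if (denom > 0) deaths / denom else 0
  list(scale = s, adjusted = pmin(s * m_base * rr, 0.999),
       baseline = min(s * m_base, 0.999))
}

#' Align a mortality schedule to aggregate death targets
#'
#' Adjusts the baseline monthly hazards so that expected deaths by age,
#' sex and calendar year equal the aggregate targets, given the projected
#' education composition of exposure, with education relative risks
#' persisting unchanged.
#'
#' @param mort a [mortality_schedule()].
#' @param exposure person-months at risk, array age x sex x education x
#'   year (as produced by [generate_targets()]).
#' @param deaths target deaths, array age x sex x year.
#' @return object of class `"ltca_hazards"`: monthly hazards
#'   age x sex x education x year plus the year index.
#' @export
align_mortality <- function(mort, exposure, deaths) {
  stopifnot(inherits(mort, "mortality_schedule"))
  dn <- dimnames(deaths)
  years <- as.integer(dn[[3]])
  ages <- as.integer(dn[[1]])
  if (!identical(ages, mort$ages))
    stop("targets and mortality schedule are on different age grids")
  h <- array(0, dim = c(length(ages), 2, 3, length(years)),
             dimnames = list(age = ages, sex = SEX_LEVELS,
                             education = EDU_LEVELS, year = years))
  rr <- mort$education_rr
  for (yi in seq_along(years)) for (s in 1:2) for (ai in seq_along(ages)) {
    al <- align_hazards(mort$m_monthly[ai, s], rr,
                        exposure[ai, s, , yi], deaths[ai, s, yi])
    h[ai, s, , yi] <- al$adjusted
  }
  structure(list(h = h, years = years, ages = ages,
                 education_rr = rr, base_year = mort$base_year),
            class = "ltca_hazards")
}

hazard_slice <- function(hazards, yi, constant = FALSE) {
  if (constant) yi <- 1L
  hazards$h[, , , yi]
}

#' Deterministic expected projection of the 65+ population
#'
#' Propagates expected person counts by month of age, sex and education
#' from the base-year stock through the monthly event order of the
#' simulation engine, with no sampling.  With a prevalence model supplied
#' it also accumulates expected allowance recipients by level, so its
#' outputs are the exact expectations of the Monte-Carlo engine's.
#'
#' @param pop a [population_config()] (expected stock composition).
#' @param mort a [mortality_schedule()]; used for the hazard surface when
#'   `hazards` is `NULL`.
#' @param entry an [entry_schedule()].
#' @param prevalence optional [ltca_prevalence()] model.
#' @param scenario a [scenario_config()].
#' @param horizon last simulated calendar year.
#' @param hazards optional aligned [align_mortality()] hazards.
#' @param rules benefit rule table (payouts for expected expenditure).
#' @param population optional realised starting population (a
#'   [generate_population()] data.frame); when given, the projection is
#'   the exact conditional expectation of a Monte-Carlo run started from
#'   that stock rather than from the configuration-level expectation.
#' @return list with `deaths` and `exposure` arrays, expected
#'   `monthly_levels` counts (months x levels 0..7), expected December
#'   cross-sections `dec_counts` (age x sex x level x year, when a
#'   prevalence model is given), `months`, and `final_alive`.
#' @export
expected_projection <- function(pop, mort, entry, prevalence = NULL,
                                scenario = scenario_config("S0"),
                                horizon, hazards = NULL,
                                rules = ltca_rules(), population = NULL) {
  ages <- mort$ages; cap <- max(ages); n_ages <- length(ages)
  years <- pop$base_year:horizon
  n_years <- length(years); n_months <- 12L * n_years
  bins <- (65L * 12L):(MAX_BIN_AGE * 12L)
  n_bins <- length(bins)
  bin_age <- hazard_lookup_ages(bins, cap)
  bin_age_i <- bin_age - 64L
  N <- matrix(0, n_bins, 6)  # col = sex + 2*(edu-1)
  if (is.null(population)) {
    # expected stock: uniform month-within-year, marginals from config
    sh0 <- education_shares(pop$base_year - pop$ages,
                            pop$education_anchors)
    for (ai in seq_along(pop$ages)) {
      a <- pop$ages[ai]
      mass <- pop$n_individuals * pop$age_weights[ai] / 12
      rows <- (a * 12L):(a * 12L + 11L) - bins[1] + 1L
      fs <- pop$female_share[ai]
      for (e in 1:3) {
        N[rows, 1L + 2L * (e - 1L)] <- N[rows, 1L + 2L * (e - 1L)] +
          mass * (1 - fs) * sh0[ai, e]
        N[rows, 2L + 2L * (e - 1L)] <- N[rows, 2L + 2L * (e - 1L)] +
          mass * fs * sh0[ai, e]
      }
    }
  } else {
    # realised stock: place each person's mass at their exact month bin
    rows <- pmin(as.integer(population$age_months), max(bins)) -
      bins[1] + 1L
    cols <- as_sex_int(population$sex) +
      2L * (as_edu_int(population$education) - 1L)
    for (i in seq_along(rows))
      N[rows[i], cols[i]] <- N[rows[i], cols[i]] + 1
  }
  # static care-age lookup probabilities per column
  P_by_col <- NULL
  if (!is.null(prevalence)) {
    care_a <- pmin(cap, floor(65 + scenario$care_age_factor *
                                (bins / 12 - 65)))
    care_a <- pmax(care_a, 65L)
    P_by_col <- vector("list", 6)
    for (e in 1:3) for (s in 1:2) {
      nd <- data.frame(age = care_a, sex = s, education = e)
      P_by_col[[s + 2L * (e - 1L)]] <-
        predict(prevalence, nd, pooled = !scenario$education_differentials)
    }
  }
  if (is.null(hazards)) {
    hz_arr <- baseline_hazard_array(mort, years)
    hazards <- structure(list(h = hz_arr, years = years, ages = ages),
                         class = "ltca_hazards")
  }
  constant <- scenario$mortality_mode == "constant_base_year"
  deaths <- array(0, dim = c(n_ages, 2, n_years),
                  dimnames = list(age = ages, sex = SEX_LEVELS,
                                  year = years))
  exposure <- array(0, dim = c(n_ages, 2, 3, n_years),
                    dimnames = list(age = ages, sex = SEX_LEVELS,
                                    education = EDU_LEVELS, year = years))
  monthly_levels <- matrix(0, n_months, 8,
                           dimnames = list(NULL, paste0("level", 0:7)))
  dec_counts <- if (!is.null(prevalence))
    array(0, dim = c(n_ages, 2, 8, n_years),
          dimnames = list(age = ages, sex = SEX_LEVELS,
                          level = paste0("level", 0:7), year = years))
  entry_sex <- c(1 - pop$female_share[1], pop$female_share[1])
  mi <- 0L
  for (yi in seq_len(n_years)) {
    hz_y <- hazard_slice(hazards, match(years[yi], hazards$years),
                         constant)
    for (m in 1:12) {
      mi <- mi + 1L
      if (m == 1L) {
        ei <- match(years[yi], entry$year)
        if (!is.na(ei) && entry$size[ei] > 0) {
          sh <- unlist(entry[ei, c("low", "medium", "high")])
          for (e in 1:3) for (s in 1:2)
            N[1L, s + 2L * (e - 1L)] <- N[1L, s + 2L * (e - 1L)] +
              entry$size[ei] * entry_sex[s] * sh[e]
        }
      }
      if (!is.null(prevalence))
        for (col in 1:6)
          monthly_levels[mi, ] <- monthly_levels[mi, ] +
            drop(crossprod(N[, col], P_by_col[[col]]))
      if (!is.null(dec_counts) && m == 12L)
        for (e in 1:3) for (s in 1:2) {
          col <- s + 2L * (e - 1L)
          for (l in 1:8)
            dec_counts[, s, l, yi] <- dec_counts[, s, l, yi] +
              rowsum(N[, col] * P_by_col[[col]][, l], bin_age_i,
                     reorder = TRUE)[, 1]
        }
      for (e in 1:3) for (s in 1:2) {
        col <- s + 2L * (e - 1L)
        exposure[, s, e, yi] <- exposure[, s, e, yi] +
          rowsum(N[, col], bin_age_i)[, 1]
        D <- N[, col] * hz_y[bin_age_i, s, e]
        deaths[, s, yi] <- deaths[, s, yi] + rowsum(D, bin_age_i)[, 1]
        N[, col] <- N[, col] - D
      }
      N <- rbind(0, N[-n_bins, , drop = FALSE]) +
        rbind(matrix(0, n_bins - 1L, 6), N[n_bins, ])
    }
  }
  list(deaths = deaths, exposure = exposure,
       monthly_levels = monthly_levels, dec_counts = dec_counts,
       months = data.frame(year = rep(years, each = 12L), month = 1:12),
       final_alive = sum(N))
}

#' Expected annual expenditure from a deterministic projection
#'
#' @param proj result of [expected_projection()] run with a prevalence
#'   model.
#' @param rules benefit rule table.
#' @return data.frame `year`, `level`, `expenditure` (EUR/year) plus
#'   attribute-free totals obtainable by aggregation.
#' @export
expected_expenditure <- function(proj, rules = ltca_rules()) {
  cents <- payout_cents(rules)
  yrs <- proj$months$year
  out <- do.call(rbind, lapply(1:7, function(l) {
    v <- tapply(proj$monthly_levels[, l + 1] * cents[l + 1], yrs, sum)
    data.frame(year = as.integer(names(v)), level = l,
               expenditure = as.vector(v) / 100)
  }))
  out[order(out$year, out$level), ]
}
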