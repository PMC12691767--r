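# Reporting: annual expenditure by level, lifetime benefit costs by
# sex and education, and age-specific prevalence cross-sections.
# All monetary aggregation is done in integer cents so that yearly totals
# reconcile exactly with individual cumulative payouts.

monthly_counts_from_panel <- function(panel) {
  need <- c("year", "month", "level")
  if (!all(need %in% names(panel)))
    stop("a panel needs columns ", paste(need, collapse = ", "))
  key <- interaction(panel$year, panel$month, drop = FALSE)
  months <- unique(panel[c("year", "month")])
  months <- months[order(months$year, months$month), ]
  cnt <- matrix(0L, nrow(months), 8,
                dimnames = list(NULL, paste0("level", 0:7)))
  tb <- table(factor(paste(panel$year, panel$month),
                     levels = paste(months$year, months$month)),
              factor(panel$level, levels = 0:7))
  cnt[, ] <- as.integer(tb)
  list(months = months, counts = cnt)
}

#' Annual benefit expenditure by allowance level
#'
#' Aggregates monthly recipient counts by level into yearly expenditure
#' at the configured rate schedule (constant prices): cell(year, level) =
#' sum over months of recipients times the monthly rate.
#'
#' @param sim an [run_scenario()] result, or a long panel data.frame with
#'   columns `year`, `month`, `level` (one row per person-month).
#' @param rules benefit rule table.
#' @param allow_partial allow years not covered by all 12 months.
#' @return data.frame of class `"ltca_expenditure"`: `year`, `level1` ..
#'   `level7`, `total` (EUR/year).
#' @export
annual_expenditure <- function(sim, rules = NULL, allow_partial = FALSE) {
  if (inherits(sim, "ltca_sim")) {
    if (is.null(rules)) rules <- sim$rules
    counts <- sim$monthly_levels
    years <- rep(sim$years, each = 12L)
  } else {
    if (is.null(rules)) rules <- ltca_rules()
    mc <- monthly_counts_from_panel(sim)
    counts <- mc$counts
    years <- mc$months$year
  }
  per_year <- table(years)
  if (!allow_partial && any(per_year != 12L))
    stop("panel covers partial year(s): ",
         paste(names(per_year)[per_year != 12L], collapse = ", "),
         " (set allow_partial = TRUE to override)")
  cents <- payout_cents(rules)
  yrs <- sort(unique(years))
  out <- data.frame(year = yrs)
  for (l in 1:7)
    out[[paste0("level", l)]] <-
      as.vector(tapply(counts[, l + 1] * cents[l + 1], years, sum)) / 100
  out$total <- rowSums(out[paste0("level", 1:7)])
  class(out) <- c("ltca_expenditure", "data.frame")
  out
}

#' Mean lifetime benefit costs by sex and education
#'
#' For the cohort aged within `cohort` (completed years) at simulation
#' start, the mean cumulative benefit received over the remaining
#' lifetime, by sex and education.  Members still alive at the horizon
#' are censored; their share is reported per stratum and their accrued
#' costs are included as-is (censoring truncates, it is not imputed).
#' Strata without members are reported as missing.
#'
#' @param sim a [run_scenario()] result.
#' @param cohort numeric c(min, max) age in years at start.
#' @return data.frame of class `"ltca_lifetime"`: `sex`, `education`,
#'   `n`, `mean_cost` (EUR), `censored_share`.
#' @export
lifetime_costs <- function(sim, cohort = c(65, 75)) {
  stopifnot(inherits(sim, "ltca_sim"))
  p <- sim$persons
  in_cohort <- p$entry_month == 0L &
    p$age_start_months >= cohort[1] * 12 &
    p$age_start_months < (cohort[2] + 1) * 12
  p <- p[in_cohort, ]
  grid <- expand.grid(education = factor(EDU_LEVELS, levels = EDU_LEVELS),
                      sex = factor(SEX_LEVELS, levels = SEX_LEVELS))[, 2:1]
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sub <- p[p$sex == grid$sex[i] & p$education == grid$education[i], ]
    if (nrow(sub) == 0L)
      return(data.frame(sex = grid$sex[i], education = grid$education[i],
                        n = 0L, mean_cost = NA_real_,
                        censored_share = NA_real_))
    data.frame(sex = grid$sex[i], education = grid$education[i],
               n = nrow(sub),
               mean_cost = mean(sub$cum_payout_cents) / 100,
               censored_share = mean(sub$alive_end))
  }))
  attr(out, "cohort") <- cohort
  class(out) <- c("ltca_lifetime", "data.frame")
  out
}

#' Benefit prevalence cross-section for a reference year
#'
#' December cross-section of recipients by single year of age, sex and
#' level, with population denominators (education aggregated out).
#'
#' @param sim a [run_scenario()] result.
#' @param year calendar year within the simulated range.
#' @return data.frame of class `"ltca_prevalence_report"`: `age`, `sex`,
#'   `population`, `level1` .. `level7` counts, `any_share`.
#' @export
prevalence_report <- function(sim, year) {
  stopifnot(inherits(sim, "ltca_sim"))
  yi <- match(year, sim$years)
  if (is.na(yi)) stop("year ", year, " outside the simulated range ",
                      min(sim$years), "-", max(sim$years))
  cnt <- apply(sim$dec[, , , , yi, drop = FALSE], c(1, 2, 4), sum)
  ages <- as.integer(dimnames(sim$dec)$age)
  out <- expand.grid(age = ages, sex = factor(SEX_LEVELS,
                                              levels = SEX_LEVELS))
  out$population <- as.vector(apply(cnt, c(1, 2), sum))
  for (l in 1:7)
    out[[paste0("level", l)]] <- as.vector(cnt[, , l + 1])
  out$any_share <- ifelse(out$population > 0,
                          rowSums(out[paste0("level", 1:7)]) /
                            out$population, NA_real_)
  attr(out, "year") <- year
  class(out) <- c("ltca_prevalence_report", "data.frame")
  out
}

#' @export
print.ltca_expenditure <- function(x, ...) {
  cat("Annual benefit expenditure (EUR, constant prices)\n")
  y <- as.data.frame(x)
  if (nrow(y) > 10)
    y <- y[round(seq(1, nrow(y), length.out = 10)), ]
  y[-1] <- lapply(y[-1], function(v) formatC(v, format = "f", digits = 0,
                                             big.mark = ","))
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
print.ltca_lifetime <- function(x, ...) {
  ch <- attr(x, "cohort")
  cat("Mean lifetime benefit cost per person, starting cohort aged ",
      ch[1], "-", ch[2], "\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 5)
  invisible(x)
}
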