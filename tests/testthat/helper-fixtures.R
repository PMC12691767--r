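# Shared fixtures, built once per test run.  Small problem sizes keep the
# default suite fast; the acceptance tests build their own larger inputs.

small_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- ltca_config(n_individuals = 1500, survey_n = 6000,
                         horizon = 2035, seed = 11)
      cache <<- list(cfg = cfg, inp = prepare_inputs(cfg))
    }
    cache
  }
})

# Minimal hand-built simulation result for accounting unit tests.
fake_sim <- function(persons, monthly_levels, years,
                     rules = ltca_rules()) {
  structure(list(monthly_levels = monthly_levels, persons = persons,
                 years = years, base_year = years[1],
                 scenario = scenario_config("S0"), seed = 0,
                 rules = rules, n_initial = nrow(persons),
                 events = data.frame(month = seq_len(12 * length(years)),
                                     year = rep(years, each = 12),
                                     entries = 0L, deaths = 0L),
                 dec = NULL, panel = NULL),
            class = "ltca_sim")
}

# Degenerate one-level prevalence model: everybody at `level` with
# probability one (via statistics concentrated on that level).
degenerate_model <- function(level, ages = 65:105) {
  svy <- generate_survey(survey_config(n_respondents = 2000, seed = 4))
  stats <- expand.grid(age = ages, sex = factor(c("male", "female"),
                                                levels = c("male", "female")),
                       level = 1:7)
  stats$prevalence <- as.numeric(stats$level == level)
  comp <- data.frame(age = ages, low = 1 / 3, medium = 1 / 3, high = 1 / 3)
  ltca_prevalence(svy, stats, comp)
}

zero_hazards <- function(years, ages = 65:105) {
  structure(list(h = array(0, dim = c(length(ages), 2, 3, length(years)),
                           dimnames = list(age = ages,
                                           sex = c("male", "female"),
                                           education = c("low", "medium",
                                                         "high"),
                                           year = years)),
                 years = years, ages = ages),
            class = "ltca_hazards")
}
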