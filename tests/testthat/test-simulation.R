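test_that("care age is the linear map anchored at 65", {
  expect_equal(care_age(70, 0.8), 69)
  expect_equal(care_age(75, 0.8), 73)
  expect_equal(care_age(90, 0.8), 85)
  expect_equal(care_age(65, 0.8), 65)
  expect_equal(care_age(75, 1.0), 75)
  expect_equal(care_age(c(70, 90), 0.8), c(69, 85))
  expect_error(care_age(60, 0.8), "65")
  expect_error(care_age(70, 1.2), "\\(0, 1\\]")
})

test_that("scenario presets match their definitions", {
  s0 <- scenario_config("S0"); s1 <- scenario_config("S1")
  s2 <- scenario_config("S2"); s3 <- scenario_config("S3")
  expect_true(s0$education_differentials && s0$care_age_factor == 1 &&
                s0$mortality_mode == "projected")
  expect_false(s1$education_differentials)
  expect_equal(s2$care_age_factor, 0.8)
  expect_equal(s3$mortality_mode, "constant_base_year")
  expect_error(scenario_config("custom", care_age_factor = 0), "\\(0, 1\\]")
})

test_that("hazard scaling preserves relative risks and meets targets", {
  # closed form: 100*2h + 100*h = 15 implies baseline h = 0.05
  al <- align_hazards(m_base = 1, rr = c(2, 1), exposure = c(100, 100),
                      deaths = 15)
  expect_equal(al$baseline, 0.05)
  expect_equal(al$adjusted, c(0.10, 0.05))
  expect_equal(al$adjusted[1] / al$adjusted[2], 2)
  # identical relative risks: hazard is deaths over exposure
  al2 <- align_hazards(1, c(1, 1, 1), c(50, 30, 20), 10)
  expect_equal(unique(al2$adjusted), 10 / 100)
  expect_error(align_hazards(1, c(1, 1), c(5, 5), 20), "exceed")
})

test_that("mortality alignment recovers the improvement surface exactly", {
  st <- small_setup()
  inp <- st$inp; cfg <- st$cfg
  hz <- inp$hazards
  # aligned hazards must equal baseline x improvement^(year-base) x rr in
  # every populated cell (the targets were generated by that very law)
  yi <- match(2030, hz$years)
  imp <- cfg$mortality$annual_improvement^(2030 - cfg$mortality$base_year)
  expected <- cfg$mortality$m_monthly[, "female"] %o%
    cfg$mortality$education_rr * imp
  got <- hz$h[, 2, , yi]
  pop_cells <- inp$targets$exposure[, 2, , yi] > 1e-6
  expect_lt(max(abs(got - expected)[pop_cells]), 1e-10)
})

test_that("monte-carlo deaths match aligned targets within poisson bounds", {
  st <- small_setup()
  inp <- st$inp
  R <- 30
  d <- matrix(0, R, length(2025:2035))
  for (r in seq_len(R)) {
    sim <- run_scenario(inp$population, inp$model, inp$hazards,
                        inp$entry, scenario_config("S0"), 2025, 2035,
                        seed = 100 + r)
    d[r, ] <- tapply(sim$events$deaths, sim$events$year, sum)
  }
  # conditional expectation given the realised stock
  proj <- expected_projection(st$cfg$population, st$cfg$mortality,
                              inp$entry, prevalence = NULL,
                              horizon = 2035, hazards = inp$hazards,
                              population = inp$population)
  tgt <- apply(proj$deaths, 3, sum)
  mc <- colMeans(d)
  expect_true(all(abs(mc - tgt) <= 3 * sqrt(pmax(tgt, 1) / R)))
})

test_that("runs are reproducible and respect common random numbers", {
  st <- small_setup()
  inp <- st$inp
  run <- function(sc) run_scenario(inp$population, inp$model, inp$hazards,
                                   inp$entry, sc, 2025, 2028, seed = 7)
  a <- run(scenario_config("S0"))
  b <- run(scenario_config("S0"))
  expect_identical(a$monthly_levels, b$monthly_levels)
  expect_identical(a$persons, b$persons)
  # care_age_factor = 1 is exactly the baseline under the same seed
  c2 <- run(scenario_config("custom", care_age_factor = 1.0))
  expect_identical(a$monthly_levels, c2$monthly_levels)
  expect_identical(a$persons$cum_payout_cents, c2$persons$cum_payout_cents)
})

test_that("a one-year horizon produces exactly twelve panel months", {
  st <- small_setup()
  inp <- st$inp
  sim <- run_scenario(inp$population, inp$model, inp$hazards, inp$entry,
                      scenario_config("S0"), 2025, 2025, seed = 3,
                      keep_panel = TRUE)
  expect_equal(nrow(sim$monthly_levels), 12)
  expect_equal(sort(unique(sim$panel$month)), 1:12)
})

test_that("zero hazards and a degenerate level produce exact payouts", {
  m1 <- degenerate_model(1)
  pop <- generate_population(population_config(n_individuals = 50,
                                               seed = 8))
  hz <- zero_hazards(2025:2025)
  entry0 <- entry_schedule(2025, base_size = 0)
  sim <- run_scenario(pop, m1, hz, entry0, scenario_config("S0"),
                      2025, 2025, seed = 5)
  expect_equal(sum(sim$events$deaths), 0)
  # every survivor accrues 12 monthly payments at level 1
  expect_true(all(sim$persons$cum_payout_cents == 12 * 20080))
  expect_equal(annual_expenditure(sim)$total, 50 * 12 * 200.80)
})

test_that("event log reconciles with the population every month", {
  st <- small_setup()
  inp <- st$inp
  sim <- run_scenario(inp$population, inp$model, inp$hazards, inp$entry,
                      scenario_config("S0"), 2025, 2032, seed = 13)
  expect_equal(sim$n_initial + sum(sim$events$entries) -
                 sum(sim$events$deaths), sum(sim$persons$alive_end))
  # deaths recorded per person match the event log month by month
  dm <- table(factor(sim$persons$death_month,
                     levels = seq_len(nrow(sim$events))))
  expect_equal(as.integer(dm), sim$events$deaths)
})

test_that("level draws have no longitudinal persistence", {
  # single-age cohort so every person shares one lookup cell per month
  pc <- population_config(n_individuals = 3000, age_range = c(70, 70),
                          seed = 9)
  pop <- generate_population(pc)
  st <- small_setup()
  hz <- zero_hazards(2025:2026)
  sim <- run_scenario(pop, st$inp$model, hz,
                      entry_schedule(2025:2026, 0),
                      scenario_config("S0"), 2025, 2026, seed = 10,
                      keep_panel = TRUE)
  pn <- sim$panel
  rec <- matrix(pn$level[order(pn$month, pn$id)] > 0, ncol = 24)
  # consecutive-month receipt indicators are uncorrelated within person
  # for fixed (age, sex, education) mixes the correlation reflects only
  # cell heterogeneity; with one age cell it should be near zero
  cors <- vapply(seq_len(23), function(m)
    suppressWarnings(stats::cor(rec[, m], rec[, m + 1])), numeric(1))
  expect_lt(max(abs(cors), na.rm = TRUE), 3 / sqrt(3000) + 0.05)
})

test_that("cross-sectional level shares track the model probabilities", {
  pc <- population_config(n_individuals = 2000, age_range = c(82, 82),
                          seed = 14)
  pop <- generate_population(pc)
  pop$age_months <- 82L * 12L   # pin birthdays so age is 82 all year
  st <- small_setup()
  hz <- zero_hazards(2025:2027)
  sim <- run_scenario(pop, st$inp$model, hz, entry_schedule(2025:2027, 0),
                      scenario_config("S0"), 2025, 2027, seed = 15,
                      keep_panel = TRUE)
  pn <- sim$panel[sim$panel$month <= 12, ]
  nd <- data.frame(age = 82, sex = pop$sex, education = pop$education)
  p_any <- mean(1 - predict(st$inp$model, nd)[, 1])
  emp <- mean(pn$level > 0)
  n_pm <- nrow(pn)
  expect_lt(abs(emp - p_any), 3 * sqrt(p_any * (1 - p_any) / n_pm))
})

test_that("stationary renewal stabilises under constant conditions", {
  # constant hazards and constant entries: expected population settles
  pc <- population_config(n_individuals = 2000, seed = 16)
  ms <- mortality_schedule(annual_improvement = 1)  # no improvement
  yrs <- 2025:2150
  es <- entry_schedule(yrs, base_size = 100, growth = 1)
  proj <- expected_projection(pc, ms, es, prevalence = NULL,
                              horizon = max(yrs))
  alive <- rowSums(matrix(apply(proj$exposure, 4, sum), ncol = 1)) / 12
  n_y <- length(alive)
  late <- alive[(n_y - 30):n_y]   # after one-lifespan burn-in
  decade_change <- abs(late[31] / late[21] - 1)
  expect_lt(decade_change, 0.01)
})
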