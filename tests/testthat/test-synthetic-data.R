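test_that("population generator honours size, seed and marginals", {
  cfg <- population_config(n_individuals = 10000, seed = 42,
                           age_range = c(65, 95),
                           female_share = 0.55,
                           age_weights = rep(1, 31))
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 10000)
  # female share within binomial 3-SE of the configured marginal
  se <- sqrt(0.55 * 0.45 / 10000)
  expect_lt(abs(mean(pop$sex == "female") - 0.55), 3 * se)
  # uniform ages: mean within 3 SE of the uniform mean
  expect_lt(abs(mean(pop$age) - 80), 3 * sqrt(mean((65:95 - 80)^2) / 10000))
  expect_true(all(pop$age_months %/% 12 == pop$age))
  # byte-identical rerun under the same config
  expect_identical(pop, generate_population(cfg))
  # a different seed changes the draw
  cfg2 <- population_config(n_individuals = 10000, seed = 43,
                            age_range = c(65, 95),
                            female_share = 0.55, age_weights = rep(1, 31))
  expect_false(identical(pop, generate_population(cfg2)))
})

test_that("population config rejects invalid shares and sizes", {
  expect_error(population_config(n_individuals = 0), "positive")
  expect_error(population_config(age_range = c(60, 105)), "at least 65")
  expect_error(population_config(female_share = 1.2), "\\[0, 1\\]")
  bad <- data.frame(birth_year = c(1920, 1960), low = c(0.9, 0.9),
                    high = c(0.3, 0.3))
  expect_error(population_config(education_anchors = bad), "composition")
})

test_that("one-individual population is a single well-formed record", {
  pop <- generate_population(population_config(n_individuals = 1, seed = 3))
  expect_equal(nrow(pop), 1)
  expect_true(pop$age >= 65 && pop$age <= 105)
  expect_true(pop$sex %in% c("male", "female"))
  expect_true(pop$education %in% c("low", "medium", "high"))
})

test_that("survey hours follow the generating logit cell probabilities", {
  # pin a cell probability and check the empirical share against it
  sc <- survey_config(n_respondents = 50000, seed = 7)
  target_cell <- expand.grid(age = 80, sex = "female", education = "low")
  p_true <- stats::plogis(
    ltcasim:::truth_linpred(sc$eligibility_coefficients, 80, "female",
                            "low", "eligibility", 2))
  svy <- generate_survey(sc)
  cell <- svy[svy$age == 80 & svy$sex == "female" & svy$education == "low", ]
  p_hat <- mean(cell$assessed_hours > 65)
  expect_lt(abs(p_hat - p_true),
            3 * sqrt(p_true * (1 - p_true) / nrow(cell)))
  # flags appear only above 180 assessed hours
  fl <- svy[, ltca_flags()]
  expect_true(all(svy$assessed_hours[rowSums(fl) > 0] > 180))
  # attached levels agree with the classifier applied to the record
  set.seed(1)
  idx <- sample.int(nrow(svy), 200)
  for (i in idx) {
    flags_i <- ltca_flags()[unlist(fl[i, ])]
    expect_identical(svy$level[i],
                     classify_level(svy$assessed_hours[i], flags_i))
  }
})

test_that("survey degenerate limits behave", {
  # zero dementia probability: no record carries the premium
  sc <- survey_config(n_respondents = 2000,
                      dementia_coefficients = c(-Inf, 0), seed = 5)
  svy <- generate_survey(sc)
  expect_false(any(svy$dementia))
  expect_equal(svy$base_hours, svy$assessed_hours)
  # impossible eligibility: everyone at or below 65 hours
  beta <- default_eligibility_coefficients()
  beta[grep(":a0$", names(beta))] <- -Inf
  sc2 <- survey_config(n_respondents = 2000,
                       eligibility_coefficients = beta, seed = 5)
  svy2 <- generate_survey(sc2)
  expect_true(all(svy2$assessed_hours <= 65))
  expect_true(all(svy2$level == 0))
})

test_that("generated prevalence is weakly decreasing in education", {
  # education offsets are negative going up the education scale, so
  # generated prevalence must fall with education in every age-sex cell
  sc <- survey_config()
  for (s in c("male", "female")) {
    P <- sapply(c("low", "medium", "high"), function(e)
      1 - level_probs_truth(sc, 65:105, s, e)[, 1])
    expect_true(all(diff(t(P)) <= 0))
  }
})

test_that("targets are proper sub-distributions consistent with truth", {
  st <- small_setup()
  tg <- st$inp$targets
  agg <- tapply(tg$prevalence$prevalence,
                list(tg$prevalence$age, tg$prevalence$sex), sum)
  expect_true(all(agg >= 0 & agg <= 1))
  expect_true(all(tg$prevalence$prevalence >= 0))
  # closed form vs large-sample simulation of the generating process
  sc <- survey_config(n_respondents = 60000, age_range = c(80, 80),
                      female_share = 1,
                      education_shares = c(low = 1, medium = 0, high = 0),
                      seed = 12)
  svy <- generate_survey(sc)
  p_closed <- level_probs_truth(sc, 80, "female", "low")
  emp <- tabulate(svy$level + 1L, 8) / nrow(svy)
  se <- sqrt(p_closed * (1 - p_closed) / nrow(svy))
  expect_true(all(abs(emp - p_closed) <= 3 * se + 1e-12))
})

test_that("zero eligibility truth yields an all-zero prevalence table", {
  beta <- default_eligibility_coefficients()
  beta[grep(":a0$", names(beta))] <- -Inf
  sc <- survey_config(eligibility_coefficients = beta)
  pc <- population_config(n_individuals = 100, seed = 2)
  ms <- mortality_schedule()
  es <- entry_schedule(2025:2027, base_size = 5)
  tg <- generate_targets(pc, ms, es, sc, horizon = 2027)
  expect_true(all(tg$prevalence$prevalence == 0))
})

test_that("target generation rejects mismatched age grids", {
  pc <- population_config(n_individuals = 100)
  ms <- mortality_schedule(ages = 65:80)
  es <- entry_schedule(2025:2026, base_size = 5)
  expect_error(generate_targets(pc, ms, es, survey_config()),
               "age-range mismatch")
})

test_that("entry schedule carries educational expansion", {
  es <- entry_schedule(2025:2080, base_size = 100)
  expect_true(all(diff(es$high) >= 0))
  expect_true(all(abs(rowSums(es[c("low", "medium", "high")]) - 1) < 1e-9))
  es0 <- entry_schedule(2025:2080, base_size = 100, expansion = FALSE)
  expect_true(all(es0$high == es0$high[1]))
})

test_that("mortality schedule validates its parameters", {
  expect_error(mortality_schedule(annual_improvement = 1.5), "\\(0, 1\\]")
  expect_error(mortality_schedule(education_rr = c(low = 1.3, medium = 2,
                                                   high = 0.8)),
               "medium must be 1")
  ms <- mortality_schedule()
  expect_true(all(ms$q_annual > 0 & ms$q_annual < 1))
  expect_true(all(diff(ms$q_annual[, "male"]) > 0))
  expect_true(all(ms$q_annual[, "female"] < ms$q_annual[, "male"]))
})
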