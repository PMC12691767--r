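test_that("saturated degree-0 fit reproduces cell-wise sample means", {
  svy <- generate_survey(survey_config(n_respondents = 5000, seed = 21))
  fit <- fit_care_logit(svy, "eligibility", degree = 0)
  y <- svy$assessed_hours > 65
  for (s in c("male", "female")) for (e in c("low", "medium", "high")) {
    cell <- svy$sex == s & svy$education == e
    p_hat <- predict(fit, data.frame(age = 70, sex = s, education = e),
                     type = "response")
    expect_equal(unname(p_hat), mean(y[cell]), tolerance = 1e-6)
  }
})

test_that("degenerate fitting samples raise informative errors", {
  svy <- generate_survey(survey_config(n_respondents = 500, seed = 22))
  svy$assessed_hours <- 10           # constant outcome
  expect_error(fit_care_logit(svy, "eligibility"), "constant")
  # missing education group: fully interactive design loses rank
  svy2 <- generate_survey(survey_config(n_respondents = 3000, seed = 23))
  svy2 <- svy2[svy2$education != "high", ]
  expect_error(fit_care_logit(svy2, "eligibility"), "rank deficient")
})

test_that("fit recovers generating coefficients at large n", {
  sc <- survey_config(n_respondents = 20000, seed = 24)
  svy <- generate_survey(sc)
  fit <- fit_care_logit(svy, "eligibility")
  expect_lt(fit$score_norm, 1e-4)
  truth <- sc$eligibility_coefficients[names(fit$coefficients)]
  z <- (fit$coefficients - truth) / sqrt(diag(fit$vcov))
  expect_lt(max(abs(z)), 5)
  # estimation chain recovers generating cell prevalences closely
  grid <- expand.grid(age = 65:99, sex = c("male", "female"),
                      education = c("low", "medium", "high"))
  p_true <- stats::plogis(ltcasim:::truth_linpred(
    sc$eligibility_coefficients, grid$age, grid$sex, grid$education,
    "eligibility", 2))
  p_fit <- predict(fit, grid, type = "response")
  expect_lt(mean(abs(p_fit - p_true)), 0.01)
})

test_that("marginal predictions collapse when education has no effect", {
  fit <- structure(list(
    coefficients = c(a0 = -1, a1 = 0.5, a2 = 0, female = 0.2,
                     edu_low = 0, edu_high = 0, `a1:female` = 0,
                     `a2:female` = 0, `a1:edu_low` = 0, `a2:edu_low` = 0,
                     `a1:edu_high` = 0, `a2:edu_high` = 0),
    vcov = diag(1e-4, 12), outcome = "severity", degree = 2),
    class = "care_logit")
  smp <- data.frame(age = c(70, 85, 90), sex = "female",
                    education = "medium")
  amp <- average_marginal_predictions(fit, smp)
  expect_equal(diff(amp$predictions$estimate), c(0, 0))
  expect_equal(amp$contrasts$estimate, c(0, 0, 0))
  expect_error(average_marginal_predictions(fit, smp[0, ]), "empty")
})

test_that("marginal prediction equals the hand-computed two-row mean", {
  fit <- structure(list(
    coefficients = c(a0 = 0.3, a1 = 0.4, female = 0.2, edu_low = -0.1,
                     edu_high = 0.5, `a1:female` = 0, `a1:edu_low` = 0,
                     `a1:edu_high` = 0),
    vcov = diag(1e-6, 8), outcome = "severity", degree = 1),
    class = "care_logit")
  smp <- data.frame(age = c(75, 95), sex = c("male", "female"),
                    education = "medium")
  amp <- average_marginal_predictions(fit, smp)
  # education forced to "high": eta = 0.3 + 0.4*a + 0.2*female + 0.5
  by_hand <- mean(stats::plogis(c(0.3 + 0.4 * 1 + 0.5,
                                  0.3 + 0.4 * 3 + 0.2 + 0.5)))
  expect_equal(amp$predictions$estimate[3], by_hand, tolerance = 1e-12)
})

test_that("delta-method SEs agree with the bootstrap", {
  sc <- survey_config(n_respondents = 2000, seed = 25)
  svy <- generate_survey(sc)
  fit <- fit_care_logit(svy, "eligibility", degree = 1)
  amp <- average_marginal_predictions(fit, svy)
  set.seed(26)
  B <- 500
  boot <- replicate(B, {
    idx <- sample.int(nrow(svy), replace = TRUE)
    bfit <- fit_care_logit(svy[idx, ], "eligibility", degree = 1)
    average_marginal_predictions(bfit, svy)$predictions$estimate
  })
  se_boot <- apply(boot, 1, stats::sd)
  expect_true(all(abs(amp$predictions$se - se_boot) / se_boot < 0.15))
})

test_that("cell alignment solves the weighted logistic equation", {
  # shift of zero when the target is already met
  lo <- c(-1.2, -0.4, 0.3); w <- c(0.3, 0.5, 0.2)
  t0 <- sum(w * stats::plogis(lo))
  expect_equal(align_cell(lo, w, t0), 0, tolerance = 1e-10)
  # closed form for a single group: logit(target) - logit(p)
  expect_equal(align_cell(0, 1, 0.25), stats::qlogis(0.25),
               tolerance = 1e-10)
  # residual below the probability tolerance for arbitrary cells
  d <- align_cell(lo, w, 0.37)
  expect_lt(abs(sum(w * stats::plogis(lo + d)) - 0.37), 1e-10)
  # grid-search oracle agrees with the root-finder
  dg <- seq(d - 0.001, d + 0.001, by = 1e-6)
  obj <- abs(vapply(dg, function(x)
    sum(w * stats::plogis(lo + x)) - 0.37, numeric(1)))
  expect_lt(abs(dg[which.min(obj)] - d), 1e-5)
  # sentinels and validation
  expect_identical(align_cell(lo, w, 0), -Inf)
  expect_identical(align_cell(lo, w, 1), Inf)
  expect_error(align_cell(lo, w, 1.2), "\\[0, 1\\]")
  expect_error(align_cell(lo, c(-1, 1, 1), 0.5), "non-negative")
})

test_that("aligned model reproduces the statistics and education odds", {
  st <- small_setup()
  m <- st$inp$model
  expect_equal(m$renormalised_cells, 0)
  # education-weighted aggregation is the identity on the statistics
  agg <- aggregate_prevalence(m)
  mrg <- merge(agg, m$stats, by = c("age", "sex", "level"))
  expect_lt(max(abs(mrg$aggregated - mrg$prevalence)), 1e-8)
  # alignment leaves within-band education odds ratios untouched:
  # levels within a band share identical pairwise log-odds differences
  tab <- m$table[m$table$age == 80 & m$table$sex == "female", ]
  lo <- stats::qlogis(as.matrix(tab[paste0("level", 1:7)]))
  for (band in list(1:2, 3:7)) {
    d_low_high <- lo[1, band] - lo[3, band]
    expect_lt(max(d_low_high) - min(d_low_high), 1e-6)
  }
  # per-person level probabilities are a proper sub-distribution
  P <- as.matrix(m$table[paste0("level", 0:7)])
  expect_true(all(P >= -1e-12))
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
})

test_that("collapse cases of the aligned model", {
  st <- small_setup()
  inp <- st$inp
  # all-zero statistics: everyone at level 0
  stats0 <- inp$targets$prevalence
  stats0$prevalence <- 0
  m0 <- build_prevalence_model(inp$model$fits$eligibility,
                               inp$model$fits$severity, stats0,
                               inp$targets$composition)
  expect_true(all(m0$table$level0 == 1))
  # education differentials off: model equals the statistics for every
  # education group
  mz <- build_prevalence_model(inp$model$fits$eligibility,
                               inp$model$fits$severity,
                               inp$targets$prevalence,
                               inp$targets$composition,
                               education_differentials = FALSE)
  key <- paste(inp$targets$prevalence$age, inp$targets$prevalence$sex,
               inp$targets$prevalence$level)
  for (l in c(1, 4, 7)) {
    i <- match(paste(mz$table$age, mz$table$sex, l), key)
    expect_equal(mz$table[[paste0("level", l)]],
                 inp$targets$prevalence$prevalence[i], tolerance = 1e-9)
  }
})

test_that("infeasible statistics are rejected", {
  st <- small_setup()
  inp <- st$inp
  bad <- inp$targets$prevalence
  bad$prevalence <- 0.2   # sums to 1.4 per cell
  expect_error(build_prevalence_model(inp$model$fits$eligibility,
                                      inp$model$fits$severity, bad,
                                      inp$targets$composition),
               "infeasible")
})

test_that("simulating from the aligned model returns the statistics", {
  st <- small_setup()
  m <- st$inp$model
  comp <- st$inp$targets$composition
  # moderate check per cell at age 85; the acceptance suite covers the
  # full grid at larger n
  for (s in c("male", "female")) {
    w <- unlist(comp[comp$age == 85, c("low", "medium", "high")])
    n_c <- 4000
    set.seed(31)
    edu <- c("low", "medium", "high")[
      1 + findInterval(stats::runif(n_c), cumsum(w))]
    nd <- data.frame(age = 85, sex = s, education = edu)
    lv <- simulate(m, nsim = 1, seed = 32, newdata = nd)
    emp <- tabulate(lv + 1L, 8)[2:8] / n_c
    tgt <- vapply(1:7, function(l)
      m$stats$prevalence[m$stats$age == 85 & m$stats$sex == s &
                           m$stats$level == l], numeric(1))
    se <- sqrt(tgt * (1 - tgt) / n_c)
    expect_true(all(abs(emp - tgt) <= 3 * se + 1e-9))
  }
})
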