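# Two-step prevalence estimation: a fully interactive any-receipt logit
# (> 65 h of assessed need), a severity logit (>= 120 h given > 65 h), and
# alignment of the education-specific predicted log odds to aggregate
# benefit statistics by one-dimensional root finding.

#' Fit a care-need logit equation
#'
#' Maximum-likelihood logistic regression for one of the two care-need
#' outcomes.  `"eligibility"` models assessed hours above 65 per month on
#' the full sample with a fully interactive design (age polynomial per
#' sex-by-education cell); `"severity"` models hours of 120 or more on the
#' subsample above 65 h, with the age polynomial interacting with sex and
#' with education separately.
#'
#' @param survey data.frame with columns `age`, `sex`, `education` and the
#'   hours column.
#' @param outcome `"eligibility"` or `"severity"`.
#' @param degree age-polynomial degree.
#' @param hours_col name of the assessed-hours column.
#' @param thresholds c(any-receipt, severity) hour cutpoints.
#' @return object of class `"care_logit"` with `coefficients`, `vcov`,
#'   fitted values and fit diagnostics.
#' @export
fit_care_logit <- function(survey, outcome = c("eligibility", "severity"),
                           degree = 2, hours_col = "assessed_hours",
                           thresholds = c(65, 120)) {
  outcome <- match.arg(outcome)
  hours <- survey[[hours_col]]
  if (is.null(hours)) stop("survey lacks column ", hours_col)
  if (outcome == "severity") {
    survey <- survey[hours > thresholds[1], , drop = FALSE]
    y <- as.numeric(survey[[hours_col]] >= thresholds[2])
  } else {
    y <- as.numeric(hours > thresholds[1])
  }
  if (length(unique(y)) < 2L)
    stop("outcome is constant on the fitting sample; ",
         "the logit is not identified (complete separation)")
  X <- logit_design(survey$age, survey$sex, survey$education, outcome,
                    degree = degree)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending cells: ",
         paste(drop_cols, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(), control =
                     stats::glm.control(maxit = 100)))
  mu <- fit$fitted.values
  beta <- fit$coefficients
  sep <- tapply(mu, interaction(survey$sex, survey$education), function(p)
    all(p < 1e-8) || all(p > 1 - 1e-8))
  if (any(sep, na.rm = TRUE) || any(abs(beta) > 30))
    stop("perfect separation detected; offending cell(s): ",
         paste(names(sep)[which(sep)], collapse = ", "),
         if (any(abs(beta) > 30))
           paste0(" (divergent coefficients: ",
                  paste(names(beta)[abs(beta) > 30], collapse = ", "), ")"))
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  V <- chol2inv(chol(info))
  dimnames(V) <- list(names(beta), names(beta))
  score <- drop(crossprod(X, y - mu))
  structure(list(coefficients = beta, vcov = V, outcome = outcome,
                 degree = degree, n = length(y),
                 deviance = fit$deviance, converged = fit$converged,
                 score_norm = sqrt(sum(score^2)),
                 prop = mean(y)),
            class = "care_logit")
}

#' @export
vcov.care_logit <- function(object, ...) object$vcov

#' Predict from a fitted care-need logit
#'
#' @param object a `care_logit` fit.
#' @param newdata data.frame with `age`, `sex`, `education`.
#' @param type `"link"` (log odds) or `"response"` (probability).
#' @param ... unused.
#' @export
predict.care_logit <- function(object, newdata,
                               type = c("link", "response"), ...) {
  type <- match.arg(type)
  X <- logit_design(newdata$age, newdata$sex, newdata$education,
                    object$outcome, degree = object$degree)
  eta <- drop(X[, names(object$coefficients), drop = FALSE] %*%
                object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.care_logit <- function(x, ...) {
  cat("Care-need logit (", x$outcome, "), n = ", x$n,
      ", outcome share = ", signif(x$prop, 3), "\n", sep = "")
  cat("Age polynomial degree ", x$degree, "; ", length(x$coefficients),
      " coefficients; score norm ", format(x$score_norm, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Average marginal predictions by education with contrasts
#'
#' For each education group the covariate is set to that group for every
#' respondent and the predicted probabilities are averaged; pairwise group
#' contrasts carry delta-method standard errors from the fit's coefficient
#' covariance.
#'
#' @param fit a [fit_care_logit()] object.
#' @param sample data.frame over which to average (must be non-empty, with
#'   `age`, `sex`, `education`).
#' @param conf_level confidence level for intervals.
#' @return list of class `"ltca_amp"` with `predictions` and `contrasts`
#'   data.frames.
#' @export
average_marginal_predictions <- function(fit, sample, conf_level = 0.95) {
  stopifnot(inherits(fit, "care_logit"))
  if (is.null(sample) || nrow(sample) == 0L) stop("empty sample")
  groups <- EDU_LEVELS
  p <- numeric(3); grads <- matrix(0, 3, length(fit$coefficients))
  for (g in seq_along(groups)) {
    nd <- sample
    nd$education <- factor(groups[g], levels = EDU_LEVELS)
    X <- logit_design(nd$age, nd$sex, nd$education, fit$outcome,
                      degree = fit$degree)
    X <- X[, names(fit$coefficients), drop = FALSE]
    mu <- stats::plogis(drop(X %*% fit$coefficients))
    p[g] <- mean(mu)
    grads[g, ] <- colMeans(X * (mu * (1 - mu)))
  }
  se <- sqrt(rowSums((grads %*% fit$vcov) * grads))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  preds <- data.frame(education = groups, estimate = p, se = se,
                      lower = p - z * se, upper = p + z * se)
  pairs <- utils::combn(3, 2)
  cd <- apply(pairs, 2, function(ij) {
    d <- grads[ij[1], ] - grads[ij[2], ]
    est <- p[ij[1]] - p[ij[2]]
    s <- sqrt(drop(d %*% fit$vcov %*% d))
    c(est, s)
  })
  contrasts <- data.frame(
    contrast = apply(pairs, 2, function(ij)
      paste(groups[ij[1]], "-", groups[ij[2]])),
    estimate = cd[1, ], se = cd[2, ],
    z = cd[1, ] / cd[2, ],
    p_value = 2 * stats::pnorm(-abs(cd[1, ] / cd[2, ])))
  structure(list(predictions = preds, contrasts = contrasts,
                 outcome = fit$outcome, conf_level = conf_level),
            class = "ltca_amp")
}

#' @export
print.ltca_amp <- function(x, ...) {
  cat("Average marginal predictions (", x$outcome, ") by education\n",
      sep = "")
  print(x$predictions, row.names = FALSE, digits = 4)
  cat("\nPairwise contrasts (delta method)\n")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Align education-specific log odds to an aggregate target
#'
#' Finds the additive log-odds shift `delta` such that the
#' education-weighted mean of `plogis(log_odds + delta)` equals the target
#' prevalence.  The weighted mean is strictly increasing in `delta`, so
#' the root is unique; it is bracketed and polished to a probability-scale
#' residual below `tol`.  Targets of 0 and 1 return `-Inf`/`+Inf`
#' (interpreted downstream as "nobody"/"everybody").  The shift is common
#' to all groups, so within-cell education odds ratios are untouched.
#'
#' @param log_odds numeric vector of per-group predicted log odds
#'   (may contain `-Inf`).
#' @param weights non-negative group weights (normalised internally).
#' @param target aggregate prevalence in [0, 1].
#' @param tol tolerance on the probability scale.
#' @return scalar shift `delta`.
#' @export
align_cell <- function(log_odds, weights, target, tol = 1e-12) {
  if (length(weights) != length(log_odds))
    stop("log_odds and weights must have equal length")
  if (any(weights < 0)) stop("weights must be non-negative")
  sw <- sum(weights)
  if (sw <= 0) stop("weights must have positive sum")
  weights <- weights / sw
  if (is.na(target) || target < 0 || target > 1)
    stop("target must lie in [0, 1]")
  if (target == 0) return(-Inf)
  if (target >= 1) return(Inf)
  reachable <- sum(weights[is.finite(log_odds)])
  if (reachable < target)
    stop("target ", target, " exceeds the reachable maximum ", reachable)
  f <- function(d) sum(weights * stats::plogis(log_odds + d)) - target
  lowerd <- -40; upperd <- 40
  while (f(lowerd) > 0) lowerd <- lowerd * 2
  while (f(upperd) < 0) upperd <- upperd * 2
  d <- stats::uniroot(f, c(lowerd, upperd), tol = 1e-12)$root
  # Newton polish on the probability scale
  for (i in 1:5) {
    r <- f(d)
    if (abs(r) < tol) break
    mu <- stats::plogis(log_odds + d)
    dp <- sum(weights * mu * (1 - mu))
    if (dp <= 0) break
    d <- d - r / dp
  }
  d
}

validate_prevalence_stats <- function(stats, ages) {
  need <- c("age", "sex", "level", "prevalence")
  if (!all(need %in% names(stats)))
    stop("prevalence statistics need columns ", paste(need, collapse = ", "))
  if (any(stats$prevalence < 0 | stats$prevalence > 1))
    stop("prevalence values must lie in [0, 1]")
  agg <- tapply(stats$prevalence, list(stats$age, stats$sex), sum)
  if (any(agg > 1 + 1e-9, na.rm = TRUE))
    stop("infeasible statistics: level prevalences sum above 1 in ",
         sum(agg > 1 + 1e-9, na.rm = TRUE), " age-sex cell(s)")
  miss <- setdiff(ages, unique(stats$age))
  if (length(miss))
    stop("prevalence statistics missing ages: ",
         paste(utils::head(miss, 5), collapse = ", "))
  invisible(TRUE)
}

#' Build the aligned prevalence model
#'
#' Combines the two fitted logit equations with the aggregate benefit
#' statistics into P(level | age, sex, education), level 0..7, on the full
#' age grid of the statistics.  Within each age-sex cell: (1) the
#' education-specific any-receipt log odds from the eligibility equation
#' are shifted so that the education-weighted any-receipt probability
#' equals the statistics' total; (2) the severity log odds are shifted so
#' the recipient-weighted share in the upper band (levels 3--7) matches;
#' (3) each of the seven levels is then aligned separately to its own
#' prevalence, applying the unconditional band log odds (identical
#' education odds for every level within a band).  If a person's level
#' probabilities sum above 1 they are renormalised and the event counted.
#'
#' @param elig_fit,sev_fit fits from [fit_care_logit()].
#' @param stats data.frame `age`, `sex`, `level` (1..7), `prevalence`.
#' @param composition education weights by age: data.frame `age`, `low`,
#'   `medium`, `high`.
#' @param education_differentials set `FALSE` to ignore the fitted
#'   education gradients (the model then reproduces the statistics for
#'   every education group).
#' @return object of class `"ltca_prevalence"`.
#' @export
build_prevalence_model <- function(elig_fit, sev_fit, stats, composition,
                                   education_differentials = TRUE) {
  ages <- sort(unique(stats$age))
  validate_prevalence_stats(stats, ages)
  wmat <- as.matrix(composition[match(ages, composition$age),
                                c("low", "medium", "high")])
  if (anyNA(wmat)) stop("composition does not cover all statistic ages")
  n_cells <- length(ages) * 2L
  tab <- expand.grid(education = factor(EDU_LEVELS, levels = EDU_LEVELS),
                     sex = factor(SEX_LEVELS, levels = SEX_LEVELS),
                     age = ages)[, 3:1]
  probs <- matrix(0, nrow(tab), 8,
                  dimnames = list(NULL, paste0("level", 0:7)))
  shifts <- expand.grid(sex = factor(SEX_LEVELS, levels = SEX_LEVELS),
                        age = ages)[, 2:1]
  shifts$delta_any <- shifts$delta_sev <- NA_real_
  shiftmat <- matrix(NA_real_, n_cells, 7,
                     dimnames = list(NULL, paste0("delta_l", 1:7)))
  renorm <- 0L
  key <- paste(stats$age, stats$sex, stats$level)
  prev_of <- function(a, s, l)
    stats$prevalence[match(paste(a, SEX_LEVELS[s], l), key)]
  row_i <- 0L
  for (ai in seq_along(ages)) for (s in 1:2) {
    row_i <- row_i + 1L
    a <- ages[ai]; w <- wmat[ai, ]
    targ <- vapply(1:7, function(l) prev_of(a, s, l), numeric(1))
    p_any_t <- sum(targ)
    nd <- data.frame(age = a, sex = SEX_LEVELS[s], education = EDU_LEVELS)
    lo_any <- predict(elig_fit, nd, type = "link")
    lo_sev <- predict(sev_fit, nd, type = "link")
    if (!education_differentials) lo_any[] <- lo_sev[] <- 0
    tab_rows <- which(tab$age == a & tab$sex == SEX_LEVELS[s])
    if (p_any_t <= 0) {
      probs[tab_rows, ] <- rep(c(1, rep(0, 7)), each = 3)
      shifts$delta_any[row_i] <- -Inf
      next
    }
    d_any <- align_cell(lo_any, w, p_any_t)
    p_any_e <- stats::plogis(lo_any + d_any)
    wc <- w * p_any_e / sum(w * p_any_e)
    hi_t <- sum(targ[3:7]) / p_any_t
    d_sev <- if (hi_t <= 0) -Inf else if (hi_t >= 1) Inf else
      align_cell(lo_sev, wc, hi_t)
    p_hi_e <- stats::plogis(lo_sev + d_sev)
    band <- cbind(lower = p_any_e * (1 - p_hi_e), upper = p_any_e * p_hi_e)
    P <- matrix(0, 3, 7)
    for (l in 1:7) {
      pb <- band[, if (l <= 2) "lower" else "upper"]
      if (targ[l] <= 0) next
      eta <- stats::qlogis(pmin(pmax(pb, 1e-300), 1 - 1e-16))
      d_l <- align_cell(eta, w, targ[l])
      P[, l] <- stats::plogis(eta + d_l)
      shiftmat[row_i, l] <- d_l
    }
    s_tot <- rowSums(P)
    over <- s_tot > 1
    if (any(over)) {
      P[over, ] <- P[over, , drop = FALSE] / s_tot[over]
      renorm <- renorm + sum(over)
    }
    probs[tab_rows, 1] <- 1 - rowSums(P)
    probs[tab_rows, 2:8] <- P
    shifts$delta_any[row_i] <- d_any
    shifts$delta_sev[row_i] <- d_sev
  }
  pooled <- matrix(0, n_cells, 8,
                   dimnames = list(NULL, paste0("level", 0:7)))
  for (l in 1:7)
    pooled[, l + 1] <- vapply(seq_len(n_cells), function(i)
      prev_of(shifts$age[i], as.integer(shifts$sex[i]), l), numeric(1))
  pooled[, 1] <- 1 - rowSums(pooled[, 2:8, drop = FALSE])
  structure(list(table = cbind(tab, as.data.frame(probs)),
                 shifts = cbind(shifts, as.data.frame(shiftmat)),
                 pooled = cbind(shifts[, c("age", "sex")],
                                as.data.frame(pooled)),
                 fits = list(eligibility = elig_fit, severity = sev_fit),
                 stats = stats, composition = composition, ages = ages,
                 renormalised_cells = renorm,
                 education_differentials = education_differentials),
            class = "ltca_prevalence")
}

#' Fit the full aligned prevalence model from survey and statistics
#'
#' One-stop model fit: estimates the any-receipt (> 65 h) and severity
#' (>= 120 h) logit equations on the survey and aligns their
#' education-specific predictions to the aggregate benefit statistics.
#' This is the model object consumed by the simulation engine.
#'
#' @param survey a care-need survey (see [generate_survey()]).
#' @param stats aggregate prevalence statistics (age, sex, level,
#'   prevalence).
#' @param composition education shares by age.
#' @param degree age-polynomial degree of both logits.
#' @param ... passed to [build_prevalence_model()].
#' @return an object of class `"ltca_prevalence"`; see
#'   [build_prevalence_model()] for its structure, and
#'   [predict.ltca_prevalence()], [simulate.ltca_prevalence()],
#'   [summary.ltca_prevalence()] for methods.
#' @examples
#' sc <- survey_config(n_respondents = 4000, seed = 7)
#' svy <- generate_survey(sc)
#' pc <- population_config(n_individuals = 2000, seed = 7)
#' ms <- mortality_schedule()
#' es <- entry_schedule(2025:2030, base_size = 100)
#' tg <- generate_targets(pc, ms, es, sc, horizon = 2030)
#' fit <- ltca_prevalence(svy, tg$prevalence, tg$composition)
#' fit
#' @export
ltca_prevalence <- function(survey, stats, composition, degree = 2, ...) {
  elig <- fit_care_logit(survey, "eligibility", degree = degree)
  sev <- fit_care_logit(survey, "severity", degree = degree)
  out <- build_prevalence_model(elig, sev, stats, composition, ...)
  out$survey_n <- nrow(survey)
  out
}

#' @export
print.ltca_prevalence <- function(x, ...) {
  cat("Aligned care-allowance prevalence model\n")
  cat("  ages ", min(x$ages), "-", max(x$ages),
      " (", length(x$ages) * 2L, " age-sex cells, 7 levels)\n", sep = "")
  cat("  eligibility fit: n =", x$fits$eligibility$n,
      "| severity fit: n =", x$fits$severity$n, "\n")
  cat("  education differentials:",
      if (x$education_differentials) "on" else "off",
      "| renormalised cells:", x$renormalised_cells, "\n")
  invisible(x)
}

#' @export
coef.ltca_prevalence <- function(object, ...)
  list(eligibility = object$fits$eligibility$coefficients,
       severity = object$fits$severity$coefficients)

#' Predict allowance-level probabilities
#'
#' @param object an [ltca_prevalence()] model.
#' @param newdata data.frame with `age`, `sex`, `education`; ages outside
#'   the model grid are clamped to its ends (the top age is an open
#'   interval).
#' @param pooled if `TRUE`, return the education-independent probabilities
#'   (the statistics themselves), as used when education differentials are
#'   switched off.
#' @param ... unused.
#' @return matrix (n x 8) of probabilities, columns `level0`..`level7`.
#' @export
predict.ltca_prevalence <- function(object, newdata, pooled = FALSE, ...) {
  a <- pmin(pmax(newdata$age, min(object$ages)), max(object$ages))
  s <- as_sex_int(newdata$sex)
  if (pooled) {
    i <- match(paste(a, s), paste(object$pooled$age,
                                  as.integer(object$pooled$sex)))
    return(as.matrix(object$pooled[i, paste0("level", 0:7)]))
  }
  e <- as_edu_int(newdata$education)
  i <- match(paste(a, s, e), paste(object$table$age,
                                   as.integer(object$table$sex),
                                   as.integer(object$table$education)))
  if (anyNA(i))
    stop("prevalence lookup failed for cell(s): ",
         paste(utils::head(paste(a, SEX_LEVELS[s], EDU_LEVELS[e])[is.na(i)],
                           3), collapse = "; "))
  as.matrix(object$table[i, paste0("level", 0:7)])
}

#' Draw allowance levels from the model
#'
#' @param object an [ltca_prevalence()] model.
#' @param nsim number of independent draws per row of `newdata`.
#' @param seed RNG seed (restored on exit).
#' @param newdata data.frame with `age`, `sex`, `education`.
#' @param pooled use education-independent probabilities.
#' @param stratified use a stratified uniform grid (randomly permuted
#'   within each group of rows sharing the same lookup cell) instead of
#'   iid uniforms for the inverse-CDF draw.  Marginally each draw still
#'   follows the model; jointly the draws are balanced, so realised level
#'   shares within a cell deviate from the model probabilities by at most
#'   a few counts.  This is the variance-reduction device commonly used
#'   to check (and enforce) alignment in microsimulation: any residual
#'   deviation from the target statistics is then bias, not noise.
#' @param ... unused.
#' @return integer matrix (nrow(newdata) x nsim) of levels 0..7.
#' @export
simulate.ltca_prevalence <- function(object, nsim = 1, seed = 1,
                                     newdata = NULL, pooled = FALSE,
                                     stratified = FALSE, ...) {
  if (is.null(newdata)) stop("newdata is required")
  P <- predict(object, newdata, pooled = pooled)
  CUM <- t(apply(P, 1, cumsum))
  n <- nrow(P)
  grp <- NULL
  if (stratified) {
    key <- paste(pmin(pmax(newdata$age, min(object$ages)),
                      max(object$ages)),
                 as_sex_int(newdata$sex),
                 if (pooled) 0L else as_edu_int(newdata$education))
    grp <- split(seq_len(n), key)
  }
  with_seed(seed, {
    out <- matrix(0L, n, nsim)
    for (j in seq_len(nsim)) {
      if (stratified) {
        u <- numeric(n)
        for (idx in grp) {
          ng <- length(idx)
          u[idx] <- (sample.int(ng) - stats::runif(ng)) / ng
        }
      } else {
        u <- stats::runif(n)
      }
      lv <- integer(n)
      for (k in 1:7) lv <- lv + (u > CUM[, k])
      out[, j] <- lv
    }
    out
  })
}

#' Summary of the aligned prevalence model
#'
#' Reports average marginal predictions by education for both equations
#' and the aggregate alignment error (maximum absolute difference between
#' the education-weighted model prevalence and the input statistics).
#'
#' @param object an [ltca_prevalence()] model.
#' @param survey optional survey sample over which to average the marginal
#'   predictions; omitted if `NULL`.
#' @param ... unused.
#' @export
summary.ltca_prevalence <- function(object, survey = NULL, ...) {
  agg <- aggregate_prevalence(object)
  m <- merge(agg, object$stats, by = c("age", "sex", "level"))
  out <- list(model = object,
              max_alignment_error = max(abs(m$aggregated - m$prevalence)),
              renormalised_cells = object$renormalised_cells)
  if (!is.null(survey)) {
    out$amp_eligibility <-
      average_marginal_predictions(object$fits$eligibility, survey)
    out$amp_severity <-
      average_marginal_predictions(object$fits$severity, survey)
  }
  class(out) <- "summary.ltca_prevalence"
  out
}

#' @export
print.summary.ltca_prevalence <- function(x, ...) {
  print(x$model)
  cat("  max |aggregated - statistics| =",
      format(x$max_alignment_error, digits = 3), "\n\n")
  if (!is.null(x$amp_eligibility)) { print(x$amp_eligibility); cat("\n") }
  if (!is.null(x$amp_severity)) print(x$amp_severity)
  invisible(x)
}

#' Education-weighted aggregate prevalence implied by the model
#'
#' Aggregating the model back over the education composition should
#' reproduce the input statistics (up to renormalised cells); used for
#' round-trip checks.
#'
#' @param object an [ltca_prevalence()] model.
#' @return data.frame `age`, `sex`, `level`, `aggregated`.
#' @export
aggregate_prevalence <- function(object) {
  tab <- object$table
  w <- as.matrix(object$composition[match(tab$age, object$composition$age),
                                    c("low", "medium", "high")])
  wt <- w[cbind(seq_len(nrow(tab)), as.integer(tab$education))]
  out <- do.call(rbind, lapply(1:7, function(l) {
    v <- tapply(wt * tab[[paste0("level", l)]],
                list(tab$age, tab$sex), sum)
    data.frame(age = as.integer(rownames(v)[row(v)]),
               sex = colnames(v)[col(v)], level = l,
               aggregated = as.vector(v))
  }))
  out$sex <- factor(out$sex, levels = SEX_LEVELS)
  out
}

#' Plot aligned prevalence curves
#'
#' Any-receipt prevalence by age for each sex and education group, with
#' the aggregate statistics overlaid.
#'
#' @param x an [ltca_prevalence()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ltca_prevalence <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (s in SEX_LEVELS) {
    tab <- x$table[x$table$sex == s, ]
    any_p <- 1 - tab$level0
    m <- matrix(any_p, ncol = 3, byrow = TRUE)
    graphics::matplot(x$ages, m, type = "l", lty = 1:3, col = 1,
                      xlab = "age", ylab = "P(any allowance)",
                      main = s, ylim = c(0, 1), ...)
    agg <- tapply(x$stats$prevalence[x$stats$sex == s],
                  x$stats$age[x$stats$sex == s], sum)
    graphics::points(as.integer(names(agg)), agg, pch = 16, cex = 0.4,
                     col = "grey40")
    graphics::legend("topleft", legend = c(EDU_LEVELS, "statistics"),
                     lty = c(1:3, NA), pch = c(NA, NA, NA, 16),
                     col = c(1, 1, 1, "grey40"), bty = "n", cex = 0.8)
  }
  invisible(x)
}
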