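# Shared covariate coding for the two logit equations.  The generator and
# the fitting routine build their linear predictors from the same design
# columns, so generating coefficients live in the same basis as estimates.

EDU_LEVELS <- c("low", "medium", "high")
SEX_LEVELS <- c("male", "female")

age_scale <- function(age) (age - 65) / 10

as_sex_int <- function(sex) {
  if (is.numeric(sex)) return(as.integer(sex))
  match(as.character(sex), SEX_LEVELS)
}

as_edu_int <- function(education) {
  if (is.numeric(education)) return(as.integer(education))
  match(as.character(education), EDU_LEVELS)
}

#' Design matrix for the care-need logit equations
#'
#' Two designs are used.  The any-receipt ("eligibility", assessed need
#' above 65 h/month) equation is fully interactive: each of the six
#' sex-by-education cells carries its own age polynomial.  The severity
#' equation (need of 120 h or more, conditional on being above 65 h) lets
#' the age polynomial interact with sex and with education separately,
#' without the three-way term; medium education and male are the reference
#' categories.
#'
#' @param age numeric vector of ages in years.
#' @param sex `"male"`/`"female"` (or 1/2).
#' @param education `"low"`/`"medium"`/`"high"` (or 1/2/3).
#' @param outcome `"eligibility"` or `"severity"`.
#' @param degree degree of the age polynomial (default 2); age enters as
#'   `((age - 65)/10)^k`.
#' @return numeric matrix with one row per observation.
#' @export
logit_design <- function(age, sex, education,
                         outcome = c("eligibility", "severity"),
                         degree = 2) {
  outcome <- match.arg(outcome)
  s <- as_sex_int(sex); e <- as_edu_int(education)
  if (anyNA(s)) stop("sex must be 'male'/'female' or 1/2")
  if (anyNA(e)) stop("education must be 'low'/'medium'/'high' or 1/2/3")
  a <- age_scale(age)
  n <- length(a)
  apow <- vapply(0:degree, function(k) a^k, numeric(n))  # n x (degree+1)
  if (!is.matrix(apow)) apow <- matrix(apow, nrow = n)
  if (outcome == "eligibility") {
    # one age polynomial per sex x education cell
    cols <- list(); nms <- character(0)
    for (ei in 1:3) for (si in 1:2) {
      cell <- (s == si & e == ei)
      for (k in 0:degree) {
        cols[[length(cols) + 1L]] <- cell * apow[, k + 1L]
        nms <- c(nms, sprintf("%s:%s:a%d", SEX_LEVELS[si], EDU_LEVELS[ei], k))
      }
    }
    X <- do.call(cbind, cols)
    colnames(X) <- nms
  } else {
    fem <- as.numeric(s == 2L)
    lo <- as.numeric(e == 1L); hi <- as.numeric(e == 3L)
    base <- apow
    colnames(base) <- paste0("a", 0:degree)
    inter <- cbind(female = fem, edu_low = lo, edu_high = hi)
    cols <- list(base)
    for (j in seq_len(ncol(inter))) {
      blk <- apow[, -1L, drop = FALSE] * inter[, j]
      colnames(blk) <- paste0("a", 1:degree, ":", colnames(inter)[j])
      cols[[length(cols) + 1L]] <- blk
    }
    X <- cbind(base, inter, do.call(cbind, cols[-1L]))
  }
  X
}

# Default generating coefficients, expressed directly in the design basis.
# Calibrated to give realistic prevalence of assessed care need 65+:
# roughly 2% any-receipt at 65 rising to ~50-60% above 100, women somewhat
# above men at high ages, a clear low-education excess and a modest
# high-education advantage.
default_eligibility_coefficients <- function(degree = 2) {
  b0 <- -3.9; b_a <- 0.90; b_a2 <- 0.05
  fem0 <- 0.25; fem_a <- 0.05
  edu0 <- c(low = 0.55, medium = 0, high = -0.30)
  edu_a <- c(low = 0.05, medium = 0, high = -0.05)
  beta <- numeric(0)
  for (ei in 1:3) for (si in 1:2) {
    cell <- c(b0 + (si == 2) * fem0 + edu0[ei],
              b_a + (si == 2) * fem_a + edu_a[ei],
              b_a2)
    if (degree > 2) cell <- c(cell, rep(0, degree - 2))
    if (degree < 2) cell <- cell[1:(degree + 1)]
    names(cell) <- sprintf("%s:%s:a%d", SEX_LEVELS[si], EDU_LEVELS[ei],
                           0:degree)
    beta <- c(beta, cell)
  }
  beta
}

default_severity_coefficients <- function(degree = 2) {
  nm <- colnames(logit_design(70, "male", "medium", "severity",
                              degree = degree))
  beta <- stats::setNames(numeric(length(nm)), nm)
  beta["a0"] <- -1.3
  beta["a1"] <- 0.35
  if (degree >= 2) beta["a2"] <- 0.02
  beta["female"] <- 0.10
  beta["edu_low"] <- 0.35
  beta["edu_high"] <- -0.15
  beta["a1:female"] <- 0.05
  beta
}

# Linear predictor under a named coefficient vector in the design basis.
# Infinite coefficients (degenerate limits) dominate wherever their design
# column is active instead of producing 0 * Inf artefacts.
truth_linpred <- function(coefs, age, sex, education, outcome, degree = 2) {
  X <- logit_design(age, sex, education, outcome, degree = degree)
  if (!identical(colnames(X), names(coefs)))
    X <- X[, names(coefs), drop = FALSE]
  fin <- coefs
  inf_j <- which(!is.finite(fin))
  fin[inf_j] <- 0
  lp <- drop(X %*% fin)
  for (j in inf_j) lp[X[, j] != 0] <- coefs[j]
  lp
}

#' Closed-form allowance-level distribution under generating coefficients
#'
#' Computes P(level = 0..7 | age, sex, education) implied by a survey
#' configuration: the eligibility logit gives the probability of assessed
#' need above 65 h, the severity logit splits recipients at 120 h, the
#' band-level splits place respondents into hour buckets, and for hours
#' above 180 the qualitative flags (drawn independently) decide levels
#' 5--7 with the highest satisfied criterion winning; 180+ respondents with
#' no flag fall back to level 4.
#'
#' @param config a [survey_config()].
#' @param age,sex,education scalar or equal-length vectors.
#' @return matrix (n x 8) of probabilities, columns `level0`..`level7`,
#'   rows summing to 1.
#' @export
level_probs_truth <- function(config, age, sex, education) {
  n <- max(length(age), length(sex), length(education))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  education <- rep_len(education, n)
  p_any <- stats::plogis(truth_linpred(config$eligibility_coefficients,
                                       age, sex, education, "eligibility",
                                       config$degree))
  p_sev <- stats::plogis(truth_linpred(config$severity_coefficients,
                                       age, sex, education, "severity",
                                       config$degree))
  lo <- config$level_split$lower; up <- config$level_split$upper
  fp <- config$flag_probs
  ext <- fp[["extraordinary_care"]]
  unc <- fp[["uncoordinated_day_night"]]
  np  <- fp[["no_purposeful_movements"]]
  p180 <- p_any * p_sev * up[3]
  out <- cbind(
    level0 = 1 - p_any,
    level1 = p_any * (1 - p_sev) * lo[1],
    level2 = p_any * (1 - p_sev) * lo[2],
    level3 = p_any * p_sev * up[1],
    level4 = p_any * p_sev * up[2] + p180 * (1 - np) * (1 - unc) * (1 - ext),
    level5 = p180 * (1 - np) * (1 - unc) * ext,
    level6 = p180 * (1 - np) * unc,
    level7 = p180 * np)
  out
}
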