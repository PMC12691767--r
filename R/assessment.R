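#' Benefit rule table for the seven-level care allowance
#'
#' Builds the rule table that drives benefit classification: per level an
#' exclusive lower bound on assessed care hours per month, an optional
#' qualitative criterion, and the monthly cash amount.  The default values
#' are the published 2025 Austrian schedule; any vintage of the schedule can
#' be substituted by passing different payouts or thresholds, which rescales
#' every monetary output of the package accordingly.
#'
#' Levels 1--4 are purely hours-based (more than 65, 95, 120 and 160 hours
#' per month).  Levels 5--7 all sit above 180 hours and are distinguished by
#' qualitative criteria: an extraordinary amount of care, uncoordinated
#' day-and-night care (or permanent presence of a carer), and no purposeful
#' movements of the four extremities.
#'
#' @param min_hours numeric(7), exclusive lower hour bounds per level;
#'   must be non-decreasing.
#' @param required_flag character(7), `"none"` or one of
#'   `r paste0('"', ltca_flags(), '"', collapse = ", ")` per level.
#' @param payout numeric(7), EUR per month, strictly increasing.
#' @return A `data.frame` of class `"ltca_rules"` with columns `level`,
#'   `min_hours`, `required_flag`, `payout`.
#' @examples
#' rules <- ltca_rules()
#' classify_level(80, character(0), rules)   # level 1
#' payout(7, rules)                          # 2156.60
#' @export
ltca_rules <- function(min_hours = c(65, 95, 120, 160, 180, 180, 180),
                       required_flag = c("none", "none", "none", "none",
                                         "extraordinary_care",
                                         "uncoordinated_day_night",
                                         "no_purposeful_movements"),
                       payout = c(200.80, 370.30, 577.00, 865.10,
                                  1175.20, 1641.10, 2156.60)) {
  stopifnot(length(min_hours) == 7L, length(required_flag) == 7L,
            length(payout) == 7L)
  if (is.unsorted(min_hours))
    stop("min_hours must be non-decreasing across levels")
  if (any(diff(payout) <= 0))
    stop("payout must be strictly increasing across levels")
  bad <- setdiff(required_flag, c("none", ltca_flags()))
  if (length(bad))
    stop("unknown required_flag: ", paste(bad, collapse = ", "))
  out <- data.frame(level = 1:7, min_hours = as.numeric(min_hours),
                    required_flag = required_flag,
                    payout = as.numeric(payout))
  class(out) <- c("ltca_rules", "data.frame")
  out
}

#' Qualitative assessment flags
#'
#' The three qualitative criteria that gate allowance levels 5--7.
#' @return character(3) of flag names.
#' @export
ltca_flags <- function() {
  c("extraordinary_care", "uncoordinated_day_night",
    "no_purposeful_movements")
}

#' Total assessed care hours including the dementia premium
#'
#' A dementia diagnosis adds an automatic premium of 40 hours per month to
#' the assessed base need before benefit classification.
#'
#' @param base_hours numeric, assessed base care need in hours/month (>= 0).
#' @param dementia logical, dementia diagnosis.
#' @param premium hours/month added for dementia (default 40).
#' @return numeric, total hours/month entering classification.
#' @examples
#' total_hours(30, dementia = TRUE)  # 70
#' @export
total_hours <- function(base_hours, dementia = FALSE, premium = 40) {
  if (any(base_hours < 0)) stop("base_hours must be non-negative")
  base_hours + ifelse(dementia, premium, 0)
}

#' Classify assessed care need into an allowance level
#'
#' Returns the highest level whose hour bound is strictly exceeded and whose
#' qualitative criterion (levels 5--7) is met; 0 means no benefit.  When
#' several flagged levels qualify (flags are mutually compatible) the
#' highest wins.
#'
#' @param hours numeric, total assessed hours/month (premium included).
#' @param flags character vector of qualitative flags present (possibly
#'   empty), or a list of such vectors when `hours` has length > 1.
#' @param rules an [ltca_rules()] table.
#' @return integer level in 0..7 (vectorised over `hours`).
#' @examples
#' rules <- ltca_rules()
#' classify_level(200, character(0), rules)                  # 4
#' classify_level(200, "no_purposeful_movements", rules)     # 7
#' @export
classify_level <- function(hours, flags = character(0), rules = ltca_rules()) {
  if (any(hours < 0)) stop("hours must be non-negative")
  if (!is.list(flags)) flags <- rep(list(flags), length(hours))
  stopifnot(length(flags) == length(hours))
  bad <- setdiff(unique(unlist(flags)), ltca_flags())
  if (length(bad)) stop("unknown flag: ", paste(bad, collapse = ", "))
  vapply(seq_along(hours), function(i) {
    ok <- hours[i] > rules$min_hours &
      (rules$required_flag == "none" | rules$required_flag %in% flags[[i]])
    if (any(ok)) max(rules$level[ok]) else 0L
  }, integer(1))
}

#' Monthly benefit amount for an allowance level
#'
#' @param level integer in 0..7 (0 = no benefit, vectorised).
#' @param rules an [ltca_rules()] table.
#' @return numeric, EUR per month.
#' @export
payout <- function(level, rules = ltca_rules()) {
  if (any(level < 0 | level > 7 | level != floor(level)))
    stop("level must be an integer in 0..7")
  c(0, rules$payout)[level + 1L]
}

#' Benefit payouts in integer cents
#'
#' Monetary accounting inside the simulation is done in integer cents so
#' yearly totals reconcile with individual cumulative payouts exactly.
#' @param rules an [ltca_rules()] table.
#' @return numeric(8), cents for levels 0..7.
#' @keywords internal
payout_cents <- function(rules = ltca_rules()) {
  round(c(0, rules$payout) * 100)
}
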