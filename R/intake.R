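# Energy accounting from 24-hour recall lines -------------------------------
#
# Turns itemized recall lines plus the composition table and Nova
# assignments into per-child energy summaries and the E4RZ statistic (the
# percent of 24-hour energy from Nova-4 foods), and derives the analysis
# covariates from raw dates and district poverty.

AGE_BREAKS <- c(6, 12, 18, 24, 30, 36)
AGE_LABELS <- c("6-11", "12-17", "18-23", "24-29", "30-35")
POVERTY_BREAKS <- c(0, 15, 20, 40, 90)
POVERTY_LABELS <- c("0-14", "15-19", "20-39", "40-90")
DAYS_PER_MONTH <- 30.4375   # mean Gregorian month length

#' Derive analysis covariates from raw child fields
#'
#' Age in floating months is the difference in days between interview and
#' birth divided by 30.4375; the calendar quarter comes from the interview
#' month; age and poverty bands follow the standard reporting cut points.
#' Children outside the 6-35 month eligibility window are flagged, not
#' dropped: exclusion bookkeeping belongs to the pipeline.
#'
#' @param birth_date,interview_date `Date` vectors (or ISO-8601 strings).
#' @param sex,area passed through.
#' @param poverty_pct district poverty percent in \[0, 100\].
#' @return data.frame with age_months, age_group, poverty_band, quarter,
#'   year and an `eligible` flag.
#' @export
derive_covariates <- function(birth_date, interview_date, sex, area,
                              poverty_pct) {
  birth_date <- as.Date(birth_date)
  interview_date <- as.Date(interview_date)
  if (any(interview_date < birth_date)) {
    stop_upf("interview before birth", class = "upf_covariate_error")
  }
  if (any(poverty_pct < 0 | poverty_pct > 100)) {
    stop_upf("poverty_pct outside [0, 100]", class = "upf_covariate_error")
  }
  age_months <- as.numeric(interview_date - birth_date) / DAYS_PER_MONTH
  eligible <- age_months >= 6 & age_months < 36
  month <- as.integer(format(interview_date, "%m"))
  data.frame(
    age_months = age_months,
    age_group = cut(age_months, AGE_BREAKS, AGE_LABELS, right = FALSE),
    sex = sex, area = area,
    poverty_pct = poverty_pct,
    poverty_band = cut(poverty_pct, POVERTY_BREAKS, POVERTY_LABELS,
                       right = FALSE, include.lowest = TRUE),
    quarter = paste0("Q", (month - 1L) %/% 3L + 1L),
    year = as.integer(format(interview_date, "%Y")),
    eligible = eligible,
    stringsAsFactors = FALSE)
}

#' Add poverty and age bands to a generated children table
#'
#' Convenience for synthetic children (which carry age_months directly).
#' @param children data.frame with age_months and poverty_pct.
#' @return the input with age_group and poverty_band columns added.
#' @export
band_covariates <- function(children) {
  children$age_group <- cut(children$age_months, AGE_BREAKS, AGE_LABELS,
                            right = FALSE)
  children$poverty_band <- cut(children$poverty_pct, POVERTY_BREAKS,
                               POVERTY_LABELS, right = FALSE,
                               include.lowest = TRUE)
  children
}

#' Summarize energy intake per child
#'
#' Computes, for every child, total 24-hour energy, energy per Nova
#' category, the E4RZ share (100 x Nova-4 kcal / total kcal) and the
#' group-by-Nova breakdown.  Record kcal is grams x (kcal per 100 g) / 100
#' from the composition table; records carrying pre-computed kcal are
#' accepted and cross-checked (warning above 2% discrepancy).  Children
#' whose records sum to zero energy are rejected — inclusion requires a
#' recall with recorded energy.
#'
#' @param records data.frame with child_id, food_code, grams and optionally
#'   kcal.
#' @param composition data.frame with food_code, group, kcal_per_100g.
#' @param nova_assignment named integer vector mapping food_code to Nova 1-4.
#' @return data.frame, one row per child: child_id, total_kcal,
#'   kcal_nova1..kcal_nova4, e4rz, plus a `breakdown` attribute holding the
#'   per-child (group, nova) kcal table.
#' @export
summarize_intake <- function(records, composition, nova_assignment) {
  if (nrow(records) == 0L) {
    stop_upf("no recall records", class = "upf_intake_error")
  }
  unknown <- setdiff(records$food_code, composition$food_code)
  if (length(unknown)) {
    stop_upf("food codes missing from composition table: %s",
             paste(utils::head(unknown, 10L), collapse = ", "),
             class = "upf_intake_error")
  }
  if (anyNA(nova_assignment[records$food_code])) {
    bad <- unique(records$food_code[is.na(nova_assignment[records$food_code])])
    stop_upf("food codes without Nova assignment: %s",
             paste(utils::head(bad, 10L), collapse = ", "),
             class = "upf_intake_error")
  }
  dens <- stats::setNames(composition$kcal_per_100g, composition$food_code)
  grp <- stats::setNames(composition$group, composition$food_code)

  kcal_calc <- records$grams * dens[records$food_code] / 100
  if (!is.null(records$kcal) && !all(is.na(records$kcal))) {
    have <- !is.na(records$kcal)
    rel <- abs(records$kcal[have] - kcal_calc[have]) /
      pmax(kcal_calc[have], 1e-9)
    if (any(rel > 0.02 & records$kcal[have] > 1)) {
      warning(sprintf(
        "%d recall lines disagree >2%% with grams x energy density",
        sum(rel > 0.02 & records$kcal[have] > 1)))
    }
    kcal <- ifelse(have, records$kcal, kcal_calc)
  } else {
    kcal <- kcal_calc
  }

  nova <- nova_assignment[records$food_code]
  group <- grp[records$food_code]
  child <- records$child_id

  total <- tapply(kcal, child, sum)
  zero <- names(total)[total <= 0]
  if (length(zero)) {
    stop_upf("children with zero recorded energy: %s",
             paste(utils::head(zero, 10L), collapse = ", "),
             class = "upf_zero_energy_error")
  }
  by_nova <- tapply(kcal, list(child, factor(nova, levels = 1:4)), sum)
  by_nova[is.na(by_nova)] <- 0

  ids <- names(total)
  out <- data.frame(child_id = ids,
                    total_kcal = as.numeric(total),
                    kcal_nova1 = by_nova[ids, 1],
                    kcal_nova2 = by_nova[ids, 2],
                    kcal_nova3 = by_nova[ids, 3],
                    kcal_nova4 = by_nova[ids, 4],
                    stringsAsFactors = FALSE)
  out$e4rz <- 100 * out$kcal_nova4 / out$total_kcal
  rownames(out) <- NULL

  bk <- stats::aggregate(kcal, list(child_id = child, group = group,
                                    nova = nova), sum)
  names(bk)[4] <- "kcal"
  attr(out, "breakdown") <- bk
  out
}

#' Weighted mean percent energy by food group and Nova category
#'
#' Each (group, nova) cell is the weighted mean over children of the cell's
#' percent of that child's total energy; over all cells the table sums to
#' 100 (energy conservation).
#'
#' @param summaries output of [summarize_intake()] (with its breakdown
#'   attribute).
#' @param weights named or aligned numeric vector of survey weights, one per
#'   child in `summaries`.
#' @return data.frame with group, nova, mean_pct.
#' @export
group_nova_breakdown <- function(summaries, weights) {
  if (nrow(summaries) == 0L) {
    stop_upf("no summaries", class = "upf_intake_error")
  }
  bk <- attr(summaries, "breakdown")
  if (is.null(bk)) {
    stop_upf("summaries lack the per-child breakdown attribute",
             class = "upf_intake_error")
  }
  if (is.null(names(weights))) {
    weights <- stats::setNames(weights, summaries$child_id)
  }
  total <- stats::setNames(summaries$total_kcal, summaries$child_id)
  bk$pct <- 100 * bk$kcal / total[bk$child_id]
  bk$w <- weights[bk$child_id]
  cells <- stats::aggregate(cbind(wp = bk$pct * bk$w),
                            list(group = bk$group, nova = bk$nova), sum)
  cells$mean_pct <- cells$wp / sum(weights[summaries$child_id])
  cells[, c("group", "nova", "mean_pct")]
}
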