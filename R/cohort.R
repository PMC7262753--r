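#' Apply study eligibility criteria to a person table
#'
#' A person is included if and only if they are at least 18 years old at the
#' index date, have non-missing sex, region and income quintile, and have a
#' coverage fraction strictly greater than `min_coverage` in every required
#' fiscal year (the "> 75% of days" rule: exactly 0.75 is excluded).
#' Exclusion reasons are assigned with a fixed priority — age, then missing
#' demographics, then coverage — so every excluded person carries exactly one
#' primary reason.
#'
#' @param persons Person table with `person_id`, `age_at_index` (or
#'   `birth_date`, from which completed years at `index_date` are computed),
#'   `sex`, `region_code`, `income_quintile`.
#' @param coverage Long table `person_id`, `fiscal_year`, `fraction`
#'   (fractions in `[0, 1]`).
#' @param index_date Date at which age is evaluated; default 2015-04-01, the
#'   start of the 2015/16 fiscal year.
#' @param required_years Fiscal years in which the coverage rule must hold;
#'   default the three years 2013/14 through 2015/16.
#' @param min_coverage Coverage threshold (strict inequality); default 0.75.
#' @return List of class `cohort_result`: `included` (character vector of
#'   person ids) and `exclusions` (`person_id`, `reason` in
#'   `c("age", "missing_demographics", "coverage")`).
#' @export
apply_eligibility <- function(persons, coverage,
                              index_date = as.Date("2015-04-01"),
                              required_years = c("2013/14", "2014/15",
                                                 "2015/16"),
                              min_coverage = 0.75) {
  if (length(required_years) == 0L) {
    stop("required_years must be nonempty", call. = FALSE)
  }
  if (min_coverage < 0 || min_coverage > 1) {
    stop("min_coverage must be in [0, 1]", call. = FALSE)
  }
  persons <- as.data.table(persons)
  coverage <- as.data.table(coverage)
  missing_years <- setdiff(required_years, unique(coverage$fiscal_year))
  if (length(missing_years)) {
    stop("data error: coverage table lacks required fiscal year(s): ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(persons$person_id)) {
    stop("data error: duplicate person_id in person table", call. = FALSE)
  }

  age <- if ("age_at_index" %in% names(persons)) {
    persons$age_at_index
  } else if ("birth_date" %in% names(persons)) {
    floor(as.numeric(index_date - as.Date(persons$birth_date)) / 365.25)
  } else {
    stop("data error: person table needs age_at_index or birth_date",
         call. = FALSE)
  }

  too_young <- !is.na(age) & age < 18
  demog_missing <- is.na(persons$sex) | is.na(persons$region_code) |
    is.na(persons$income_quintile)

  cov <- coverage[fiscal_year %in% required_years,
                  .(ok = sum(fraction > min_coverage) == length(required_years)),
                  by = person_id]
  cov_ok <- persons$person_id %in% cov[ok == TRUE, person_id]

  reason <- rep(NA_character_, nrow(persons))
  reason[!cov_ok] <- "coverage"
  reason[demog_missing] <- "missing_demographics"
  reason[too_young] <- "age"

  out <- list(
    included = persons$person_id[is.na(reason)],
    exclusions = data.table(person_id = persons$person_id[!is.na(reason)],
                            reason = reason[!is.na(reason)])
  )
  class(out) <- "cohort_result"
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Cohort: ", length(x$included), " included, ",
      nrow(x$exclusions), " excluded\n", sep = "")
  if (nrow(x$exclusions)) {
    print(x$exclusions[, .N, by = reason])
  }
  invisible(x)
}
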