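#' Classify a cohort into four need-based population segments
#'
#' Applies the segment rules to two classification years of event data:
#'
#' 1. **Low need** — at most one chronic condition and no complexity event;
#' 2. **Multiple morbidities** — two or more chronic conditions and no
#'    complexity event;
#' 3. **Medically complex** — at least one chronic condition together with a
#'    complexity event linked to one of the person's detected conditions
#'    (e.g. dialysis counts only among people meeting the chronic kidney
#'    disease definition);
#' 4. **Frail** — aged 65+ and receiving frailty-based care, deemed
#'    palliative, or meeting at least two Edmonton-scale criteria.
#'
#' Precedence is 4 > 3 > 2 > 1 (frail wins over complex, etc.), yielding a
#' mutually exclusive and exhaustive partition of the cohort. Chronic
#' conditions are counted as *distinct* registry conditions whose case
#' definition is satisfied in the window; codes outside the registry never
#' count. The SES stratum dichotomises the income quintile: 1-2 low,
#' 3-5 high.
#'
#' @param events List of event tables (`billings`, `hospital`, ...).
#' @param persons Person table (for age and income quintile).
#' @param registry A [condition_registry()].
#' @param classification_years Two consecutive fiscal years; default
#'   `c("2013/14", "2014/15")`.
#' @param index_date Date at which the frailty age gate (65+) is evaluated.
#' @param cohort_ids Optional character vector restricting classification to
#'   a subset (e.g. the eligible cohort); default all persons.
#' @return `data.table` with one row per person: `person_id`, `segment`
#'   (integer 1-4), `n_chronic_conditions`, `n_chronic_conditions_capped`
#'   (at 5), `ses` (`"low"`/`"high"`), `frailty_criteria_met` (number of
#'   distinct Edmonton criteria observed, reported regardless of the gate).
#' @export
segment_cohort <- function(events, persons, registry = default_registry(),
                           classification_years = c("2013/14", "2014/15"),
                           index_date = as.Date("2015-04-01"),
                           cohort_ids = NULL) {
  if (length(registry$conditions) == 0L) {
    stop("registry configuration error: empty condition registry",
         call. = FALSE)
  }
  persons <- as.data.table(persons)
  if (!is.null(cohort_ids)) persons <- persons[person_id %in% cohort_ids]

  feats <- segment_features(events, registry, classification_years)
  out <- data.table(person_id = persons$person_id)
  set(out, j = "n_chronic_conditions", value = rep(0L, nrow(out)))
  out[feats$conditions[, .(v = .N), by = person_id],
      n_chronic_conditions := i.v, on = "person_id"]
  set(out, j = "complexity",
      value = out$person_id %in% feats$complexity$person_id)
  set(out, j = "frailty_criteria_met", value = rep(0L, nrow(out)))
  if (nrow(feats$edmonton)) {
    out[feats$edmonton[, .(v = uniqueN(criterion)), by = person_id],
        frailty_criteria_met := i.v, on = "person_id"]
  }
  set(out, j = "frail_marker",
      value = out$person_id %in% feats$frailty_flags$person_id)
  age <- persons$age_at_index[match(out$person_id, persons$person_id)]
  frail <- !is.na(age) & age >= 65 &
    (out$frail_marker | out$frailty_criteria_met >= 2L)
  out[, segment := assign_segment(n_chronic_conditions, complexity, frail)]
  out[, n_chronic_conditions_capped := pmin(n_chronic_conditions, 5L)]
  out[, ses := dichotomize_ses(
    persons$income_quintile[match(person_id, persons$person_id)],
    allow_missing = TRUE)]
  out[, c("complexity", "frail_marker") := NULL]
  out[]
}

# Per-person registry features over the classification window. Returns
# tables: conditions (person_id, condition), complexity (person_id,
# event_name), frailty_flags (person_id), edmonton (person_id, criterion).
segment_features <- function(events, registry, classification_years) {
  b <- events$billings[fiscal_year %in% classification_years &
                         !is.na(dx),
                       .(person_id, code = dx, ambulatory,
                         src = "billing")]
  h <- events$hospital[fiscal_year %in% classification_years & !is.na(dx),
                       .(person_id, code = dx, ambulatory = FALSE,
                         src = "hospital")]
  ev <- rbind(b, h)
  ev[, code := normalize_code(code)]
  lut <- registry_match_codes(ev$code, registry)
  hits <- merge(ev, lut, by = "code", allow.cartesian = TRUE)

  cond_hits <- hits[category == "condition"]
  rules <- vapply(registry$conditions, `[[`, character(1), "rule")
  cond <- cond_hits[, .(n_amb = sum(src == "billing" & ambulatory),
                        n_hosp = sum(src == "hospital"),
                        n_any = .N),
                    by = .(person_id, condition = name)]
  cond[, rule := rules[condition]]
  cond <- cond[(rule == "any" & n_any >= 1L) |
                 (rule == "amb2_or_hosp1" & (n_amb >= 2L | n_hosp >= 1L)),
               .(person_id, condition)]

  trig <- unique(hits[category == "complexity",
                      .(person_id, event_name = name)])
  linked <- vapply(registry$complexity_events, `[[`, character(1),
                   "condition")
  trig[, condition := linked[event_name]]
  complexity <- merge(trig, cond, by = c("person_id", "condition"))

  frailty_flags <- unique(hits[category == "frailty", .(person_id)])
  edmonton <- unique(hits[category == "edmonton", .(person_id, criterion)])

  list(conditions = cond, complexity = complexity,
       frailty_flags = frailty_flags, edmonton = edmonton)
}

#' Segment assignment from the three classification flags
#'
#' Total function implementing the precedence 4 (frail) > 3 (complex, which
#' additionally requires at least one chronic condition) > 2 (two or more
#' conditions) > 1.
#'
#' @param n_conditions Nonnegative integer vector of distinct chronic
#'   conditions.
#' @param complexity Logical: linked complexity event present.
#' @param frail Logical: frailty rule met (including the 65+ age gate).
#' @return Integer vector of segments in 1-4.
#' @export
assign_segment <- function(n_conditions, complexity, frail) {
  fifelse(frail, 4L,
          fifelse(complexity & n_conditions >= 1L, 3L,
                  fifelse(n_conditions >= 2L, 2L, 1L)))
}

#' Dichotomise income quintile into SES strata
#'
#' Quintiles 1-2 are low SES, 3-5 high SES.
#'
#' @param income_quintile Integer vector with values 1-5.
#' @param allow_missing If `TRUE`, `NA` quintiles yield `NA` instead of an
#'   error.
#' @return Character vector `"low"`/`"high"`.
#' @export
dichotomize_ses <- function(income_quintile, allow_missing = FALSE) {
  bad <- !is.na(income_quintile) &
    (income_quintile < 1L | income_quintile > 5L)
  if (any(bad)) {
    stop("data error: income quintile out of range 1-5", call. = FALSE)
  }
  if (!allow_missing && anyNA(income_quintile)) {
    stop("data error: missing income quintile", call. = FALSE)
  }
  fifelse(is.na(income_quintile), NA_character_,
          fifelse(income_quintile <= 2L, "low", "high"))
}

#' Single-person segmentation operations
#'
#' Thin per-person wrappers over the vectorised classifier, convenient in
#' tests and spot checks.
#'
#' @param events Event tables.
#' @param persons Person table (for `detect_frailty`).
#' @param registry A [condition_registry()].
#' @param person_id One person identifier.
#' @param classification_years Two fiscal years.
#' @param index_date Date for the frailty age gate.
#' @return `count_chronic_conditions()`: integer. `detect_complexity()`:
#'   logical. `detect_frailty()`: list of `frail` and `criteria_met`.
#' @name person_segmentation
NULL

#' @rdname person_segmentation
#' @export
count_chronic_conditions <- function(events, registry, person_id,
                                     classification_years) {
  if (length(registry$conditions) == 0L) {
    stop("registry configuration error: empty condition registry",
         call. = FALSE)
  }
  id <- person_id
  f <- segment_features(one_person_events(events, id), registry,
                        classification_years)
  nrow(f$conditions)
}

#' @rdname person_segmentation
#' @export
detect_complexity <- function(events, registry, person_id,
                              classification_years) {
  id <- person_id
  f <- segment_features(one_person_events(events, id), registry,
                        classification_years)
  nrow(f$complexity) > 0L
}

#' @rdname person_segmentation
#' @export
detect_frailty <- function(events, persons, registry, person_id,
                           classification_years,
                           index_date = as.Date("2015-04-01")) {
  id <- person_id
  f <- segment_features(one_person_events(events, id), registry,
                        classification_years)
  criteria <- if (nrow(f$edmonton)) uniqueN(f$edmonton$criterion) else 0L
  age <- persons$age_at_index[persons$person_id == id]
  frail <- length(age) == 1L && !is.na(age) && age >= 65 &&
    (nrow(f$frailty_flags) > 0L || criteria >= 2L)
  list(frail = frail, criteria_met = as.integer(criteria))
}
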