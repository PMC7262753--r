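#' Person-level cost, use and primary-care attribute measures
#'
#' Computes, for every person in the cohort, outcome-year cost components
#' (family physician, specialist, inpatient hospital, day surgery, emergency
#' department, prescriptions) and their total; outcome-year utilisation
#' counts (FP visits, hospital separations, ED visits, distinct ATC
#' 4th-level medication classes); and three primary-care attribute measures:
#' out-of-hours access (any FP billing flagged out of hours in the outcome
#' year), the usual-provider-of-care continuity index (UPC: share of
#' ambulatory FP visits over a multi-year window made to the most-visited
#' FP; undefined when the person has no ambulatory FP visits in the window),
#' and coordination (saw fewer than five distinct FPs in ambulatory care in
#' the outcome year).
#'
#' @param events List of event tables as produced by [generate_events()]:
#'   `billings`, `hospital`, `ed`, `dispensing`.
#' @param persons Person table; one metrics row is emitted per person.
#' @param outcome_year Fiscal-year label of the outcome year.
#' @param upc_window Character vector of fiscal years for the continuity
#'   (UPC) window; conventionally the two classification years plus the
#'   outcome year.
#' @param collapse_same_day Count multiple same-day billings to one provider
#'   as a single visit (default `TRUE`).
#' @return A `data.table` keyed by `person_id` with cost, use and attribute
#'   columns (`cost_total` equals the sum of the six components).
#' @export
compute_metrics <- function(events, persons, outcome_year,
                            upc_window, collapse_same_day = TRUE) {
  check_nonnegative_amounts(events)
  base <- data.table(person_id = persons$person_id)
  setkey(base, person_id)

  b <- events$billings
  oy <- b[fiscal_year == outcome_year]
  add <- function(dt, col) {
    set(base, j = col, value = rep(0, nrow(base)))
    if (nrow(dt)) {
      agg <- dt[, .(v = sum(v)), by = person_id]
      base[agg, (col) := i.v, on = "person_id"]
    }
  }
  add(oy[specialty == "FP", .(person_id, v = amount)], "cost_fp")
  add(oy[specialty == "specialist", .(person_id, v = amount)],
      "cost_specialist")
  h <- events$hospital[fiscal_year == outcome_year]
  add(h[type == "inpatient", .(person_id, v = cost)], "cost_hospital")
  add(h[type == "day_surgery", .(person_id, v = cost)], "cost_day_surgery")
  add(events$ed[fiscal_year == outcome_year, .(person_id, v = cost)],
      "cost_ed")
  add(events$dispensing[fiscal_year == outcome_year,
                        .(person_id, v = cost)], "cost_rx")
  base[, cost_total := cost_fp + cost_specialist + cost_hospital +
         cost_day_surgery + cost_ed + cost_rx]

  # use counts
  fpv <- fp_visits(b, outcome_year, ambulatory_only = FALSE,
                   collapse = collapse_same_day)
  addn <- function(dt, col) {
    set(base, j = col, value = rep(0L, nrow(base)))
    if (nrow(dt)) {
      agg <- dt[, .(v = .N), by = person_id]
      base[agg, (col) := i.v, on = "person_id"]
    }
  }
  addn(fpv, "n_fp_visits")
  addn(h[type == "inpatient"], "n_hospital_separations")
  addn(events$ed[fiscal_year == outcome_year], "n_ed_visits")

  disp <- events$dispensing[fiscal_year == outcome_year]
  bad <- is.na(disp$atc) | nchar(disp$atc) < 5L
  if (any(bad)) {
    message(sum(bad), " dispensing row(s) with malformed ATC codes skipped")
    disp <- disp[!bad]
  }
  set(base, j = "n_atc4_classes", value = rep(0L, nrow(base)))
  if (nrow(disp)) {
    agg <- disp[, .(v = uniqueN(substr(atc, 1L, 5L))), by = person_id]
    base[agg, n_atc4_classes := i.v, on = "person_id"]
  }

  # attributes of primary care
  upc_dt <- upc_table(b, upc_window, collapse = collapse_same_day)
  set(base, j = "upc", value = rep(NA_real_, nrow(base)))
  base[upc_dt, upc := i.upc, on = "person_id"]

  acc <- oy[specialty == "FP" & out_of_hours == TRUE, unique(person_id)]
  set(base, j = "access_out_of_hours", value = base$person_id %in% acc)

  amb <- oy[specialty == "FP" & ambulatory == TRUE]
  set(base, j = "n_distinct_fps", value = rep(0L, nrow(base)))
  if (nrow(amb)) {
    agg <- amb[, .(v = uniqueN(provider_id)), by = person_id]
    base[agg, n_distinct_fps := i.v, on = "person_id"]
  }
  base[, coordination_lt5 := n_distinct_fps < 5L]
  base[]
}

# Ambulatory (optionally any-location) FP visits, optionally collapsing
# same-day billings to one provider into a single visit.
fp_visits <- function(billings, years, ambulatory_only = TRUE,
                      collapse = TRUE) {
  v <- billings[specialty == "FP" & fiscal_year %in% years]
  if (ambulatory_only) v <- v[ambulatory == TRUE]
  if (collapse) {
    v <- unique(v[, .(person_id, provider_id, service_date)])
  } else {
    v <- v[, .(person_id, provider_id, service_date)]
  }
  v
}

# Per-person UPC over a window: modal-provider visit share among ambulatory
# FP visits. Persons with zero such visits are absent from the result.
upc_table <- function(billings, window, collapse = TRUE) {
  v <- fp_visits(billings, window, ambulatory_only = TRUE, collapse = collapse)
  if (nrow(v) == 0L) {
    return(data.table(person_id = character(), upc = numeric()))
  }
  pp <- v[, .(n_visits = .N), by = .(person_id, provider_id)]
  pp[, .(upc = max(n_visits) / sum(n_visits)), by = person_id]
}

check_nonnegative_amounts <- function(events) {
  if (nrow(events$billings) && any(events$billings$amount < 0)) {
    stop("data error: negative billing amounts", call. = FALSE)
  }
  if (nrow(events$hospital) && any(events$hospital$cost < 0)) {
    stop("data error: negative hospital costs", call. = FALSE)
  }
  if (nrow(events$ed) && any(events$ed$cost < 0)) {
    stop("data error: negative ED costs", call. = FALSE)
  }
  if (nrow(events$dispensing) && any(events$dispensing$cost < 0)) {
    stop("data error: negative dispensing costs", call. = FALSE)
  }
  invisible(events)
}

#' Single-person metric operations
#'
#' Convenience wrappers computing one measure for one person; the table-level
#' [compute_metrics()] is the workhorse for whole cohorts.
#'
#' @param events,billings Event tables (see [compute_metrics()]).
#' @param person_id A single person identifier.
#' @param outcome_year,window Fiscal-year label(s).
#' @return `compute_costs()`: named list of the six cost components plus
#'   `cost_total`. `compute_use()`: named list of the four use counts.
#'   `compute_upc()`: a number in (0, 1] or `NA` when the person has no
#'   ambulatory FP visits in the window. `compute_access()`: logical.
#'   `compute_coordination()`: list of `coordination_lt5` and
#'   `n_distinct_fps`.
#' @name person_metrics
NULL

one_person_events <- function(events, id) {
  list(billings = events$billings[person_id == id],
       hospital = events$hospital[person_id == id],
       ed = events$ed[person_id == id],
       dispensing = events$dispensing[person_id == id])
}

#' @rdname person_metrics
#' @export
compute_costs <- function(events, person_id, outcome_year) {
  ev <- one_person_events(events, person_id)
  m <- compute_metrics(ev, data.table(person_id = person_id), outcome_year,
                       upc_window = outcome_year)
  as.list(m[, .(cost_fp, cost_specialist, cost_hospital, cost_day_surgery,
                cost_ed, cost_rx, cost_total)])
}

#' @rdname person_metrics
#' @export
compute_use <- function(events, person_id, outcome_year) {
  ev <- one_person_events(events, person_id)
  m <- compute_metrics(ev, data.table(person_id = person_id), outcome_year,
                       upc_window = outcome_year)
  as.list(m[, .(n_fp_visits, n_hospital_separations, n_ed_visits,
                n_atc4_classes)])
}

#' @rdname person_metrics
#' @export
compute_upc <- function(billings, person_id, window) {
  id <- person_id
  dt <- upc_table(as.data.table(billings)[person_id == id], window)
  if (nrow(dt) == 0L) NA_real_ else dt$upc[1L]
}

#' @rdname person_metrics
#' @export
compute_access <- function(billings, person_id, outcome_year) {
  id <- person_id
  nrow(billings[person_id == id & specialty == "FP" &
                  fiscal_year == outcome_year & out_of_hours == TRUE]) > 0L
}

#' @rdname person_metrics
#' @export
compute_coordination <- function(billings, person_id, outcome_year) {
  id <- person_id
  amb <- billings[person_id == id & specialty == "FP" &
                    fiscal_year == outcome_year & ambulatory == TRUE]
  n <- uniqueN(amb$provider_id)
  list(coordination_lt5 = n < 5L, n_distinct_fps = as.integer(n))
}
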