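library(data.table)

empty_events <- function() careseg:::synthetic_empty_tables()

add_billing <- function(events, person, provider = "FP0001",
                        date = "2013-06-01", amount = 50,
                        specialty = "FP", ambulatory = TRUE,
                        out_of_hours = FALSE, dx = NA_character_,
                        location = "office") {
  date <- as.Date(date)
  row <- data.table(person_id = person, provider_id = provider,
                    specialty = specialty, service_date = date,
                    fiscal_year = fy_of_date(date), amount = amount,
                    ambulatory = ambulatory, out_of_hours = out_of_hours,
                    location = location, dx = dx)
  events$billings <- rbind(events$billings, row)
  events
}

add_hospital <- function(events, person, date = "2013-06-01", cost = 0,
                         type = "inpatient", dx = NA_character_) {
  date <- as.Date(date)
  row <- data.table(person_id = person, type = type, sep_date = date,
                    fiscal_year = fy_of_date(date), cost = cost, dx = dx)
  events$hospital <- rbind(events$hospital, row)
  events
}

add_ed <- function(events, person, date = "2015-06-01", cost = 100,
                   dx = NA_character_) {
  date <- as.Date(date)
  row <- data.table(person_id = person, visit_date = date,
                    fiscal_year = fy_of_date(date), cost = cost, dx = dx)
  events$ed <- rbind(events$ed, row)
  events
}

add_dispensing <- function(events, person, date = "2015-06-01",
                           atc = "A10BA02", cost = 25) {
  date <- as.Date(date)
  row <- data.table(person_id = person, disp_date = date,
                    fiscal_year = fy_of_date(date), atc = atc, cost = cost)
  events$dispensing <- rbind(events$dispensing, row)
  events
}

make_persons <- function(ids, age = 50, sex = "female", region = "R01",
                         quintile = 3L) {
  data.table(person_id = ids,
             age_at_index = rep_len(age, length(ids)),
             sex = rep_len(sex, length(ids)),
             region_code = rep_len(region, length(ids)),
             income_quintile = as.integer(rep_len(quintile, length(ids))))
}

make_coverage <- function(ids, years = c("2013/14", "2014/15", "2015/16"),
                          fraction = 0.9) {
  CJ(person_id = ids, fiscal_year = years)[, fraction := fraction][]
}

test_registry <- function() {
  condition_registry(
    conditions = list(
      diabetes = list(codes = c("E11", "250")),
      chf = list(codes = "I50"),
      ckd = list(codes = "N18"),
      hypertension = list(codes = "401", rule = "amb2_or_hosp1")
    ),
    complexity_events = list(
      dialysis = list(codes = "Z49", condition = "ckd")
    ),
    frailty_markers = list(
      frailty_care = "R54",
      palliative = "Z51.5",
      edmonton = list(dementia = "F03", incontinence = "R32",
                      weight_loss = "R63.4")
    )
  )
}

CLS_YEARS <- c("2013/14", "2014/15")
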