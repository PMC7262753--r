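#' Generate a synthetic person table with known true segments
#'
#' Draws demographics conditional on a true (planted) segment for each
#' person: ages from segment-specific age-band mixes (frail persons are
#' always 65+), sex, income quintile via the segment's low-SES probability,
#' a region code, and per-fiscal-year coverage fractions. A configurable
#' fraction of persons is made ineligible (missing quintile or region, or a
#' coverage year at or below 75%) so the eligibility stage has work to do.
#'
#' @param config A [generator_config()].
#' @return A list with `persons` (person_id, age_at_index, sex, region_code,
#'   income_quintile), `coverage` (person_id, fiscal_year, fraction) and
#'   `truth` (person_id, true_segment). Deterministic given `config$seed`.
#' @export
generate_population <- function(config) {
  validate_generator_config(config)
  n <- as.integer(config$n_persons)
  if (n == 0L) {
    return(list(
      persons = data.table(person_id = character(), age_at_index = integer(),
                           sex = character(), region_code = character(),
                           income_quintile = integer()),
      coverage = data.table(person_id = character(), fiscal_year = character(),
                            fraction = numeric()),
      truth = data.table(person_id = character(), true_segment = integer())
    ))
  }
  set.seed(as.integer(config$seed))
  person_id <- sprintf("P%07d", seq_len(n))
  seg <- sample.int(4L, n, replace = TRUE, prob = config$segment_mix)

  # age band within segment, uniform age within band
  band_breaks <- list(c(18L, 44L), c(45L, 64L), c(65L, 74L), c(75L, 94L))
  band <- integer(n)
  u <- runif(n)
  cum <- t(apply(config$age_band_probs, 1L, cumsum))
  for (s in 1:4) {
    i <- seg == s
    band[i] <- findInterval(u[i], cum[s, ], left.open = TRUE) + 1L
  }
  lo <- vapply(band_breaks, `[`, integer(1), 1L)[band]
  hi <- vapply(band_breaks, `[`, integer(1), 2L)[band]
  age <- lo + floor(runif(n) * (hi - lo + 1L))

  sex <- ifelse(runif(n) < config$female_prob_by_segment[seg],
                "female", "male")
  low_ses <- runif(n) < config$ses_low_prob_by_segment[seg]
  quintile <- ifelse(low_ses, 1L + floor(runif(n) * 2),
                     3L + floor(runif(n) * 3))
  region <- sprintf("R%02d", 1L + floor(runif(n) * 16))

  # ineligible sprinkle: 1 = missing quintile, 2 = missing region, 3 = low
  # coverage in the first fiscal year
  inel <- runif(n) < config$ineligible_frac
  inel_type <- ifelse(inel, 1L + floor(runif(n) * 3), 0L)
  quintile[inel_type == 1L] <- NA_integer_
  region[inel_type == 2L] <- NA_character_

  persons <- data.table(person_id = person_id, age_at_index = as.integer(age),
                        sex = sex, region_code = region,
                        income_quintile = as.integer(quintile))

  yrs <- config$fiscal_years
  coverage <- data.table(
    person_id = rep(person_id, each = length(yrs)),
    fiscal_year = rep(yrs, times = n),
    fraction = runif(n * length(yrs), 0.80, 1.0)
  )
  drop_ids <- person_id[inel_type == 3L]
  coverage[person_id %in% drop_ids & fiscal_year == yrs[1L],
           fraction := runif(.N, 0.20, 0.70)]

  truth <- data.table(person_id = person_id, true_segment = seg)
  list(persons = persons, coverage = coverage, truth = truth)
}
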