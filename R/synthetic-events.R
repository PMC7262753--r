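#' Generate linked synthetic event tables with planted ground truth
#'
#' Materialises billing, hospital, emergency-department and dispensing tables
#' for a generated population such that:
#'
#' * re-running the segmentation rules on the event data recovers each
#'   person's true segment exactly (codes are planted deterministically:
#'   segment-2 persons get two or more distinct registry conditions and no
#'   complexity trigger or frailty marker; segment-3 persons get a complexity
#'   trigger plus its linked condition; segment-4 persons get a frailty
#'   marker pattern; "noise" codes outside the registry are sprinkled on
#'   remaining rows and never affect classification);
#' * the outcome-year total cost of each person is drawn from the configured
#'   two-part model (Bernoulli any-cost with logit link; Gamma magnitude with
#'   log link) evaluated at the very covariate values the metrics stage will
#'   compute (age group, sex, capped chronic-condition count, SES, UPC,
#'   coordination, out-of-hours access), so downstream model fits are
#'   parameter-recovery exercises against known truth;
#' * every event is dated within the configured fiscal years.
#'
#' The drawn total is spread over the person's outcome-year events by
#' component (FP, specialist, hospital, day surgery, ED, prescriptions) using
#' the configured component shares, renormalised over the components in
#' which the person actually has events; a person with a positive cost but no
#' outcome-year event receives a single dispensing row carrying the cost.
#'
#' @param persons,truth Tables from [generate_population()].
#' @param config The same [generator_config()].
#' @param registry Condition registry used for planting; defaults to
#'   [default_registry()].
#' @return List with `billings`, `hospital`, `ed`, `dispensing` tables and
#'   `truth`, the input truth augmented with planted condition counts, the
#'   any-cost probability, expected cost and the drawn outcome-year total;
#'   the coefficient maps used are attached as attributes
#'   `part_one_coefficients` / `part_two_coefficients`.
#' @export
generate_events <- function(persons, truth, config,
                            registry = default_registry()) {
  validate_generator_config(config)
  if (!setequal(persons$person_id, truth$person_id) ||
      nrow(persons) != nrow(truth)) {
    stop("linkage error: persons and truth tables do not match",
         call. = FALSE)
  }
  n <- nrow(persons)
  empty <- synthetic_empty_tables()
  if (n == 0L) {
    return(c(empty, list(truth = data.table(
      person_id = character(), true_segment = integer(),
      n_conditions = integer(), p_any_cost = numeric(),
      expected_cost = numeric(), total_cost = numeric()))))
  }
  set.seed((as.integer(config$seed) + 1L) %% 2147483647L)

  truth <- merge(data.table(person_id = persons$person_id),
                 truth, by = "person_id", sort = FALSE)
  seg <- truth$true_segment
  yrs <- config$fiscal_years
  cls_yrs <- classification_years(config)
  oy <- outcome_year(config)

  noise_pool <- synthetic_noise_codes(registry)

  ## ---- plant chronic conditions, complexity events, frailty markers ----
  cond_names <- names(registry$conditions)
  K <- length(cond_names)
  ncond <- integer(n)
  ncond[seg == 1L] <- rbinom(sum(seg == 1L), 1L, 0.27)
  ncond[seg == 2L] <- 2L + pmin(rpois(sum(seg == 2L), 0.5), min(3L, K - 2L))
  ncond[seg == 3L] <- 1L + pmin(rpois(sum(seg == 3L), 1.5), min(4L, K - 1L))
  ncond[seg == 4L] <- pmin(rpois(sum(seg == 4L), 2.8), min(5L, K))

  ev_names <- names(registry$complexity_events)
  if (length(ev_names) == 0L && any(seg == 3L)) {
    stop("generator error: cannot plant segment 3 without complexity events",
         call. = FALSE)
  }
  fm <- registry$frailty_markers
  if (any(seg == 4L) && length(fm$frailty_care) == 0L &&
      length(fm$palliative) == 0L && length(fm$edmonton) < 2L) {
    stop("generator error: cannot plant the frail segment without ",
         "frailty markers in the registry", call. = FALSE)
  }
  ev_pick <- sample.int(max(1L, length(ev_names)), n, replace = TRUE)
  linked_idx <- if (length(ev_names)) {
    match(vapply(registry$complexity_events, `[[`, character(1), "condition"),
          cond_names)[ev_pick]
  } else rep(NA_integer_, n)

  # distinct-condition selection: iteratively take the argmax of a random
  # matrix; segment 3's linked condition is forced to be selected first
  R <- matrix(runif(n * K), n, K)
  force3 <- which(seg == 3L)
  R[cbind(force3, linked_idx[force3])] <- 2
  sel <- matrix(FALSE, n, K)
  for (j in seq_len(min(max(ncond), K))) {
    top <- max.col(R, ties.method = "first")
    take <- ncond >= j
    sel[cbind(which(take), top[take])] <- TRUE
    R[cbind(seq_len(n), top)] <- -1
  }

  frail_type <- sample(c("frailty_care", "palliative", "edmonton"), n,
                       replace = TRUE)
  edm_names <- names(registry$frailty_markers$edmonton)

  needed <- plant_code_table(seg, sel, ncond, ev_pick, frail_type, edm_names,
                             registry, cond_names)

  ## ---- family-physician and specialist billing rows ----
  no_fp <- runif(n) < config$no_fp_frac[seg]
  usual <- sprintf("FP%04d", sample.int(config$n_providers, n, replace = TRUE))
  vis_rate <- ifelse(no_fp, 0, config$fp_visit_rate[seg])
  nvis <- matrix(rpois(n * length(yrs), rep(vis_rate, length(yrs))),
                 n, length(yrs))
  bill <- data.table(
    pidx = rep(rep(seq_len(n), length(yrs)), as.vector(nvis)),
    fiscal_year = rep(rep(yrs, each = n), as.vector(nvis))
  )
  if (nrow(bill)) {
    use_usual <- runif(nrow(bill)) < config$p_usual[seg[bill$pidx]]
    # non-usual visits go to a small person-specific secondary pool (walk-in
    # style), keeping the yearly distinct-FP count realistic
    usual_idx <- as.integer(substr(usual, 3L, 6L))
    shift <- 1L + floor(runif(nrow(bill)) * 5)
    alt <- sprintf("FP%04d",
                   ((usual_idx[bill$pidx] - 1L + shift) %%
                      config$n_providers) + 1L)
    bill[, provider_id := ifelse(use_usual, usual[pidx], alt)]
    bill[, specialty := "FP"]
  } else {
    bill[, `:=`(provider_id = character(), specialty = character())]
  }

  nspec <- matrix(rpois(n * length(yrs),
                        rep(config$specialist_rate[seg], length(yrs))),
                  n, length(yrs))
  spec <- data.table(
    pidx = rep(rep(seq_len(n), length(yrs)), as.vector(nspec)),
    fiscal_year = rep(rep(yrs, each = n), as.vector(nspec))
  )
  if (nrow(spec)) {
    spec[, provider_id := sprintf("SP%03d", sample.int(200L, .N,
                                                       replace = TRUE))]
    spec[, specialty := "specialist"]
  } else {
    spec[, `:=`(provider_id = character(), specialty = character())]
  }
  billings <- rbind(bill, spec)
  billings[, service_date := fy_random_date(fiscal_year)]
  billings[, `:=`(ambulatory = specialty == "FP", out_of_hours = FALSE,
                  location = "office", dx = NA_character_)]
  # classification-year amounts: ordinary fee-for-service dollars (outcome
  # year amounts are set by the cost-allocation step below)
  billings[, amount := 0]
  billings[fiscal_year != oy,
           amount := round(rgamma(.N, shape = 4, scale = 12), 2)]

  ## ---- attach planted codes to classification-year carrier rows ----
  if (nrow(needed)) {
    setorder(billings, pidx, fiscal_year, service_date, provider_id)
    billings[, visit_id := .I]
    carriers <- billings[fiscal_year %in% cls_yrs,
                         .(visit_id, seq = seq_len(.N)), by = pidx]
    needed[, seq := seq_len(.N), by = pidx]
    hit <- merge(needed, carriers, by = c("pidx", "seq"))
    billings[hit$visit_id, dx := hit$code]
    missed <- needed[!carriers, on = c("pidx", "seq")]
    if (nrow(missed)) {
      extra <- data.table(
        pidx = missed$pidx, fiscal_year = cls_yrs[1L],
        provider_id = sprintf("SP%03d",
                              sample.int(200L, nrow(missed), replace = TRUE)),
        specialty = "specialist",
        service_date = fy_random_date(rep(cls_yrs[1L], nrow(missed))),
        ambulatory = FALSE, out_of_hours = FALSE, location = "other",
        dx = missed$code,
        amount = round(rgamma(nrow(missed), shape = 4, scale = 12), 2),
        visit_id = 0L
      )
      billings <- rbind(billings, extra)
    }
    billings[, visit_id := NULL]
  }
  # noise codes outside the registry on a share of the remaining rows
  blank <- which(is.na(billings$dx))
  noisy <- blank[runif(length(blank)) < config$noise_code_rate]
  billings[noisy, dx := sample(noise_pool, length(noisy), replace = TRUE)]

  ## ---- out-of-hours access flags (one outcome-year FP row per winner) ----
  oyfp <- billings[, .I[fiscal_year == oy & specialty == "FP"]]
  if (length(oyfp)) {
    cand <- data.table(row = oyfp, pidx = billings$pidx[oyfp])
    first <- cand[, .(row = row[1L]), by = pidx]
    winners <- first[runif(.N) < config$access_prob[seg[pidx]]]
    if (nrow(winners)) billings[winners$row, out_of_hours := TRUE]
  }

  ## ---- hospital / day surgery / ED / dispensing rows (outcome year) ----
  nh <- rpois(n, config$hospital_rate[seg])
  nds <- rpois(n, config$day_surgery_rate[seg])
  hospital <- data.table(
    pidx = c(rep(seq_len(n), nh), rep(seq_len(n), nds)),
    type = c(rep("inpatient", sum(nh)), rep("day_surgery", sum(nds)))
  )
  hospital[, fiscal_year := oy]
  hospital[, sep_date := fy_random_date(rep(oy, .N))]
  hospital[, cost := 0]
  hospital[, dx := sample(noise_pool, .N, replace = TRUE)]

  ned <- rpois(n, config$ed_rate[seg])
  ed <- data.table(pidx = rep(seq_len(n), ned), fiscal_year = oy)
  ed[, visit_date := fy_random_date(rep(oy, .N))]
  ed[, cost := 0]
  ed[, dx := sample(noise_pool, .N, replace = TRUE)]

  atc_pool <- synthetic_atc_pool()
  natc <- rpois(n, config$atc_rate[seg])
  dispensing <- data.table(pidx = rep(seq_len(n), natc), fiscal_year = oy)
  dispensing[, disp_date := fy_random_date(rep(oy, .N))]
  dispensing[, atc := sample(atc_pool, .N, replace = TRUE)]
  dispensing[, cost := 0]

  ## ---- draw outcome-year totals from the two-part model ----
  X <- data.table(
    pidx = seq_len(n),
    segment = seg,
    age_group = age_group_of(persons$age_at_index),
    sex = persons$sex,
    n_chronic_capped = pmin(ncond, 5L),
    ses = dichotomize_ses(persons$income_quintile, allow_missing = TRUE)
  )
  upc_src <- billings[specialty == "FP" & ambulatory == TRUE,
                      .(person_id = pidx, provider_id, service_date,
                        fiscal_year, specialty, ambulatory)]
  upcs <- upc_table(upc_src, yrs)
  set(X, j = "upc", value = rep(NA_real_, nrow(X)))
  X[upcs, upc := i.upc, on = c(pidx = "person_id")]
  X[, access_out_of_hours := pidx %in% billings[out_of_hours == TRUE, pidx]]
  ndfp <- billings[specialty == "FP" & ambulatory == TRUE & fiscal_year == oy,
                   .(nd = uniqueN(provider_id)), by = pidx]
  set(X, j = "n_distinct_fps", value = rep(0L, nrow(X)))
  X[ndfp, n_distinct_fps := i.nd, on = "pidx"]
  X[, coordination_lt5 := n_distinct_fps < 5L]

  lp1 <- two_part_linpred(X, config$part_one_coefficients, part = "one")
  p1 <- plogis(lp1)
  any_cost <- rbinom(n, 1L, p1) == 1L
  lp2 <- log(config$base_cost) +
    two_part_linpred(X, config$part_two_coefficients, part = "two")
  mu <- exp(lp2)
  total <- numeric(n)
  total[any_cost] <- rgamma(sum(any_cost), shape = config$gamma_shape,
                            scale = mu[any_cost] / config$gamma_shape)

  ## ---- allocate totals over outcome-year events by component ----
  cnt <- function(dt, cond = rep(TRUE, nrow(dt))) {
    out <- integer(n)
    if (nrow(dt)) {
      t <- dt[cond, .N, by = pidx]
      out[t$pidx] <- t$N
    }
    out
  }
  m_fp <- cnt(billings, billings$fiscal_year == oy &
                billings$specialty == "FP")
  m_sp <- cnt(billings, billings$fiscal_year == oy &
                billings$specialty == "specialist")
  m_ho <- cnt(hospital, hospital$type == "inpatient")
  m_ds <- cnt(hospital, hospital$type == "day_surgery")
  m_ed <- cnt(ed)
  m_rx <- cnt(dispensing)

  # positive-cost persons with no outcome-year event: one dispensing row
  orphan <- which(total > 0 & (m_fp + m_sp + m_ho + m_ds + m_ed + m_rx) == 0L)
  if (length(orphan)) {
    dispensing <- rbind(dispensing, data.table(
      pidx = orphan, fiscal_year = oy,
      disp_date = fy_start(oy) + 182L,
      atc = atc_pool[1L], cost = 0))
    m_rx[orphan] <- 1L
  }

  counts <- cbind(fp = m_fp, specialist = m_sp, hospital = m_ho,
                  day_surgery = m_ds, ed = m_ed, rx = m_rx)
  w <- config$component_shares[seg, , drop = FALSE] * (counts > 0L)
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  comp <- w / rs * total

  per_row <- comp / pmax(counts, 1L)
  billings[fiscal_year == oy & specialty == "FP",
           amount := per_row[pidx, "fp"]]
  billings[fiscal_year == oy & specialty == "specialist",
           amount := per_row[pidx, "specialist"]]
  hospital[type == "inpatient", cost := per_row[pidx, "hospital"]]
  hospital[type == "day_surgery", cost := per_row[pidx, "day_surgery"]]
  ed[, cost := per_row[pidx, "ed"]]
  dispensing[, cost := per_row[pidx, "rx"]]

  ## ---- finalise ----
  id <- persons$person_id
  billings[, person_id := id[pidx]]
  hospital[, person_id := id[pidx]]
  ed[, person_id := id[pidx]]
  dispensing[, person_id := id[pidx]]
  billings <- billings[, .(person_id, provider_id, specialty, service_date,
                           fiscal_year, amount, ambulatory, out_of_hours,
                           location, dx)]
  setorder(billings, person_id, service_date, provider_id, specialty)
  hospital <- hospital[, .(person_id, type, sep_date, fiscal_year, cost, dx)]
  setorder(hospital, person_id, sep_date, type)
  ed <- ed[, .(person_id, visit_date, fiscal_year, cost, dx)]
  setorder(ed, person_id, visit_date)
  dispensing <- dispensing[, .(person_id, disp_date, fiscal_year, atc, cost)]
  setorder(dispensing, person_id, disp_date, atc)

  truth <- data.table(person_id = id, true_segment = seg,
                      n_conditions = ncond, p_any_cost = p1,
                      expected_cost = p1 * mu, total_cost = total)
  setattr(truth, "part_one_coefficients", config$part_one_coefficients)
  setattr(truth, "part_two_coefficients", config$part_two_coefficients)
  list(billings = billings, hospital = hospital, ed = ed,
       dispensing = dispensing, truth = truth)
}

# Long table of codes that must appear in the classification window for each
# person, in planting priority order (conditions, then the complexity
# trigger, then frailty markers).
plant_code_table <- function(seg, sel, ncond, ev_pick, frail_type, edm_names,
                             registry, cond_names) {
  pieces <- list()
  for (k in seq_along(cond_names)) {
    who <- which(sel[, k])
    if (length(who)) {
      pieces[[length(pieces) + 1L]] <- data.table(
        pidx = who, code = registry$conditions[[k]]$codes[1L], prio = 1L)
    }
  }
  ev_names <- names(registry$complexity_events)
  who3 <- which(seg == 3L)
  if (length(who3) && length(ev_names)) {
    trig <- vapply(registry$complexity_events, function(e) e$codes[1L],
                   character(1))
    pieces[[length(pieces) + 1L]] <- data.table(
      pidx = who3, code = trig[ev_pick[who3]], prio = 2L)
  }
  who4 <- which(seg == 4L)
  if (length(who4)) {
    fc <- who4[frail_type[who4] == "frailty_care"]
    pa <- who4[frail_type[who4] == "palliative"]
    em <- who4[frail_type[who4] == "edmonton"]
    if (length(registry$frailty_markers$frailty_care) == 0L) {
      pa <- c(pa, fc); fc <- integer()
    }
    if (length(fc)) {
      pieces[[length(pieces) + 1L]] <- data.table(
        pidx = fc, code = registry$frailty_markers$frailty_care[1L],
        prio = 3L)
    }
    if (length(pa)) {
      pieces[[length(pieces) + 1L]] <- data.table(
        pidx = pa, code = registry$frailty_markers$palliative[1L], prio = 3L)
    }
    if (length(em) && length(edm_names) >= 2L) {
      c1 <- sample.int(length(edm_names), length(em), replace = TRUE)
      shift <- 1L + floor(runif(length(em)) * (length(edm_names) - 1L))
      c2 <- ((c1 - 1L + shift) %% length(edm_names)) + 1L
      ed_codes <- vapply(registry$frailty_markers$edmonton,
                         `[`, character(1), 1L)
      pieces[[length(pieces) + 1L]] <- data.table(
        pidx = c(em, em), code = c(ed_codes[c1], ed_codes[c2]), prio = 3L)
    } else if (length(em)) {
      # registry without two Edmonton criteria: fall back to palliative
      pieces[[length(pieces) + 1L]] <- data.table(
        pidx = em, code = registry$frailty_markers$palliative[1L], prio = 3L)
    }
  }
  if (length(pieces) == 0L) {
    return(data.table(pidx = integer(), code = character(), prio = integer()))
  }
  out <- rbindlist(pieces)
  setorder(out, pidx, prio, code)
  out
}

synthetic_noise_codes <- function(registry) {
  pool <- c("J06", "M54", "K21", "H10", "L20", "B34", "A09", "T14",
            "S52", "G43", "780", "719")
  reg <- registry_all_codes(registry)
  clash <- vapply(pool, function(cd) any(startsWith(cd, reg)) ||
                    any(startsWith(reg, cd)), logical(1))
  pool <- pool[!clash]
  if (length(pool) == 0L) {
    stop("generator error: no noise codes disjoint from the registry",
         call. = FALSE)
  }
  pool
}

synthetic_atc_pool <- function() {
  c("A02BC01", "A10BA02", "A10BB01", "C03CA01", "C07AB02", "C09AA05",
    "C10AA01", "J01CA04", "M01AE01", "N02BE01", "N05BA04", "N06AB03",
    "R03AC02", "R06AE07", "B01AC06", "H03AA01", "L04AB01", "P01BA02",
    "D07AC01", "G03CA03", "S01ED01", "V03AE01", "A12AA04", "C08CA01")
}

synthetic_empty_tables <- function() {
  list(
    billings = data.table(person_id = character(), provider_id = character(),
                          specialty = character(), service_date = as.Date(character()),
                          fiscal_year = character(), amount = numeric(),
                          ambulatory = logical(), out_of_hours = logical(),
                          location = character(), dx = character()),
    hospital = data.table(person_id = character(), type = character(),
                          sep_date = as.Date(character()),
                          fiscal_year = character(), cost = numeric(),
                          dx = character()),
    ed = data.table(person_id = character(), visit_date = as.Date(character()),
                    fiscal_year = character(), cost = numeric(),
                    dx = character()),
    dispensing = data.table(person_id = character(),
                            disp_date = as.Date(character()),
                            fiscal_year = character(), atc = character(),
                            cost = numeric())
  )
}

#' Run the full generator and optionally write the tables as CSV
#'
#' @param config A [generator_config()].
#' @param registry Condition registry for planting.
#' @param dir If non-`NULL`, the seven tables (persons, coverage, billings,
#'   hospital, ed, dispensing, truth) are written there as CSV.
#' @return List with `persons`, `coverage`, `truth` and the four event
#'   tables.
#' @export
generate_synthetic_data <- function(config, registry = default_registry(),
                                    dir = NULL) {
  pop <- generate_population(config)
  ev <- generate_events(pop$persons, pop$truth, config, registry)
  out <- list(persons = pop$persons, coverage = pop$coverage,
              truth = ev$truth, billings = ev$billings,
              hospital = ev$hospital, ed = ev$ed,
              dispensing = ev$dispensing)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      fwrite(out[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  out
}

# Age bands used throughout reporting and modelling.
age_group_of <- function(age) {
  cut(age, breaks = c(-Inf, 44, 64, 74, Inf),
      labels = c("18-44", "45-64", "65-74", "75+"))
}

# Shared linear predictor over the model covariates; part "one" ignores the
# three primary-care attribute covariates, part "two" includes them.
# Missing coefficient names contribute zero.
two_part_linpred <- function(dt, coefs, part = c("one", "two")) {
  part <- match.arg(part)
  g <- function(nm) if (nm %in% names(coefs)) unname(coefs[[nm]]) else 0
  ag <- as.character(dt$age_group)
  lp <- rep(g("intercept"), nrow(dt)) +
    g("age_18_44") * (ag == "18-44") +
    g("age_45_64") * (ag == "45-64") +
    g("age_75p") * (ag == "75+") +
    g("sex_female") * (dt$sex == "female") +
    g("n_chronic") * dt$n_chronic_capped +
    g("ses_low") * (!is.na(dt$ses) & dt$ses == "low") +
    g("seg2") * (dt$segment == 2L) +
    g("seg3") * (dt$segment == 3L) +
    g("seg4") * (dt$segment == 4L)
  if (part == "two") {
    u <- dt$upc
    u[is.na(u)] <- 0
    lp <- lp + g("upc") * u +
      g("coordination_lt5") * dt$coordination_lt5 +
      g("access") * dt$access_out_of_hours
  }
  lp
}
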