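#' Assemble publication-shaped report tables
#'
#' Builds the five exhibit objects of a segmentation analysis:
#'
#' * `table2` — cohort characteristics by segment and SES stratum (counts,
#'   percent female, age-band distribution, mean and SD of chronic
#'   conditions);
#' * `table3` — mean cost components, use counts and primary-care attribute
#'   measures by segment and SES;
#' * `table4` / `table5` — part-one odds-ratio and part-two cost-ratio
#'   tables per segment;
#' * `fig1` / `fig2` — per-provider panel and billing segment shares, sorted
#'   by descending low-need share for stacked-distribution plotting.
#'
#' Segments with zero persons appear as explicit zero/`NA` columns rather
#' than being dropped; segment order is fixed 1 through 4.
#'
#' @param segments Output of [segment_cohort()] (cohort members only).
#' @param persons Person table.
#' @param metrics Output of [compute_metrics()].
#' @param fits Output of [fit_all_segments()], or `NULL` to skip
#'   table4/table5.
#' @param panel_comp Output of [panel_composition()], or `NULL`.
#' @param billing_comp Output of [billing_composition()], or `NULL`.
#' @return List of class `report_bundle`.
#' @export
build_reports <- function(segments, persons, metrics, fits = NULL,
                          panel_comp = NULL, billing_comp = NULL) {
  segments <- as.data.table(segments)
  persons <- as.data.table(persons)
  metrics <- as.data.table(metrics)

  d <- merge(segments, persons, by = "person_id")
  d[, age_group := age_group_of(age_at_index)]
  strata <- function(dt, f) {
    rbind(dt[, f(.SD), by = .(segment)][, stratum := "overall"],
          dt[!is.na(ses), f(.SD), by = .(segment, stratum = ses)],
          fill = TRUE)
  }
  t2 <- strata(d, function(sd) {
    data.table(
      n = nrow(sd),
      pct_female = 100 * mean(sd$sex == "female"),
      pct_age_18_44 = 100 * mean(sd$age_group == "18-44"),
      pct_age_45_64 = 100 * mean(sd$age_group == "45-64"),
      pct_age_65_74 = 100 * mean(sd$age_group == "65-74"),
      pct_age_75p = 100 * mean(sd$age_group == "75+"),
      mean_chronic = mean(sd$n_chronic_conditions),
      sd_chronic = stats::sd(sd$n_chronic_conditions)
    )
  })
  t2 <- pad_segments(t2)

  m <- merge(metrics, segments[, .(person_id, segment, ses)],
             by = "person_id")
  t3 <- strata(m, function(sd) {
    data.table(
      n = nrow(sd),
      mean_cost_fp = mean(sd$cost_fp),
      mean_cost_specialist = mean(sd$cost_specialist),
      mean_cost_hospital = mean(sd$cost_hospital),
      mean_cost_day_surgery = mean(sd$cost_day_surgery),
      mean_cost_ed = mean(sd$cost_ed),
      mean_cost_rx = mean(sd$cost_rx),
      mean_cost_total = mean(sd$cost_total),
      mean_fp_visits = mean(sd$n_fp_visits),
      hospital_separations_per_100 = 100 * mean(sd$n_hospital_separations),
      ed_visits_per_100 = 100 * mean(sd$n_ed_visits),
      mean_atc4_classes = mean(sd$n_atc4_classes),
      pct_access_out_of_hours = 100 * mean(sd$access_out_of_hours),
      mean_upc = mean(sd$upc, na.rm = TRUE),
      pct_seeing_lt5_fps = 100 * mean(sd$coordination_lt5)
    )
  })
  t3 <- pad_segments(t3)

  ratio_table <- function(which_part) {
    if (is.null(fits)) return(NULL)
    rbindlist(lapply(names(fits), function(nm) {
      pf <- fits[[nm]][[which_part]]
      cbind(data.table(segment = pf$segment, n = pf$n), pf$estimates)
    }))
  }
  t4 <- ratio_table("part_one")
  t5 <- ratio_table("part_two")

  sort_fig <- function(comp) {
    if (is.null(comp)) return(NULL)
    comp <- copy(as.data.table(comp))
    setorder(comp, -share_seg1, provider_id)
    comp[]
  }

  out <- list(table2 = t2, table3 = t3, table4 = t4, table5 = t5,
              fig1 = sort_fig(panel_comp), fig2 = sort_fig(billing_comp))
  class(out) <- "report_bundle"
  out
}

# ensure all four segments appear in a by-segment summary, as explicit
# zero/NA rows, ordered segment then stratum
pad_segments <- function(t) {
  have <- unique(t[, .(segment, stratum)])
  want <- CJ(segment = 1:4, stratum = c("overall", "high", "low"))
  miss <- want[!have, on = c("segment", "stratum")]
  if (nrow(miss)) {
    miss[, n := 0L]
    t <- rbind(t, miss, fill = TRUE)
  }
  t[, stratum := factor(stratum, levels = c("overall", "high", "low"))]
  setorder(t, segment, stratum)
  t[]
}

#' Run the whole pipeline on synthetic data
#'
#' Generates a synthetic population and its event tables, applies
#' eligibility, classifies the cohort into segments, attributes panels,
#' computes metrics, truncates costs, fits the segment-stratified two-part
#' models, and assembles the report bundle. Fully deterministic given the
#' configuration seed; logs row counts per stage via messages.
#'
#' @param config A [generator_config()].
#' @param registry Condition registry.
#' @param fit_models Fit the two-part models (default `TRUE`; skipping them
#'   is useful when only descriptive outputs are needed).
#' @param sensitivity Also run the categorical-chronic sensitivity fits.
#' @return List of class `pipeline_result` with every intermediate object
#'   (`data`, `cohort`, `segments`, `panel`, `panel_comp`, `billing_comp`,
#'   `metrics`, `model_data`, `fits`, `reports`, `log`).
#' @export
run_pipeline <- function(config, registry = default_registry(),
                         fit_models = TRUE, sensitivity = FALSE) {
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dat <- stage("synthetic_data", generate_synthetic_data(config, registry))
  cls_yrs <- classification_years(config)
  oy <- outcome_year(config)
  idx <- index_date(config)

  cohort <- stage("cohort", apply_eligibility(
    dat$persons, dat$coverage, index_date = idx,
    required_years = config$fiscal_years))
  seg <- stage("segmentation", segment_cohort(
    dat, dat$persons, registry, classification_years = cls_yrs,
    index_date = idx, cohort_ids = cohort$included))
  panel <- stage("attribution", assign_panel(
    dat$billings, window = config$fiscal_years,
    person_ids = cohort$included))
  pcomp <- stage("attribution", panel_composition(panel, seg))
  bcomp <- stage("attribution", suppressMessages(
    billing_composition(dat$billings, seg, fiscal_years = oy)))
  met <- stage("metrics", compute_metrics(
    dat, dat$persons[person_id %in% cohort$included], oy,
    upc_window = config$fiscal_years))

  fits <- NULL
  md <- NULL
  if (fit_models) {
    md <- stage("cost_model", prepare_model_data(met, seg, dat$persons))
    md <- stage("cost_model", suppressMessages(truncate_costs(md)))
    fits <- stage("cost_model", fit_all_segments(md,
                                                 sensitivity = sensitivity))
  }
  reports <- stage("reporting", build_reports(
    seg, dat$persons, met, fits, pcomp, bcomp))

  log <- data.table(
    stage = c("persons", "included", "segments", "panel_assigned",
              "metrics_rows", "model_rows"),
    rows = c(nrow(dat$persons), length(cohort$included), nrow(seg),
             sum(!is.na(panel$provider_id)), nrow(met),
             if (is.null(md)) NA_integer_ else nrow(md))
  )
  out <- list(data = dat, cohort = cohort, segments = seg, panel = panel,
              panel_comp = pcomp, billing_comp = bcomp, metrics = met,
              model_data = md, fits = fits, reports = reports, log = log)
  class(out) <- "pipeline_result"
  out
}

#' Write a report bundle as deterministic CSV files
#'
#' One CSV per exhibit (`table2.csv`, `table3.csv`, `table4.csv`,
#' `table5.csv`, `fig1_panel_shares.csv`, `fig2_billing_shares.csv`).
#' Reruns with the same seed and configuration produce byte-identical
#' files.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(table2 = "table2.csv", table3 = "table3.csv",
             table4 = "table4.csv", table5 = "table5.csv",
             fig1 = "fig1_panel_shares.csv", fig2 = "fig2_billing_shares.csv")
  paths <- character()
  for (nm in names(files)) {
    if (is.null(bundle[[nm]])) next
    p <- file.path(dir, files[[nm]])
    fwrite(bundle[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
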