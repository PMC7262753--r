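#!/usr/bin/env Rscript
# Stage 4 — compute outcome-year (2015/16) costs by component, use counts,
# and the three primary-care attribute measures (out-of-hours access,
# usual-provider continuity over three years, coordination) for every
# cohort member.

suppressPackageStartupMessages({
  library(careseg)
  library(data.table)
})

dirs <- "results/synthetic"
events <- list(billings = fread(file.path(dirs, "billings.csv")),
               hospital = fread(file.path(dirs, "hospital.csv")),
               ed = fread(file.path(dirs, "ed.csv")),
               dispensing = fread(file.path(dirs, "dispensing.csv")))
persons <- fread(file.path(dirs, "persons.csv"))
cohort <- fread("results/cohort_included.csv")
segments <- fread("results/segments.csv")

metrics <- compute_metrics(events, persons[person_id %in% cohort$person_id],
                           outcome_year = "2015/16",
                           upc_window = c("2013/14", "2014/15", "2015/16"))
fwrite(metrics, "results/metrics.csv")

msum <- merge(metrics, segments[, .(person_id, segment)], by = "person_id")[
  , .(mean_total_cost = round(mean(cost_total)),
      mean_fp_visits = round(mean(n_fp_visits), 1),
      mean_upc = round(mean(upc, na.rm = TRUE), 2),
      pct_access = round(100 * mean(access_out_of_hours), 1),
      pct_lt5_fps = round(100 * mean(coordination_lt5), 1)),
  by = segment][order(segment)]
cat("Cost/use/attribute summary by segment:\n")
print(msum)
cat("Persons with undefined continuity (no FP visits in 3 years):",
    sum(is.na(metrics$upc)), "\n")
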