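win3 <- c("2013/14", "2014/15", "2015/16")

panel_of <- function(ev, person = "A") {
  assign_panel(ev$billings, window = win3, person_ids = person)
}

test_that("plurality of ambulatory visits wins, with the documented tie cascade", {
  # A: 5 visits beats B: 3 visits
  ev <- empty_events()
  for (i in 1:5) ev <- add_billing(ev, "A", "FPa", sprintf("2013-05-%02d", i))
  for (i in 1:3) ev <- add_billing(ev, "A", "FPb", sprintf("2013-06-%02d", i))
  r <- panel_of(ev)
  expect_identical(r$provider_id, "FPa")
  expect_identical(r$n_visits_to_assigned, 5L)
  expect_identical(r$tie_break_used, "none")

  # tie on visits -> higher summed ambulatory billings
  ev <- empty_events()
  for (i in 1:4) ev <- add_billing(ev, "A", "FPa", sprintf("2013-05-%02d", i),
                                   amount = 100)
  for (i in 1:4) ev <- add_billing(ev, "A", "FPb", sprintf("2013-06-%02d", i),
                                   amount = 75)
  r <- panel_of(ev)
  expect_identical(r$provider_id, "FPa")
  expect_identical(r$tie_break_used, "billings")

  # tie on visits and dollars -> most recently seen
  ev <- empty_events()
  for (i in 1:4) ev <- add_billing(ev, "A", "FPa", sprintf("2014-05-%02d", i),
                                   amount = 100)
  for (i in 1:3) ev <- add_billing(ev, "A", "FPb", sprintf("2014-06-%02d", i),
                                   amount = 100)
  ev <- add_billing(ev, "A", "FPb", "2016-02-01", amount = 100)
  r <- panel_of(ev)
  expect_identical(r$provider_id, "FPb")
  expect_identical(r$tie_break_used, "recency")

  # full residual tie -> lexicographic provider id, deterministically
  ev <- empty_events()
  ev <- add_billing(ev, "A", "FPz", "2013-05-01", amount = 50)
  ev <- add_billing(ev, "A", "FPy", "2013-05-01", amount = 50)
  r <- panel_of(ev)
  expect_identical(r$provider_id, "FPy")
  expect_identical(r$tie_break_used, "provider_id")
})

test_that("patients without ambulatory FP visits stay unassigned", {
  ev <- add_billing(empty_events(), "A", "SP001", "2013-05-01",
                    specialty = "specialist", ambulatory = FALSE)
  ev <- add_billing(ev, "A", "FPa", "2013-06-01", ambulatory = FALSE)
  r <- panel_of(ev)
  expect_true(is.na(r$provider_id))
  expect_identical(r$n_visits_to_assigned, 0L)
})

test_that("same-day billings to one provider collapse to one visit by default", {
  ev <- empty_events()
  for (i in 1:3) ev <- add_billing(ev, "A", "FPa", "2013-05-01")  # 1 visit
  for (i in 1:2) ev <- add_billing(ev, "A", "FPb",
                                   sprintf("2013-06-%02d", i))   # 2 visits
  expect_identical(panel_of(ev)$provider_id, "FPb")
  r2 <- assign_panel(ev$billings, window = win3, person_ids = "A",
                     collapse_same_day = FALSE)
  expect_identical(r2$provider_id, "FPa")
})

test_that("attribution matches the exhaustive oracle on randomized structures with forced ties", {
  set.seed(1234)
  ev <- empty_events()
  ids <- sprintf("P%03d", 1:150)
  provs <- sprintf("FP%02d", 1:6)
  for (p in ids) {
    for (j in 1:sample(1:4, 1)) {
      pr <- sample(provs, 1)
      nb <- sample(1:5, 1)
      for (k in 1:nb) {
        ev <- add_billing(ev, p, pr,
                          as.Date("2013-04-01") + sample(0:1000, 1),
                          amount = sample(c(50, 50, 75, 100), 1))
      }
    }
  }
  # forced ties at each cascade stage
  ev <- add_billing(ev, "T1", "FPa", "2013-05-01", amount = 60)
  ev <- add_billing(ev, "T1", "FPb", "2013-05-02", amount = 50)
  ev <- add_billing(ev, "T2", "FPa", "2013-05-01", amount = 50)
  ev <- add_billing(ev, "T2", "FPb", "2013-07-01", amount = 50)
  ev <- add_billing(ev, "T3", "FPa", "2013-05-01", amount = 50)
  ev <- add_billing(ev, "T3", "FPb", "2013-05-01", amount = 50)
  all_ids <- c(ids, "T1", "T2", "T3")
  res <- assign_panel(ev$billings, window = win3, person_ids = all_ids)
  oracle <- vapply(all_ids, function(p) oracle_panel(ev$billings, p, win3),
                   character(1))
  expect_identical(setNames(res$provider_id, res$person_id)[all_ids], oracle)
  expect_identical(res[person_id == "T1", tie_break_used], "billings")
  expect_identical(res[person_id == "T2", tie_break_used], "recency")
  expect_identical(res[person_id == "T3", tie_break_used], "provider_id")

  # permuting input rows never changes any assignment
  perm <- ev$billings[sample(.N)]
  res2 <- assign_panel(perm, window = win3, person_ids = all_ids)
  expect_identical(res, res2)
})

test_that("panel composition shares sum to one and respect counts", {
  seg <- data.table(person_id = c("A", "B", "C", "D", "E"),
                    segment = c(1L, 2L, 3L, 4L, 1L))
  asg <- data.table(person_id = c("A", "B", "C", "D", "E"),
                    provider_id = c("FPa", "FPa", "FPa", "FPa", NA),
                    n_visits_to_assigned = c(3L, 2L, 1L, 1L, 0L),
                    tie_break_used = "none")
  pc <- panel_composition(asg, seg)
  expect_identical(nrow(pc), 1L)   # unassigned E contributes nowhere
  expect_identical(pc$n_panel, 4)
  expect_equal(unlist(pc[, .(share_seg1, share_seg2, share_seg3,
                             share_seg4)]),
               c(share_seg1 = 0.25, share_seg2 = 0.25,
                 share_seg3 = 0.25, share_seg4 = 0.25))
  # missing segment for an assigned person -> linkage error
  expect_error(panel_composition(asg, seg[person_id != "B"]),
               "linkage error")
})

test_that("billing composition covers unpaneled patients and drops $0 providers", {
  seg <- data.table(person_id = c("A", "B"), segment = c(1L, 4L))
  ev <- empty_events()
  ev <- add_billing(ev, "A", "FPa", "2015-05-01", amount = 100)
  ev <- add_billing(ev, "B", "FPa", "2015-06-01", amount = 300)
  ev <- add_billing(ev, "B", "FPb", "2015-06-02", amount = 0)
  expect_message(bc <- billing_composition(ev$billings, seg,
                                           fiscal_years = "2015/16"),
                 "omitted")
  expect_identical(bc$provider_id, "FPa")
  expect_equal(bc$share_seg1, 0.25)
  expect_equal(bc$share_seg4, 0.75)
})

test_that("panel sizes conserve the number of assigned patients", {
  cfg <- generator_config(n_persons = 1200, seed = 55)
  dat <- generate_synthetic_data(cfg)
  seg <- segment_cohort(dat, dat$persons)
  asg <- assign_panel(dat$billings, window = cfg$fiscal_years,
                      person_ids = dat$persons$person_id)
  pc <- panel_composition(asg, seg)
  expect_equal(sum(pc$n_panel), sum(!is.na(asg$provider_id)))
  shares <- pc[, share_seg1 + share_seg2 + share_seg3 + share_seg4]
  expect_true(all(abs(shares - 1) < 1e-12))
})
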