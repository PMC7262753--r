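test_that("chronic conditions are counted as distinct registry conditions", {
  reg <- test_registry()
  ev <- empty_events()
  # diabetes coded on three billings, CHF on one hospital record -> 2
  ev <- add_billing(ev, "A", date = "2013-05-01", dx = "E11.9")
  ev <- add_billing(ev, "A", date = "2013-08-01", dx = "E110")
  ev <- add_billing(ev, "A", date = "2014-05-01", dx = "250")
  ev <- add_hospital(ev, "A", date = "2014-10-01", dx = "I50.1")
  expect_identical(count_chronic_conditions(ev, reg, "A", CLS_YEARS), 2L)

  # the same condition coded forty times still counts once
  ev2 <- empty_events()
  for (i in 1:40) {
    ev2 <- add_billing(ev2, "B", date = sprintf("2013-05-%02d", (i %% 28) + 1),
                       dx = "E11")
  }
  expect_identical(count_chronic_conditions(ev2, reg, "B", CLS_YEARS), 1L)

  # codes outside the registry never count
  ev3 <- add_billing(empty_events(), "C", date = "2013-05-01", dx = "M54")
  expect_identical(count_chronic_conditions(ev3, reg, "C", CLS_YEARS), 0L)

  # events outside the classification window never count
  ev4 <- add_billing(empty_events(), "D", date = "2015-05-01", dx = "E11")
  expect_identical(count_chronic_conditions(ev4, reg, "D", CLS_YEARS), 0L)
})

test_that("empty registry raises a configuration error", {
  expect_error(condition_registry(list()), "empty")
  expect_error(condition_registry(
    conditions = list(a = list(codes = "X")),
    complexity_events = list(bad = list(codes = "Y", condition = "nope"))),
    "unknown condition")
})

test_that("claim-count rules gate condition detection", {
  reg <- test_registry()   # hypertension needs >=2 ambulatory or >=1 hospital
  ev <- add_billing(empty_events(), "A", date = "2013-05-01", dx = "401")
  expect_identical(count_chronic_conditions(ev, reg, "A", CLS_YEARS), 0L)
  ev <- add_billing(ev, "A", date = "2013-09-01", dx = "4011")
  expect_identical(count_chronic_conditions(ev, reg, "A", CLS_YEARS), 1L)
  ev2 <- add_hospital(empty_events(), "B", date = "2013-07-01", dx = "401")
  expect_identical(count_chronic_conditions(ev2, reg, "B", CLS_YEARS), 1L)
})

test_that("complexity requires the trigger AND its linked condition", {
  reg <- test_registry()
  # dialysis plus chronic kidney disease -> complex
  ev <- add_billing(empty_events(), "A", date = "2013-05-01", dx = "N18")
  ev <- add_billing(ev, "A", date = "2013-06-01", dx = "Z49.1")
  expect_true(detect_complexity(ev, reg, "A", CLS_YEARS))
  # dialysis without the kidney-disease definition met -> not complex
  ev2 <- add_billing(empty_events(), "B", date = "2013-06-01", dx = "Z49.1")
  expect_false(detect_complexity(ev2, reg, "B", CLS_YEARS))
  # dialysis with some OTHER condition met -> still not complex
  ev3 <- add_billing(empty_events(), "C", date = "2013-05-01", dx = "E11")
  ev3 <- add_billing(ev3, "C", date = "2013-06-01", dx = "Z49")
  expect_false(detect_complexity(ev3, reg, "C", CLS_YEARS))
  expect_false(detect_complexity(empty_events(), "D", reg = reg,
                                 classification_years = CLS_YEARS))
})

test_that("frailty needs the 65+ gate plus a marker or two Edmonton criteria", {
  reg <- test_registry()
  persons <- make_persons(c("A", "B", "C", "D"), age = c(80, 60, 70, 70))
  ev <- add_billing(empty_events(), "A", date = "2013-05-01", dx = "Z51.5")
  ev <- add_billing(ev, "B", date = "2013-05-01", dx = "F03")
  ev <- add_billing(ev, "B", date = "2013-06-01", dx = "R32")
  ev <- add_billing(ev, "B", date = "2013-07-01", dx = "R63.4")
  ev <- add_billing(ev, "C", date = "2013-05-01", dx = "F03")
  ev <- add_billing(ev, "D", date = "2013-05-01", dx = "F03")
  ev <- add_billing(ev, "D", date = "2013-06-01", dx = "R32")

  expect_true(detect_frailty(ev, persons, reg, "A", CLS_YEARS)$frail)
  # three Edmonton criteria but aged 60: gated out, criteria still reported
  resB <- detect_frailty(ev, persons, reg, "B", CLS_YEARS)
  expect_false(resB$frail)
  expect_identical(resB$criteria_met, 3L)
  # one criterion only at 70: not frail
  expect_false(detect_frailty(ev, persons, reg, "C", CLS_YEARS)$frail)
  # two criteria at 70: frail
  expect_true(detect_frailty(ev, persons, reg, "D", CLS_YEARS)$frail)
})

test_that("segment assignment follows the 4 > 3 > 2 > 1 precedence", {
  expect_identical(assign_segment(2L, FALSE, FALSE), 2L)
  expect_identical(assign_segment(3L, TRUE, TRUE), 4L)
  expect_identical(assign_segment(0L, FALSE, FALSE), 1L)
  expect_identical(assign_segment(1L, FALSE, FALSE), 1L)
  expect_identical(assign_segment(1L, TRUE, FALSE), 3L)
  # a complexity trigger without any chronic condition stays low need
  expect_identical(assign_segment(0L, TRUE, FALSE), 1L)
  expect_identical(assign_segment(5L, FALSE, TRUE), 4L)
})

test_that("SES dichotomization splits quintiles 1-2 vs 3-5", {
  expect_identical(dichotomize_ses(c(1L, 2L, 3L, 4L, 5L)),
                   c("low", "low", "high", "high", "high"))
  expect_error(dichotomize_ses(0L), "data error")
  expect_error(dichotomize_ses(6L), "data error")
  expect_error(dichotomize_ses(NA_integer_), "data error")
  expect_identical(dichotomize_ses(NA_integer_, allow_missing = TRUE),
                   NA_character_)
})

test_that("adding a condition never lowers the segment (monotonicity)", {
  for (n in 0:5) {
    for (cx in c(FALSE, TRUE)) {
      for (fr in c(FALSE, TRUE)) {
        expect_gte(assign_segment(n + 1L, cx, fr), assign_segment(n, cx, fr))
      }
    }
  }
})

test_that("segmentation partitions the cohort and matches the brute-force oracle", {
  cfg <- generator_config(n_persons = 600, seed = 41)
  dat <- generate_synthetic_data(cfg)
  reg <- default_registry()
  seg <- segment_cohort(dat, dat$persons, reg)
  expect_identical(nrow(seg), nrow(dat$persons))
  expect_identical(anyDuplicated(seg$person_id), 0L)
  expect_true(all(seg$segment %in% 1:4))
  expect_true(all(seg$n_chronic_conditions_capped ==
                    pmin(seg$n_chronic_conditions, 5L)))
  ages <- dat$persons$age_at_index[match(seg$person_id,
                                         dat$persons$person_id)]
  oracle <- vapply(seq_len(nrow(seg)), function(i) {
    oracle_person_segment(dat, seg$person_id[i], ages[i], reg)
  }, integer(1))
  expect_identical(seg$segment, oracle)
})

test_that("the bundled example registry matches the built-in default", {
  p <- system.file("extdata", "registry.yaml", package = "careseg")
  expect_true(file.exists(p))
  expect_equal(read_registry(p), default_registry())
})

test_that("registry YAML round-trips through read_registry", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    match = "prefix",
    conditions = list(diabetes = list(codes = list("E11", "250")),
                      chf = list(codes = list("I50"))),
    complexity_events = list(device = list(codes = list("Z95"),
                                           condition = "chf")),
    frailty_markers = list(frailty_care = list("R54"),
                           palliative = list("Z51.5"),
                           edmonton = list(dementia = list("F03"),
                                           falls = list("R29.6")))
  ), path)
  reg <- read_registry(path)
  expect_s3_class(reg, "condition_registry")
  expect_setequal(names(reg$conditions), c("diabetes", "chf"))
  expect_identical(reg$complexity_events$device$condition, "chf")
  ev <- add_billing(empty_events(), "A", date = "2013-05-01", dx = "E11.2")
  expect_identical(count_chronic_conditions(ev, reg, "A", CLS_YEARS), 1L)
  expect_error(read_registry(file.path(tempdir(), "nope.yaml")), "not found")
})
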