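mk_md <- function(cost, age = "65-74", sex = "male") {
  data.table(person_id = sprintf("P%04d", seq_along(cost)),
             segment = 1L,
             cost_total = cost,
             age_group = factor(rep_len(age, length(cost)),
                                levels = c("65-74", "18-44", "45-64", "75+")),
             sex = factor(rep_len(sex, length(cost)),
                          levels = c("male", "female")))
}

test_that("winsorization caps at the within-group 99th percentile", {
  # {1..99, 1000}: the outlier is pulled to the interpolated percentile
  x <- c(1:99, 1000)
  tr <- truncate_costs(mk_md(x))
  expect_equal(max(tr$cost_total), oracle_percentile(x))
  expect_identical(sum(tr$truncated), 1L)
  expect_equal(tr$cost_total[1:99], as.numeric(1:99))

  # equal costs are untouched
  tr2 <- truncate_costs(mk_md(rep(40, 100)))
  expect_identical(sum(tr2$truncated), 0L)
  expect_equal(tr2$cost_total, rep(40, 100))

  # empty input is a no-op
  tr3 <- truncate_costs(mk_md(numeric()))
  expect_identical(nrow(tr3), 0L)

  # singleton group: cap equals the value, reported via a message
  expect_message(tr4 <- truncate_costs(mk_md(c(5))), "single")
  expect_equal(tr4$cost_total, 5)
})

test_that("winsorization matches the percentile oracle on random groups and is idempotent", {
  set.seed(7)
  for (rep in 1:20) {
    n1 <- sample(5:400, 1)
    n2 <- sample(5:400, 1)
    md <- rbind(mk_md(rgamma(n1, 2, scale = 500), age = "65-74"),
                mk_md(rgamma(n2, 1, scale = 2000), age = "75+"))
    tr <- truncate_costs(md)
    for (ag in c("65-74", "75+")) {
      x <- md[age_group == ag, cost_total]
      cap <- oracle_percentile(x)
      got <- tr[age_group == ag, cost_total]
      expect_equal(got, pmin(x, cap))
      # at most ceil(1%) of rows altered per group
      expect_lte(sum(x > cap), ceiling(0.01 * length(x)))
    }
    expect_true(all(tr$cost_total <= md$cost_total))
    tr2 <- truncate_costs(tr[, !"truncated"])
    expect_equal(tr2$cost_total, tr$cost_total)
  }
})

test_that("part-one recovery: planted odds ratios are found within 3 SE", {
  p1 <- c(intercept = 0.5, age_18_44 = log(0.6), sex_female = log(2.0),
          n_chronic = log(1.5), ses_low = log(0.9))
  p2 <- default_part_two_coefficients()
  sim <- simulate_two_part(30000, p1, p2, segment = 1L, seed = 101)
  fit <- fit_part_one(sim, 1L)
  est <- fit$estimates[term == "seslow"]
  z <- abs(log(est$ratio) - log(0.9)) / est$se
  expect_lt(z, 3)
  est_f <- fit$estimates[term == "sexfemale"]
  expect_lt(abs(log(est_f$ratio) - log(2.0)) / est_f$se, 3)
  # ratio = exp(coefficient) exactly
  expect_equal(est$ratio, exp(coef(fit$fit)[["seslow"]]))
})

test_that("part-two recovery: planted cost ratios are found within 3 SE", {
  p1 <- c(intercept = 2)
  p2 <- c(intercept = 0, ses_low = log(1.10), upc = log(0.61),
          n_chronic = log(1.3), access = log(2.0))
  sim <- simulate_two_part(30000, p1, p2, gamma_shape = 2, segment = 4L,
                           seed = 202)
  fit <- fit_part_two(sim, 4L)
  for (tm in list(c("seslow", log(1.10)), c("upc", log(0.61)),
                  c("access_out_of_hoursTRUE", log(2.0)))) {
    est <- fit$estimates[term == tm[1]]
    expect_lt(abs(log(est$ratio) - as.numeric(tm[2])) / est$se, 3)
  }
  expect_true(all(fit$estimates$lower <= fit$estimates$ratio))
  expect_true(all(fit$estimates$ratio <= fit$estimates$upper))
})

test_that("degenerate and empty fits raise explicit errors", {
  p1 <- c(intercept = 30)   # everyone uses care
  sim <- simulate_two_part(500, p1, default_part_two_coefficients(),
                           seed = 5)
  expect_error(fit_part_one(sim, 1L), "degenerate")
  expect_error(fit_part_one(sim, 3L), "empty segment")
  sim$cost_total[1] <- -1
  sim$any_cost[1] <- TRUE
  expect_error(fit_part_two(sim, 1L), "non-positive")
})

test_that("an intercept-only part-two fit reproduces the mean cost in closed form", {
  set.seed(11)
  y <- rgamma(400, shape = 2, scale = 600)
  d <- data.table(segment = 1L, cost_total = y, any_cost = TRUE,
                  age_group = factor("65-74"), sex = factor("male"),
                  n_chronic_capped = 0, ses = factor("high"),
                  upc = 0.5, coordination_lt5 = TRUE,
                  access_out_of_hours = FALSE)
  fit <- glm(cost_total ~ 1, data = d, family = Gamma(link = "log"))
  expect_equal(exp(coef(fit)[[1]]), mean(y), tolerance = 1e-8)
})

test_that("the frail segment drops under-65 age levels automatically", {
  p1 <- c(intercept = 1.5)
  p2 <- c(intercept = 0, age_75p = log(0.9))
  md <- rbind(simulate_two_part(4000, p1, p2, segment = 4L, seed = 303),
              simulate_two_part(4000, p1, p2, segment = 1L, seed = 304),
              simulate_two_part(2000, p1, p2, segment = 2L, seed = 9),
              simulate_two_part(2000, p1, p2, segment = 3L, seed = 10))
  fits <- fit_all_segments(md)
  terms4 <- fits$segment4$part_one$estimates$term
  expect_false(any(grepl("18-44|45-64", terms4)))
  terms1 <- fits$segment1$part_one$estimates$term
  expect_true(any(grepl("18-44", terms1)))
  expect_lte(fits$segment1$part_two$n, fits$segment1$part_one$n)
})

test_that("continuous and categorical chronic-condition fits agree in sign", {
  p1 <- c(intercept = 0.3, n_chronic = log(1.6))
  p2 <- c(intercept = 0, n_chronic = log(1.4))
  sim <- simulate_two_part(20000, p1, p2, segment = 2L, seed = 404)
  cont <- fit_part_two(sim, 2L, chronic = "continuous")
  cat_ <- fit_part_two(sim, 2L, chronic = "categorical")
  b_cont <- log(cont$estimates[term == "n_chronic_capped", ratio])
  cat_terms <- cat_$estimates[grepl("n_chronic", term)]
  # dummies increase monotonically on the log scale when the truth is linear
  expect_gt(b_cont, 0)
  expect_true(all(diff(log(cat_terms$ratio)) > 0) ||
                nrow(cat_terms) <= 1)
})

test_that("empty segments are skipped with a warning", {
  p1 <- c(intercept = 0.5)
  p2 <- c(intercept = 0)
  md <- rbind(simulate_two_part(3000, p1, p2, segment = 1L, seed = 1),
              simulate_two_part(3000, p1, p2, segment = 2L, seed = 2),
              simulate_two_part(3000, p1, p2, segment = 3L, seed = 3))
  expect_warning(fits <- fit_all_segments(md), "segment 4")
  expect_named(fits, c("segment1", "segment2", "segment3"))
})
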