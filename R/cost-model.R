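#' Winsorize total costs at the 99th percentile within age-sex groups
#'
#' Within each age-group-by-sex stratum, total costs above the stratum's
#' empirical 99th percentile — the `ceiling(0.99 * n)`-th order statistic
#' (`stats::quantile` type 1) — are capped at that percentile; values at or
#' below are unchanged. The order-statistic definition (rather than an
#' interpolated percentile) makes capping exactly idempotent: the cap is
#' itself a data value, so truncating twice equals truncating once. Capping
#' rather than deletion keeps every person in the model while preventing
#' extreme stays from dominating the Gamma fit.
#'
#' @param model_data Table with `cost_total`, `age_group` and `sex` columns
#'   (see [prepare_model_data()]).
#' @param probs Percentile used for the cap; default 0.99.
#' @return The input with `cost_total` capped and a logical `truncated`
#'   column flagging altered rows. Groups with a single person are capped at
#'   their own value (a no-op) and reported via a message.
#' @export
truncate_costs <- function(model_data, probs = 0.99) {
  dt <- copy(as.data.table(model_data))
  if (nrow(dt) == 0L) {
    dt[, truncated := logical(0)]
    return(dt[])
  }
  singles <- dt[, .N, by = .(age_group, sex)][N < 2L]
  if (nrow(singles)) {
    message(nrow(singles), " age-sex group(s) with a single person: ",
            "percentile equals the value itself")
  }
  dt[, cap := quantile(cost_total, probs = probs, type = 1, names = FALSE),
     by = .(age_group, sex)]
  dt[, truncated := cost_total > cap]
  dt[truncated == TRUE, cost_total := cap]
  dt[, cap := NULL]
  dt[]
}

#' Assemble model-ready data from metrics, segments and persons
#'
#' Joins the person-year metrics to the segment assignment and demographics,
#' codes the model covariates with the published reference levels (age
#' 65-74, male, high SES, saw 5+ FPs, no out-of-hours billing), computes the
#' any-cost indicator, and drops persons with no ambulatory FP visit in the
#' continuity window (undefined UPC), mirroring the regression-table
#' exclusions.
#'
#' @param metrics Output of [compute_metrics()].
#' @param segments Output of [segment_cohort()].
#' @param persons Person table.
#' @return `data.table` with factors `age_group` (ref `"65-74"`), `sex`
#'   (ref `"male"`), `ses` (ref `"high"`), numeric `n_chronic_capped` and
#'   `upc`, logicals `coordination_lt5`, `access_out_of_hours`, `any_cost`,
#'   and `cost_total`.
#' @export
prepare_model_data <- function(metrics, segments, persons) {
  dt <- merge(as.data.table(metrics),
              as.data.table(segments)[, .(person_id, segment,
                                          n_chronic_conditions_capped, ses)],
              by = "person_id")
  p <- as.data.table(persons)
  dt[, age_group := stats::relevel(age_group_of(
    p$age_at_index[match(person_id, p$person_id)]), ref = "65-74")]
  dt[, sex := factor(p$sex[match(person_id, p$person_id)],
                     levels = c("male", "female"))]
  dt[, ses := factor(ses, levels = c("high", "low"))]
  setnames(dt, "n_chronic_conditions_capped", "n_chronic_capped")
  dt[, any_cost := cost_total > 0]
  dt <- dt[!is.na(upc)]
  dt[]
}

#' Fit part one of the two-part cost model (any cost: logistic)
#'
#' Logistic regression of the any-cost indicator on age group, sex, capped
#' chronic-condition count and SES within one segment, by maximum likelihood
#' (IRLS). Coefficients are reported as odds ratios with 95% Wald confidence
#' intervals on the exponentiated scale. The three primary-care attributes
#' never enter part one.
#'
#' @param model_data Output of [prepare_model_data()] (already truncated or
#'   not; positivity of `cost_total` is unaffected by winsorization).
#' @param segment Segment to fit (1-4).
#' @param chronic `"continuous"` (capped count as one term, the primary
#'   analysis) or `"categorical"` (dummies, the sensitivity analysis).
#' @return List of class `part_fit`: `estimates` (term, ratio, lower, upper,
#'   se, p), `n`, `fit` (the `glm` object), `part`, `segment`.
#' @export
fit_part_one <- function(model_data, segment, chronic = c("continuous",
                                                          "categorical")) {
  chronic <- match.arg(chronic)
  seg <- segment
  d <- as.data.table(model_data)[segment == seg]
  if (nrow(d) == 0L) {
    stop("empty segment: no observations for segment ", seg, call. = FALSE)
  }
  if (all(d$any_cost) || !any(d$any_cost)) {
    stop("degenerate fit: outcome is constant (all ",
         if (all(d$any_cost)) "users" else "non-users",
         ") in segment ", seg, call. = FALSE)
  }
  d <- droplevels(d)
  rhs <- if (chronic == "continuous") "n_chronic_capped" else
    "factor(n_chronic_capped)"
  f <- stats::as.formula(paste("any_cost ~ age_group + sex +", rhs, "+ ses"))
  fit <- glm(f, data = d, family = binomial())
  check_fit_diagnostics(fit, "part one", seg)
  new_part_fit(fit, n = nrow(d), part = "one", segment = seg)
}

#' Fit part two of the two-part cost model (cost magnitude: Gamma)
#'
#' Gamma GLM with log link for total cost among positive-cost users of the
#' segment, adding the three primary-care attributes (UPC continuous in
#' (0, 1], coordination, out-of-hours access) to the part-one covariates.
#' Exponentiated coefficients are cost ratios with 95% Wald intervals.
#'
#' @inheritParams fit_part_one
#' @param attributes Include the three primary-care attribute covariates
#'   (default `TRUE`; `FALSE` gives the covariate set shared with part one).
#' @return A `part_fit` list (ratios are cost ratios).
#' @export
fit_part_two <- function(model_data, segment,
                         chronic = c("continuous", "categorical"),
                         attributes = TRUE) {
  chronic <- match.arg(chronic)
  seg <- segment
  d <- as.data.table(model_data)[segment == seg & any_cost == TRUE]
  if (nrow(d) == 0L) {
    stop("empty segment: no positive-cost observations for segment ", seg,
         call. = FALSE)
  }
  if (any(d$cost_total <= 0)) {
    stop("precondition violation: non-positive costs in part-two data",
         call. = FALSE)
  }
  d <- droplevels(d)
  rhs <- if (chronic == "continuous") "n_chronic_capped" else
    "factor(n_chronic_capped)"
  f <- paste("cost_total ~ age_group + sex +", rhs, "+ ses")
  if (attributes) {
    f <- paste(f, "+ upc + coordination_lt5 + access_out_of_hours")
  }
  fit <- glm(stats::as.formula(f), data = d, family = Gamma(link = "log"))
  check_fit_diagnostics(fit, "part two", seg)
  new_part_fit(fit, n = nrow(d), part = "two", segment = seg)
}

#' Fit the two-part model in every segment
#'
#' One part-one and one part-two fit per segment. In segments containing
#' only 65+ persons (the frail segment by construction) the younger age
#' levels are absent and are dropped from the design matrix automatically.
#' Empty segments are skipped with a warning. Optionally repeats the fits
#' with the chronic-condition count as categorical dummies (sensitivity
#' analysis).
#'
#' @param model_data Output of [prepare_model_data()], typically after
#'   [truncate_costs()].
#' @param sensitivity Also run the categorical-chronic variant.
#' @return List of class `two_part_results`: per segment a list with
#'   `part_one`, `part_two` and (if requested) `part_one_categorical`,
#'   `part_two_categorical`.
#' @export
fit_all_segments <- function(model_data, sensitivity = FALSE) {
  out <- list()
  for (s in 1:4) {
    if (!any(model_data$segment == s)) {
      warning("segment ", s, " is empty; skipped")
      next
    }
    res <- list(part_one = fit_part_one(model_data, s),
                part_two = fit_part_two(model_data, s))
    if (sensitivity) {
      res$part_one_categorical <- fit_part_one(model_data, s, "categorical")
      res$part_two_categorical <- fit_part_two(model_data, s, "categorical")
    }
    out[[paste0("segment", s)]] <- res
  }
  class(out) <- "two_part_results"
  out
}

new_part_fit <- function(fit, n, part, segment) {
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- cf / se
  est <- data.table(
    term = names(cf),
    ratio = exp(cf),
    lower = exp(cf - 1.959964 * se),
    upper = exp(cf + 1.959964 * se),
    se = se,
    p = 2 * pnorm(-abs(z))
  )
  structure(list(estimates = est, n = n, part = part, segment = segment,
                 converged = fit$converged, fit = fit),
            class = "part_fit")
}

check_fit_diagnostics <- function(fit, part, segment) {
  if (!fit$converged) {
    stop("diagnostic error: ", part, " did not converge in segment ",
         segment, call. = FALSE)
  }
  big <- abs(coef(fit)) > 15
  big[is.na(big)] <- TRUE
  if (any(big)) {
    stop("diagnostic error: ", part, " in segment ", segment,
         " shows separation or rank deficiency in covariate(s): ",
         paste(names(coef(fit))[big], collapse = ", "), call. = FALSE)
  }
  invisible(fit)
}

#' @export
print.part_fit <- function(x, ...) {
  lab <- if (x$part == "one") "odds ratios" else "cost ratios"
  cat("Two-part model, part ", x$part, " (", lab, "), segment ", x$segment,
      ", n = ", x$n, "\n", sep = "")
  print(x$estimates[, .(term, ratio = round(ratio, 3),
                        lower = round(lower, 3), upper = round(upper, 3))])
  invisible(x)
}

#' Simulate model-ready data directly from a two-part cost model
#'
#' Draws covariates (age group, sex, capped chronic-condition count, SES,
#' UPC, coordination, access) from simple marginal distributions and
#' outcomes from the configured logistic and Gamma models, bypassing the
#' event generator. Used for calibration studies of the fitting routines
#' (bias and confidence-interval coverage over many replicates) where
#' materialising full claims tables would be wasteful.
#'
#' @param n Number of persons.
#' @param part_one,part_two Named coefficient vectors (see
#'   [generator_config()] for the naming scheme).
#' @param gamma_shape Gamma shape of the cost distribution.
#' @param base_cost Reference expected cost (enters as `log(base_cost)` in
#'   the part-two intercept).
#' @param segment Segment label stamped on the rows; segment 4 restricts
#'   ages to 65+.
#' @param seed Optional seed.
#' @return Model-ready `data.table` as from [prepare_model_data()], with an
#'   `any_cost` indicator and positive `cost_total` for users.
#' @export
simulate_two_part <- function(n, part_one, part_two, gamma_shape = 2,
                              base_cost = 950, segment = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  ages <- if (segment == 4L) c("65-74", "75+") else
    c("18-44", "45-64", "65-74", "75+")
  X <- data.table(
    segment = rep(as.integer(segment), n),
    age_group = factor(sample(ages, n, replace = TRUE), levels = ages),
    sex = factor(sample(c("male", "female"), n, replace = TRUE),
                 levels = c("male", "female")),
    n_chronic_capped = sample(0:5, n, replace = TRUE),
    ses = factor(sample(c("high", "low"), n, replace = TRUE),
                 levels = c("high", "low")),
    upc = pmax(runif(n), 1e-3),
    coordination_lt5 = runif(n) < 0.9,
    access_out_of_hours = runif(n) < 0.15
  )
  X[, age_group := stats::relevel(age_group, ref = "65-74")]
  lp1 <- two_part_linpred(X, part_one, part = "one")
  X[, any_cost := rbinom(n, 1L, plogis(lp1)) == 1L]
  lp2 <- log(base_cost) + two_part_linpred(X, part_two, part = "two")
  X[, cost_total := 0]
  idx <- which(X$any_cost)
  X[idx, cost_total := rgamma(length(idx), shape = gamma_shape,
                              scale = exp(lp2[idx]) / gamma_shape)]
  X[, person_id := sprintf("S%07d", seq_len(n))]
  X[]
}
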