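#' Attribute patients to family-physician panels by plurality of visits
#'
#' Each patient is assigned to the family physician with whom they had the
#' highest number of ambulatory visits over the attribution window
#' (conventionally three fiscal years). Ties go to the provider with the
#' higher summed ambulatory billing dollars, then to the provider seen most
#' recently; a residual exact tie (same count, dollars and last date) is
#' broken by lexicographic provider id so the assignment is deterministic
#' under any permutation of the input rows. Patients with zero ambulatory FP
#' visits in the window remain unassigned (`provider_id` `NA`). Specialist
#' billings never contribute.
#'
#' @param billings Billing table.
#' @param window Fiscal years of the attribution window; default
#'   `c("2013/14", "2014/15", "2015/16")`.
#' @param person_ids Persons to assign; defaults to everyone appearing in
#'   `billings`. Persons with no qualifying visits are returned unassigned.
#' @param collapse_same_day Count multiple same-day billings to one provider
#'   as one visit (default `TRUE`).
#' @return `data.table`: `person_id`, `provider_id` (`NA` if unassigned),
#'   `n_visits_to_assigned`, `tie_break_used` in
#'   `c("none", "billings", "recency", "provider_id")`.
#' @export
assign_panel <- function(billings, window = c("2013/14", "2014/15",
                                              "2015/16"),
                         person_ids = NULL,
                         collapse_same_day = TRUE) {
  billings <- as.data.table(billings)
  if (is.null(person_ids)) person_ids <- unique(billings$person_id)

  amb <- billings[specialty == "FP" & ambulatory == TRUE &
                    fiscal_year %in% window]
  if (nrow(amb) == 0L) {
    return(data.table(person_id = person_ids, provider_id = NA_character_,
                      n_visits_to_assigned = 0L, tie_break_used = "none"))
  }
  visits <- if (collapse_same_day) {
    amb[, .(n_visits = uniqueN(service_date), total_amount = sum(amount),
            last_date = max(service_date)),
        by = .(person_id, provider_id)]
  } else {
    amb[, .(n_visits = .N, total_amount = sum(amount),
            last_date = max(service_date)),
        by = .(person_id, provider_id)]
  }
  setorder(visits, person_id, -n_visits, -total_amount, -last_date,
           provider_id)
  top <- visits[, {
    tb <- if (.N == 1L || n_visits[1L] > n_visits[2L]) {
      "none"
    } else if (total_amount[1L] > total_amount[2L]) {
      "billings"
    } else if (last_date[1L] > last_date[2L]) {
      "recency"
    } else {
      "provider_id"
    }
    .(provider_id = provider_id[1L], n_visits_to_assigned = n_visits[1L],
      tie_break_used = tb)
  }, by = person_id]

  out <- data.table(person_id = person_ids)
  out <- merge(out, top, by = "person_id", all.x = TRUE, sort = TRUE)
  out[is.na(provider_id), `:=`(n_visits_to_assigned = 0L,
                               tie_break_used = "none")]
  out[]
}

#' Segment composition of physician panels
#'
#' Counts and shares of each provider's panel falling in each segment.
#' Providers with zero panelled patients do not appear (they can still
#' appear in [billing_composition()]).
#'
#' @param assignments Output of [assign_panel()].
#' @param segments Segment assignment table with `person_id`, `segment`.
#' @return `data.table` with one row per provider: panel size `n_panel`,
#'   counts `n_seg1`..`n_seg4` and shares `share_seg1`..`share_seg4`
#'   (summing to 1 per provider).
#' @export
panel_composition <- function(assignments, segments) {
  a <- as.data.table(assignments)[!is.na(provider_id)]
  set(a, j = "segment",
      value = as.data.table(segments)[match(a$person_id, person_id),
                                      segment])
  if (anyNA(a$segment)) {
    stop("linkage error: panel-assigned person(s) lack a segment",
         call. = FALSE)
  }
  composition_table(a[, .(provider_id, segment, w = 1)])
}

#' Segment composition of physician billing dollars
#'
#' Shares of each family physician's billing dollars attributable to
#' patients of each segment, over *all* patients the physician billed for
#' (panelled or not). Providers with zero billed dollars in the window are
#' omitted with a message.
#'
#' @param billings Billing table (FP rows are used).
#' @param segments Segment assignment table.
#' @param fiscal_years Window; default the outcome year `"2015/16"`.
#' @return `data.table` per provider: `total_amount`, dollar counts and
#'   shares by segment.
#' @export
billing_composition <- function(billings, segments,
                                fiscal_years = "2015/16") {
  b <- as.data.table(billings)[specialty == "FP" &
                                 fiscal_year %in% fiscal_years]
  set(b, j = "segment",
      value = as.data.table(segments)[match(b$person_id, person_id),
                                      segment])
  b <- b[!is.na(segment)]
  tot <- b[, .(w = sum(amount)), by = .(provider_id, segment)]
  zero <- tot[, .(t = sum(w)), by = provider_id][t <= 0, provider_id]
  if (length(zero)) {
    message(length(zero), " provider(s) with $0 billings omitted")
    tot <- tot[!provider_id %in% zero]
  }
  res <- composition_table(tot)
  setnames(res, "n_panel", "total_amount")
  setnames(res, paste0("n_seg", 1:4), paste0("amount_seg", 1:4))
  res
}

composition_table <- function(dt) {
  wide <- dcast(dt[, .(w = sum(w)), by = .(provider_id, segment)],
                provider_id ~ segment, value.var = "w", fill = 0)
  wide <- copy(wide)
  for (s in as.character(1:4)) {
    if (!s %in% names(wide)) set(wide, j = s, value = 0)
  }
  setnames(wide, as.character(1:4), paste0("n_seg", 1:4))
  wide[, n_panel := n_seg1 + n_seg2 + n_seg3 + n_seg4]
  for (s in 1:4) {
    set(wide, j = paste0("share_seg", s),
        value = wide[[paste0("n_seg", s)]] / wide$n_panel)
  }
  setcolorder(wide, c("provider_id", "n_panel"))
  setorder(wide, provider_id)
  wide[]
}
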