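# Independent straight-line re-implementations used as oracles. These
# deliberately avoid the package's vectorised code paths: plain loops,
# explicit comparisons.

oracle_code_match <- function(code, set, mode = "prefix") {
  code <- gsub(".", "", toupper(code), fixed = TRUE)
  for (s in set) {
    if (mode == "prefix") {
      if (substr(code, 1, nchar(s)) == s) return(TRUE)
    } else if (code == s) {
      return(TRUE)
    }
  }
  FALSE
}

# segment for one person by direct rule evaluation
oracle_person_segment <- function(events, person, age, registry,
                                  years = CLS_YEARS) {
  b <- events$billings[events$billings$person_id == person &
                         events$billings$fiscal_year %in% years &
                         !is.na(events$billings$dx), ]
  h <- events$hospital[events$hospital$person_id == person &
                         events$hospital$fiscal_year %in% years &
                         !is.na(events$hospital$dx), ]
  conds <- character()
  for (nm in names(registry$conditions)) {
    def <- registry$conditions[[nm]]
    n_any <- 0; n_amb <- 0; n_hosp <- 0
    if (nrow(b)) for (i in seq_len(nrow(b))) {
      if (oracle_code_match(b$dx[i], def$codes, registry$match)) {
        n_any <- n_any + 1
        if (isTRUE(b$ambulatory[i])) n_amb <- n_amb + 1
      }
    }
    if (nrow(h)) for (i in seq_len(nrow(h))) {
      if (oracle_code_match(h$dx[i], def$codes, registry$match)) {
        n_any <- n_any + 1
        n_hosp <- n_hosp + 1
      }
    }
    ok <- if (def$rule == "any") n_any >= 1 else (n_amb >= 2 || n_hosp >= 1)
    if (ok) conds <- c(conds, nm)
  }
  complex <- FALSE
  for (nm in names(registry$complexity_events)) {
    ev <- registry$complexity_events[[nm]]
    seen <- FALSE
    if (nrow(b)) for (i in seq_len(nrow(b))) {
      if (oracle_code_match(b$dx[i], ev$codes, registry$match)) seen <- TRUE
    }
    if (nrow(h)) for (i in seq_len(nrow(h))) {
      if (oracle_code_match(h$dx[i], ev$codes, registry$match)) seen <- TRUE
    }
    if (seen && ev$condition %in% conds) complex <- TRUE
  }
  fm <- registry$frailty_markers
  flag <- FALSE
  crit <- character()
  all_rows <- rbind(
    if (nrow(b)) data.frame(dx = b$dx) else NULL,
    if (nrow(h)) data.frame(dx = h$dx) else NULL
  )
  if (!is.null(all_rows) && nrow(all_rows)) {
    for (i in seq_len(nrow(all_rows))) {
      cd <- all_rows$dx[i]
      if (oracle_code_match(cd, fm$frailty_care, registry$match)) flag <- TRUE
      if (oracle_code_match(cd, fm$palliative, registry$match)) flag <- TRUE
      for (cn in names(fm$edmonton)) {
        if (oracle_code_match(cd, fm$edmonton[[cn]], registry$match)) {
          crit <- union(crit, cn)
        }
      }
    }
  }
  frail <- age >= 65 && (flag || length(crit) >= 2)
  if (frail) return(4L)
  if (complex && length(conds) >= 1) return(3L)
  if (length(conds) >= 2) return(2L)
  1L
}

# exhaustive three-stage panel attribution for one person
oracle_panel <- function(billings, person, window, collapse = TRUE) {
  b <- billings[billings$person_id == person &
                  billings$specialty == "FP" &
                  billings$ambulatory == TRUE &
                  billings$fiscal_year %in% window, ]
  if (nrow(b) == 0) return(NA_character_)
  provs <- sort(unique(b$provider_id))
  nv <- am <- numeric(length(provs))
  ld <- rep(as.Date("1900-01-01"), length(provs))
  for (j in seq_along(provs)) {
    rows <- b[b$provider_id == provs[j], ]
    nv[j] <- if (collapse) length(unique(rows$service_date)) else nrow(rows)
    am[j] <- sum(rows$amount)
    ld[j] <- max(rows$service_date)
  }
  best <- which(nv == max(nv))
  if (length(best) > 1) best <- best[am[best] == max(am[best])]
  if (length(best) > 1) best <- best[ld[best] == max(ld[best])]
  if (length(best) > 1) best <- best[order(provs[best])[1]]
  provs[best[1]]
}

# 99th percentile as an explicit order statistic (inverse empirical CDF)
oracle_percentile <- function(x, p = 0.99) {
  x <- sort(x)
  x[max(1, ceiling(length(x) * p))]
}
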