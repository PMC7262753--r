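#' Condition registry: configurable case definitions for segmentation
#'
#' The registry maps condition names to diagnosis-code sets (with a per
#' condition claim-count rule), complexity events to their trigger codes and
#' the chronic condition they are linked to (e.g. dialysis is a complexity
#' indicator only among people with chronic kidney disease), and frailty
#' markers (frailty-based-care codes, palliative codes, and Edmonton-scale
#' criterion definitions, of which at least two must be met).
#'
#' Codes are matched after normalisation (uppercased, dots stripped) either by
#' prefix (default, so `"I50"` matches `"I50.1"`) or exactly, which
#' accommodates both ICD-9 and ICD-10-CA style coding.
#'
#' @param conditions Named list; each element a list with `codes` (character)
#'   and optional `rule`, one of `"any"` (default: at least one qualifying
#'   code in the window) or `"amb2_or_hosp1"` (at least two ambulatory claims
#'   or at least one hospital claim).
#' @param complexity_events Named list; each element a list with `codes` and
#'   `condition`, the name of the linked chronic condition.
#' @param frailty_markers List with character-code elements `frailty_care` and
#'   `palliative`, and `edmonton`, a named list of criterion-name -> codes.
#' @param match `"prefix"` or `"exact"`.
#' @return An object of class `condition_registry`.
#' @export
condition_registry <- function(conditions, complexity_events = list(),
                               frailty_markers = list(frailty_care = character(),
                                                      palliative = character(),
                                                      edmonton = list()),
                               match = c("prefix", "exact")) {
  match <- match.arg(match)
  if (length(conditions) == 0L) {
    stop("registry configuration error: 'conditions' is empty", call. = FALSE)
  }
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("registry configuration error: all conditions must be named",
         call. = FALSE)
  }
  conditions <- lapply(conditions, function(cc) {
    if (is.character(cc)) cc <- list(codes = cc)
    cc$codes <- normalize_code(cc$codes)
    cc$rule <- if (is.null(cc$rule)) "any" else cc$rule
    if (!cc$rule %in% c("any", "amb2_or_hosp1")) {
      stop("registry configuration error: unknown rule '", cc$rule, "'",
           call. = FALSE)
    }
    cc
  })
  for (nm in names(complexity_events)) {
    ev <- complexity_events[[nm]]
    if (is.null(ev$condition) || !ev$condition %in% names(conditions)) {
      stop("registry configuration error: complexity event '", nm,
           "' references unknown condition '", ev$condition, "'",
           call. = FALSE)
    }
    complexity_events[[nm]]$codes <- normalize_code(ev$codes)
  }
  fm <- frailty_markers
  fm$frailty_care <- normalize_code(fm$frailty_care %||% character())
  fm$palliative <- normalize_code(fm$palliative %||% character())
  fm$edmonton <- lapply(fm$edmonton %||% list(), normalize_code)
  structure(list(conditions = conditions,
                 complexity_events = complexity_events,
                 frailty_markers = fm,
                 match = match),
            class = "condition_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalise a diagnosis code for matching
#'
#' Uppercases and strips dots, so `"i50.1"` becomes `"I501"`.
#' @param code Character vector of codes.
#' @return Normalised character vector.
#' @export
normalize_code <- function(code) {
  gsub(".", "", toupper(trimws(as.character(code))), fixed = TRUE)
}

#' Read a condition registry from a YAML file
#'
#' @param path Path to a YAML file with top-level keys `conditions`,
#'   `complexity_events`, `frailty_markers`, and optional `match`.
#' @return A `condition_registry`.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) {
    stop("registry configuration error: file not found: ", path,
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  condition_registry(
    conditions = raw$conditions,
    complexity_events = raw$complexity_events %||% list(),
    frailty_markers = raw$frailty_markers %||%
      list(frailty_care = character(), palliative = character(),
           edmonton = list()),
    match = raw$match %||% "prefix"
  )
}

#' Default synthetic condition registry
#'
#' A compact registry used by the synthetic-claims generator and examples:
#' six chronic conditions, three complexity events (each linked to one
#' condition), and frailty markers including four Edmonton-scale criteria.
#' Codes are ICD-10-style but the sets are illustrative, not clinically
#' validated; real analyses should load a jurisdiction-specific registry with
#' [read_registry()].
#'
#' @return A `condition_registry`.
#' @export
default_registry <- function() {
  condition_registry(
    conditions = list(
      diabetes = list(codes = c("E10", "E11", "250")),
      chf = list(codes = c("I50", "428")),
      copd = list(codes = c("J44", "496")),
      ckd = list(codes = c("N18", "585")),
      hypertension = list(codes = c("I10", "401")),
      depression = list(codes = c("F32", "F33", "311"))
    ),
    complexity_events = list(
      dialysis = list(codes = c("Z49"), condition = "ckd"),
      home_oxygen = list(codes = c("Z99.8"), condition = "copd"),
      cardiac_device = list(codes = c("Z95"), condition = "chf")
    ),
    frailty_markers = list(
      frailty_care = c("R54"),
      palliative = c("Z51.5"),
      edmonton = list(
        dementia = c("F03"),
        incontinence = c("R32"),
        weight_loss = c("R63.4"),
        functional_dependence = c("Z74.0")
      )
    ),
    match = "prefix"
  )
}

# All normalised codes appearing anywhere in a registry (used to keep
# generator noise codes disjoint from classification codes).
registry_all_codes <- function(registry) {
  unique(c(
    unlist(lapply(registry$conditions, `[[`, "codes")),
    unlist(lapply(registry$complexity_events, `[[`, "codes")),
    registry$frailty_markers$frailty_care,
    registry$frailty_markers$palliative,
    unlist(registry$frailty_markers$edmonton)
  ))
}

# Map a vector of raw event codes to registry entries. Returns a data.table
# with columns code (raw), category, name, criterion (edmonton only).
registry_match_codes <- function(codes, registry) {
  u <- unique(normalize_code(codes))
  entries <- list()
  add <- function(set, category, name, criterion = NA_character_) {
    if (length(set) == 0L) return()
    hit <- if (registry$match == "prefix") {
      m <- matrix(vapply(set, function(p) startsWith(u, p),
                         logical(length(u))), nrow = length(u))
      u[rowSums(m) > 0L]
    } else {
      u[u %in% set]
    }
    if (length(hit)) {
      entries[[length(entries) + 1L]] <<- data.table::data.table(
        code = hit, category = category, name = name, criterion = criterion)
    }
  }
  for (nm in names(registry$conditions)) {
    add(registry$conditions[[nm]]$codes, "condition", nm)
  }
  for (nm in names(registry$complexity_events)) {
    add(registry$complexity_events[[nm]]$codes, "complexity", nm)
  }
  add(registry$frailty_markers$frailty_care, "frailty", "frailty_care")
  add(registry$frailty_markers$palliative, "frailty", "palliative")
  for (nm in names(registry$frailty_markers$edmonton)) {
    add(registry$frailty_markers$edmonton[[nm]], "edmonton", "edmonton", nm)
  }
  if (length(entries) == 0L) {
    return(data.table::data.table(code = character(), category = character(),
                                  name = character(), criterion = character()))
  }
  data.table::rbindlist(entries)
}
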