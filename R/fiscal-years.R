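#' Fiscal-year helpers
#'
#' Fiscal years follow the Canadian convention: April 1 to March 31, labelled
#' `"2013/14"` for the year starting 2013-04-01.
#'
#' @param label Fiscal-year label, e.g. `"2013/14"`.
#' @return `fy_start()`/`fy_end()` return `Date`; `fy_of_date()` returns a
#'   label for each input date; `fy_sequence()` returns `n` consecutive labels.
#' @examples
#' fy_start("2013/14")            # 2013-04-01
#' fy_of_date(as.Date("2014-03-31"))  # "2013/14"
#' @name fiscal_years
NULL

fy_check_label <- function(label) {
  ok <- grepl("^[0-9]{4}/[0-9]{2}$", label)
  if (!all(ok)) {
    stop("malformed fiscal-year label(s): ",
         paste(label[!ok], collapse = ", "), call. = FALSE)
  }
  invisible(label)
}

#' @rdname fiscal_years
#' @export
fy_start <- function(label) {
  fy_check_label(label)
  as.Date(paste0(substr(label, 1, 4), "-04-01"))
}

#' @rdname fiscal_years
#' @export
fy_end <- function(label) {
  fy_check_label(label)
  as.Date(paste0(as.integer(substr(label, 1, 4)) + 1L, "-03-31"))
}

#' @param date A `Date` vector.
#' @rdname fiscal_years
#' @export
fy_of_date <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  start <- ifelse(m >= 4L, y, y - 1L)
  sprintf("%d/%02d", start, (start + 1L) %% 100L)
}

#' @param first First fiscal-year label.
#' @param n Number of consecutive fiscal years.
#' @rdname fiscal_years
#' @export
fy_sequence <- function(first, n) {
  fy_check_label(first)
  y0 <- as.integer(substr(first, 1, 4))
  sprintf("%d/%02d", y0 + seq_len(n) - 1L, (y0 + seq_len(n)) %% 100L)
}

# Uniform random dates within one fiscal year, one per element of `label`.
fy_random_date <- function(label) {
  s <- fy_start(label)
  offs <- floor(runif(length(label)) * 365)
  s + offs
}
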