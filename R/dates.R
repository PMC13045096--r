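# Year-month arithmetic. Dates carry month or year precision; internally a
# date is an integer month index (year * 12 + month - 1) so ordering and
# binning are plain integer operations.

#' Parse year-month date strings
#'
#' Accepts `"YYYY-MM"` (month precision) or `"YYYY"` (year precision, mapped
#' to January for placement on the timeline but compared at year precision
#' when checking temporal order).
#'
#' @param x character vector of date strings.
#' @return A data.frame with columns `ym` (integer month index), `precision`
#'   (`"month"` or `"year"`) and `date` (the normalised `"YYYY-MM"` string).
#'   `NA` inputs yield `NA` rows.
#' @examples
#' ym_parse(c("2020-03", "2021"))
#' @export
ym_parse <- function(x) {
  x <- as.character(x)
  n <- length(x)
  ym <- rep(NA_integer_, n)
  precision <- rep(NA_character_, n)
  blank <- is.na(x) | !nzchar(trimws(x))
  for (i in seq_len(n)) {
    if (blank[i]) next
    s <- trimws(x[i])
    if (grepl("^\\d{4}-\\d{2}$", s)) {
      yr <- as.integer(substr(s, 1, 4))
      mo <- as.integer(substr(s, 6, 7))
      if (mo < 1L || mo > 12L) {
        stop("unparseable date '", s, "': month out of range", call. = FALSE)
      }
      ym[i] <- yr * 12L + mo - 1L
      precision[i] <- "month"
    } else if (grepl("^\\d{4}$", s)) {
      ym[i] <- as.integer(s) * 12L
      precision[i] <- "year"
    } else {
      stop("unparseable date '", s, "': expected YYYY-MM or YYYY",
           call. = FALSE)
    }
  }
  data.frame(ym = ym, precision = precision, date = ym_format(ym),
             stringsAsFactors = FALSE)
}

#' Format an integer month index as "YYYY-MM"
#' @param ym integer month index as produced by [ym_parse()].
#' @return character vector.
#' @export
ym_format <- function(ym) {
  out <- rep(NA_character_, length(ym))
  ok <- !is.na(ym)
  out[ok] <- sprintf("%04d-%02d", ym[ok] %/% 12L, ym[ok] %% 12L + 1L)
  out
}

# Floor a month index to the start of its bin at the given width.
ym_floor <- function(ym, width = c("month", "quarter", "year")) {
  width <- match.arg(width)
  step <- switch(width, month = 1L, quarter = 3L, year = 12L)
  (ym %/% step) * step
}

# Human-readable bin label: "2019-03", "2019Q1" or "2019".
bin_label <- function(ym, width) {
  yr <- ym %/% 12L
  mo <- ym %% 12L + 1L
  switch(width,
    month   = sprintf("%04d-%02d", yr, mo),
    quarter = sprintf("%04dQ%d", yr, (mo - 1L) %/% 3L + 1L),
    year    = sprintf("%04d", yr))
}
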