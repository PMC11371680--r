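#' Parse FAERS date strings, keeping partial dates as partials
#'
#' FAERS date fields hold 8-digit `yyyymmdd` values but are frequently
#' truncated to `yyyymm` or `yyyy`, or absent. Partial dates are retained as
#' typed partials (year/month components only) rather than coerced to a full
#' date, so downstream arithmetic such as time-to-onset never fabricates a
#' day component.
#'
#' @param x Character (or coercible) vector of raw date strings.
#'
#' @return A tibble with one row per input: `raw` (the input), `date` (a
#'   `Date`, non-`NA` only for valid 8-digit values), `year`, `month`
#'   (integers, `NA` where unknown), and `precision`, one of `"day"`,
#'   `"month"`, `"year"`, `"missing"`. The attribute `n_invalid` counts
#'   non-empty inputs that could not be interpreted (wrong length,
#'   non-digits, impossible month or day).
#'
#' @examples
#' parse_faers_date(c("20200105", "202001", "2020", "", "20201301"))
#' @export
parse_faers_date <- function(x) {
  raw <- as.character(x)
  s <- stringr::str_trim(raw)
  s[is.na(s)] <- ""
  n <- nchar(s)
  all_digits <- stringr::str_detect(s, "^[0-9]*$")

  year <- month <- rep(NA_integer_, length(s))
  date <- rep(as.Date(NA), length(s))
  precision <- rep("missing", length(s))

  i4 <- all_digits & n == 4L
  year[i4] <- as.integer(s[i4])
  precision[i4] <- "year"

  i6 <- all_digits & n == 6L
  y6 <- as.integer(substr(s[i6], 1L, 4L))
  m6 <- as.integer(substr(s[i6], 5L, 6L))
  ok6 <- m6 >= 1L & m6 <= 12L
  year[i6][ok6] <- y6[ok6]
  month[i6][ok6] <- m6[ok6]
  precision[i6][ok6] <- "month"

  i8 <- all_digits & n == 8L
  d8 <- as.Date(s[i8], format = "%Y%m%d")
  ok8 <- !is.na(d8)
  date[i8][ok8] <- d8[ok8]
  year[i8][ok8] <- as.integer(format(d8[ok8], "%Y"))
  month[i8][ok8] <- as.integer(format(d8[ok8], "%m"))
  precision[i8][ok8] <- "day"

  out <- tibble(raw = raw, date = date, year = year, month = month,
                precision = precision)
  attr(out, "n_invalid") <- sum(n > 0L & precision == "missing")
  out
}
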