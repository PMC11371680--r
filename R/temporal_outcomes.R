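#' Time from therapy start to pulmonary event onset
#'
#' For each cohort report with a pulmonary event, onset time is the
#' difference in days between the report's event onset date and the
#' earliest therapy start date among the drug rows that matched a CAR-T
#' product. Reports are excluded — with a typed reason — when either date
#' is missing or partial (partial dates are never coerced into full
#' dates), or when the difference is negative.
#'
#' @param cohort A [build_cohort()] result.
#' @param ther The deduplicated THER tibble.
#'
#' @return Tibble with one row per pulmonary-event report: `primaryid`,
#'   `product`, `days` (integer, `NA` when excluded) and `reason`, one of
#'   `"ok"`, `"missing_event_date"`, `"partial_event_date"`,
#'   `"missing_start_date"`, `"partial_start_date"`, `"negative"`.
#' @export
time_to_onset <- function(cohort, ther) {
  stopifnot(inherits(cohort, "cart_cohort"))
  rep_tbl <- cohort$reports[cohort$reports$pae_flag, , drop = FALSE]

  starts <- dplyr::inner_join(
    cohort$matched_drugs, as_tibble(ther),
    by = c("primaryid", "drug_seq" = "dsg_drug_seq"),
    relationship = "many-to-many")
  sp <- parse_faers_date(starts$start_dt)
  starts$start_date <- sp$date
  starts$start_precision <- sp$precision
  start_by_report <- starts |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(
      start_date = if (any(!is.na(.data$start_date)))
        min(.data$start_date, na.rm = TRUE) else as.Date(NA),
      any_partial = any(.data$start_precision %in% c("year", "month")),
      .groups = "drop")

  ep <- parse_faers_date(rep_tbl$event_dt)
  out <- rep_tbl[, c("primaryid", "product")]
  out$event_date <- ep$date
  out$event_precision <- ep$precision
  out <- dplyr::left_join(out, start_by_report, by = "primaryid")
  out$any_partial[is.na(out$any_partial)] <- FALSE

  days <- as.integer(out$event_date - out$start_date)
  reason <- dplyr::case_when(
    out$event_precision == "missing" ~ "missing_event_date",
    out$event_precision %in% c("year", "month") ~ "partial_event_date",
    is.na(out$start_date) & out$any_partial ~ "partial_start_date",
    is.na(out$start_date) ~ "missing_start_date",
    days < 0L ~ "negative",
    TRUE ~ "ok")
  tibble(primaryid = out$primaryid, product = out$product,
         days = ifelse(reason == "ok", days, NA_integer_),
         reason = reason)
}

#' Summarise onset times per product and overall
#'
#' Median and interquartile range use Tukey's inclusive hinges (base
#' `fivenum()`), matching the integer-day quartiles conventionally
#' reported; the 30-day proportion counts day 30 as within. Strata with no
#' usable value are absent rather than zero.
#'
#' @param tto A [time_to_onset()] result.
#'
#' @return Tibble with rows per product plus `"Overall"`: `product`,
#'   `n_usable`, `n_excluded`, `median_days`, `q1`, `q3`,
#'   `prop_within_30d` (in `[0, 1]`).
#' @export
summarize_tto <- function(tto) {
  one <- function(df, label) {
    ok <- df$days[df$reason == "ok"]
    if (length(ok) == 0L) return(NULL)
    fn <- stats::fivenum(ok)
    tibble(product = label, n_usable = length(ok),
           n_excluded = sum(df$reason != "ok"),
           median_days = fn[3], q1 = fn[2], q3 = fn[4],
           prop_within_30d = mean(ok <= 30))
  }
  by_prod <- tto |>
    dplyr::filter(!is.na(.data$product)) |>
    dplyr::group_by(.data$product) |>
    dplyr::group_map(~ one(.x, .y$product)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(by_prod, one(tto, "Overall"))
}

#' Case-fatality proportion of pulmonary events per product
#'
#' Cases are pulmonary-event reports assigned to a product; deaths are
#' those with outcome code `DE`. The proportion is kept at full precision
#' (`fatality_pct` = 100 deaths / cases); display rounding is applied only
#' when writing report tables.
#'
#' @param cohort A [build_cohort()] result.
#'
#' @return Tibble with `product`, `pae_cases`, `deaths`, `fatality_pct`.
#' @export
fatality_by_drug <- function(cohort) {
  stopifnot(inherits(cohort, "cart_cohort"))
  cohort$reports |>
    dplyr::filter(.data$pae_flag, !is.na(.data$product)) |>
    dplyr::group_by(.data$product) |>
    dplyr::summarise(pae_cases = dplyr::n(),
                     deaths = sum(.data$death_flag),
                     .groups = "drop") |>
    dplyr::mutate(fatality_pct = 100 * .data$deaths / .data$pae_cases)
}

.age_stratum <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "Missing",
    age_years < 18 ~ "<18",
    age_years < 65 ~ ">=18, <65",
    TRUE ~ ">=65")
}

#' Cohort demographics, pulmonary subset against the full cohort
#'
#' Counts and percentages (over the respective column total) for sex, age
#' strata, median age with inclusive-hinge IQR, the top five reporting
#' countries plus Other, and reporter classes — for the pulmonary-event
#' subset and the whole cohort.
#'
#' @param cohort A [build_cohort()] result.
#' @param top_countries Number of named countries before "Other" (5).
#'
#' @return Tibble with `characteristic`, `level`, `n_pae`, `pct_pae`,
#'   `n_total`, `pct_total`. Age summary rows (`median`, `q1`, `q3`) carry
#'   the years in the `n_*` columns and `NA` percentages.
#' @export
demographics_table <- function(cohort, top_countries = 5) {
  stopifnot(inherits(cohort, "cart_cohort"))
  rp <- cohort$reports
  pae <- rp[rp$pae_flag, , drop = FALSE]

  count_levels <- function(x, levels) {
    x <- ifelse(is.na(x), "Missing", x)
    unname(vapply(levels, function(l) sum(x == l), integer(1)))
  }
  block <- function(characteristic, levels, x_pae, x_all) {
    n1 <- count_levels(x_pae, levels)
    n2 <- count_levels(x_all, levels)
    tibble(characteristic = characteristic, level = levels,
           n_pae = as.double(n1), pct_pae = 100 * n1 / nrow(pae),
           n_total = as.double(n2), pct_total = 100 * n2 / nrow(rp))
  }

  sex_lab <- function(x) dplyr::recode(x, F = "Female", M = "Male")
  out <- block("sex", c("Female", "Male", "Missing"),
               sex_lab(pae$sex), sex_lab(rp$sex))

  out <- dplyr::bind_rows(
    out,
    block("age", c("<18", ">=18, <65", ">=65", "Missing"),
          .age_stratum(pae$age_years), .age_stratum(rp$age_years)))
  age_summary <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) rep(NA_real_, 3) else stats::fivenum(x)[c(3, 2, 4)]
  }
  s1 <- age_summary(pae$age_years); s2 <- age_summary(rp$age_years)
  out <- dplyr::bind_rows(
    out,
    tibble(characteristic = "age_summary", level = c("median", "q1", "q3"),
           n_pae = s1, pct_pae = NA_real_,
           n_total = s2, pct_total = NA_real_))

  top <- pae |>
    dplyr::filter(!is.na(.data$country)) |>
    dplyr::count(.data$country, sort = TRUE) |>
    dplyr::slice_head(n = top_countries) |>
    dplyr::pull(.data$country)
  country_lab <- function(x) ifelse(is.na(x) | !x %in% top, "Other", x)
  out <- dplyr::bind_rows(
    out,
    block("country", c(top, "Other"),
          country_lab(pae$country), country_lab(rp$country)))

  hcp <- c("physician", "pharmacist", "other health-professional")
  rep_lab <- function(x) ifelse(is.na(x), "Missing", x)
  hcp_row <- tibble(
    characteristic = "reporter", level = "healthcare professional",
    n_pae = as.double(sum(pae$reporter_class %in% hcp)),
    pct_pae = 100 * sum(pae$reporter_class %in% hcp) / nrow(pae),
    n_total = as.double(sum(rp$reporter_class %in% hcp)),
    pct_total = 100 * sum(rp$reporter_class %in% hcp) / nrow(rp))
  out <- dplyr::bind_rows(
    out, hcp_row,
    block("reporter", c(hcp, "consumer", "Missing"),
          rep_lab(pae$reporter_class), rep_lab(rp$reporter_class)))
  out
}

#' Pulmonary-event report counts per FDA receipt year
#'
#' Years are taken from the FDA receipt date, the only date universally
#' present in FAERS; reports without a parseable receipt year are excluded
#' and counted in the `n_excluded` attribute.
#'
#' @param cohort A [build_cohort()] result.
#'
#' @return Tibble with `year`, `n_pae_reports`, `n_reports` (all cohort
#'   reports that year), attribute `n_excluded`.
#' @export
counts_by_year <- function(cohort) {
  stopifnot(inherits(cohort, "cart_cohort"))
  rp <- cohort$reports
  usable <- !is.na(rp$fda_year)
  out <- rp[usable, , drop = FALSE] |>
    dplyr::group_by(year = .data$fda_year) |>
    dplyr::summarise(n_pae_reports = sum(.data$pae_flag),
                     n_reports = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$year)
  attr(out, "n_excluded") <- sum(!usable)
  out
}
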