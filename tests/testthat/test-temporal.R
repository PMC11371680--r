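make_tto_cohort <- function(event_dts, start_dts, products = NULL) {
  n <- length(event_dts)
  products <- products %||% rep("Axi-cel", n)
  reports <- tibble::tibble(
    primaryid = as.character(seq_len(n)),
    product = products, products = as.list(products),
    pae_flag = TRUE, death_flag = FALSE, serious_flag = FALSE,
    sex = "M", age_years = 50, country = "US",
    reporter_class = "physician", fda_dt = "20220101",
    fda_date = as.Date("2022-01-01"), fda_year = 2022L,
    event_dt = event_dts, caseid = as.character(seq_len(n)))
  cohort <- structure(list(
    reports = reports,
    events = tibble::tibble(primaryid = reports$primaryid, pt = "Hypoxia",
                            soc = pae_soc(), is_pae = TRUE),
    background_events = tibble::tibble(primaryid = character(0),
                                       pt = character(0)),
    matched_drugs = tibble::tibble(primaryid = reports$primaryid,
                                   drug_seq = 1L, product = products),
    counters = list()), class = "cart_cohort")
  ther <- tibble::tibble(primaryid = as.character(seq_len(n)),
                         dsg_drug_seq = 1L, start_dt = start_dts,
                         end_dt = NA_character_)
  list(cohort = cohort, ther = ther)
}

test_that("onset days subtract dates, excluding partial, missing and negative", {
  fx <- make_tto_cohort(
    event_dts = c("20200105", "20191230", "20200105", NA, "202001",
                  "20200110"),
    start_dts = c("20200101", "20200101", "202001", "20200101", "20200101",
                  "20200101"))
  tto <- time_to_onset(fx$cohort, fx$ther)
  tto <- tto[order(as.integer(tto$primaryid)), ]
  expect_equal(tto$days[1], 4L)
  expect_equal(tto$reason,
               c("ok", "negative", "partial_start_date",
                 "missing_event_date", "partial_event_date", "ok"))
  expect_equal(tto$days[6], 9L)
})

test_that("earliest matched therapy start is used when several exist", {
  fx <- make_tto_cohort("20200110", "20200105")
  fx$ther <- dplyr::bind_rows(
    fx$ther,
    tibble::tibble(primaryid = "1", dsg_drug_seq = 1L,
                   start_dt = "20200101", end_dt = NA_character_))
  tto <- time_to_onset(fx$cohort, fx$ther)
  expect_equal(tto$days, 9L)
})

test_that("onset summaries use inclusive hinges and day-30 inclusion", {
  fx <- make_tto_cohort(
    event_dts = format(as.Date("2020-01-01") + c(1, 2, 2, 3, 10), "%Y%m%d"),
    start_dts = rep("20200101", 5))
  s <- summarize_tto(time_to_onset(fx$cohort, fx$ther))
  ov <- s[s$product == "Overall", ]
  expect_equal(ov$median_days, 2)       # sort-and-index oracle on [1,2,2,3,10]
  expect_equal(ov$q1, 2)
  expect_equal(ov$q3, 3)
  expect_equal(ov$prop_within_30d, 1)
  expect_equal(ov$n_usable, 5L)

  one <- summarize_tto(tibble::tibble(primaryid = "1", product = "Axi-cel",
                                      days = 5L, reason = "ok"))
  expect_equal(one$median_days[one$product == "Overall"], 5)
  expect_equal(one$q1[one$product == "Overall"], 5)
  expect_equal(one$q3[one$product == "Overall"], 5)

  # day 30 is inside, day 31 outside
  fx30 <- make_tto_cohort(
    event_dts = format(as.Date("2020-01-01") + c(30, 31), "%Y%m%d"),
    start_dts = rep("20200101", 2))
  s30 <- summarize_tto(time_to_onset(fx30$cohort, fx30$ther))
  expect_equal(s30$prop_within_30d[s30$product == "Overall"], 0.5)
})

test_that("onset summaries are permutation-invariant and drop empty strata", {
  withr::local_seed(77)
  days <- sample(0:60, 40, TRUE)
  t1 <- tibble::tibble(primaryid = as.character(1:40),
                       product = rep(c("A", "B"), 20),
                       days = days, reason = "ok")
  perm <- t1[sample(40), ]
  expect_equal(dplyr::arrange(summarize_tto(t1), product),
               dplyr::arrange(summarize_tto(perm), product))
  none <- tibble::tibble(primaryid = "1", product = "A", days = NA_integer_,
                         reason = "missing_event_date")
  expect_equal(nrow(summarize_tto(none)), 0L)
})

test_that("recovered onset median matches the generator's distribution", {
  cfg <- synth_config(seed = 321, n_background = 0,
                      product_counts = c("Axi-cel" = 10000),
                      signal_multipliers = tibble::tibble(
                        product = character(0), pt = character(0),
                        multiplier = numeric(0)),
                      duplicate_rate = 0, deletion_rate = 0,
                      event_dt_missing = 0, start_dt_missing = 0)
  g <- generate_faers(cfg)
  med <- stats::median(g$truth$onset_days, na.rm = TRUE)
  # theoretical log-normal median is exp(meanlog) = 2 days
  expect_lte(abs(med - 2), 1)
})

test_that("fatality rows divide deaths by cases at full precision", {
  reports <- tibble::tibble(
    primaryid = as.character(1:6), caseid = as.character(1:6),
    product = c("Tisa-cel", "Tisa-cel", "Tisa-cel", "Ide-cel", "Ide-cel",
                NA),
    products = as.list(c("Tisa-cel", "Tisa-cel", "Tisa-cel", "Ide-cel",
                         "Ide-cel", NA)),
    pae_flag = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    death_flag = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    serious_flag = TRUE, sex = "M", age_years = 50, country = "US",
    reporter_class = "physician", fda_dt = "20220101",
    fda_date = as.Date("2022-01-01"), fda_year = 2022L, event_dt = NA)
  co <- structure(list(reports = reports, counters = list()),
                  class = "cart_cohort")
  f <- fatality_by_drug(co)
  expect_equal(f$pae_cases[f$product == "Tisa-cel"], 3L)
  expect_equal(f$deaths[f$product == "Tisa-cel"], 2L)
  expect_equal(f$fatality_pct[f$product == "Tisa-cel"], 200 / 3)
  # no PAE cases for a product with only non-PAE reports -> absent row
  expect_equal(f$pae_cases[f$product == "Ide-cel"], 1L)
  expect_equal(f$fatality_pct[f$product == "Ide-cel"], 0)
  expect_true(all(f$deaths <= f$pae_cases))
})

test_that("demographics columns sum to their totals and strata split at 18/65", {
  g <- generate_faers(small_synth_config(seed = 5))
  co <- cohort_from_synth(g)
  dm <- demographics_table(co)
  n_pae <- sum(co$reports$pae_flag)
  sex <- dm[dm$characteristic == "sex", ]
  expect_equal(sum(sex$n_pae), n_pae)
  expect_equal(sum(sex$n_total), nrow(co$reports))
  expect_equal(sum(sex$pct_pae), 100)
  age <- dm[dm$characteristic == "age", ]
  expect_equal(sum(age$n_pae), n_pae)
  country <- dm[dm$characteristic == "country", ]
  expect_equal(sum(country$n_total), nrow(co$reports))

  expect_equal(cartpv:::.age_stratum(c(17, 17.99, 18, 64.99, 65, NA)),
               c("<18", "<18", ">=18, <65", ">=18, <65", ">=65", "Missing"))
})

test_that("annual counts bucket by receipt year and conserve totals", {
  g <- generate_faers(small_synth_config(seed = 13))
  co <- cohort_from_synth(g)
  yr <- counts_by_year(co)
  expect_equal(sum(yr$n_reports) + attr(yr, "n_excluded"),
               nrow(co$reports))
  expect_equal(sum(yr$n_pae_reports), sum(co$reports$pae_flag &
                                            !is.na(co$reports$fda_year)))
  expect_true(all(yr$year >= 2017 & yr$year <= 2023))
})
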