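test_that("drug matching is case-insensitive substring containment", {
  def <- toy_definition()
  expect_equal(match_drug("YESCARTA", definition = def), "Axi-cel")
  expect_equal(match_drug("Kymriah 50 mg suspension", definition = def),
               "Tisa-cel")
  expect_equal(match_drug("aspirin", definition = def), character(0))
  expect_equal(match_drug("  yesCARTA  injection ", definition = def),
               "Axi-cel")
  # ambiguous synonym hits both carriers
  expect_equal(match_drug("autoleucel", definition = def),
               c("Brexu-cel", "Cilta-cel"))
  # match via active ingredient only
  expect_equal(match_drug("unknown product", "tisagenlecleucel",
                          definition = def), "Tisa-cel")
})

test_that("SOC assignment is exact after case-folding, unmapped terms counted", {
  def <- toy_definition()
  soc <- assign_soc(c("Hypoxia", "HYPOXIA ", "Pyrexia", "Never seen", NA),
                    def)
  expect_equal(soc[1], pae_soc())
  expect_equal(soc[2], pae_soc())
  expect_equal(soc[3], "General disorders")
  expect_true(is.na(soc[4]))
  expect_equal(attr(soc, "n_unmapped"), 1L)
})

test_that("age normalisation converts every unit code to years", {
  expect_equal(normalize_age(6, "MON"), 0.5)
  expect_equal(normalize_age(6, "DEC"), 60)
  expect_equal(normalize_age(730.5, "DY"), 2)
  expect_equal(normalize_age(52.18, "WK"), 1)
  expect_equal(normalize_age(8766, "HR"), 1)
  expect_equal(normalize_age(59, "YR"), 59)
  expect_equal(normalize_age(59, NA), 59)  # missing code -> years
  expect_warning(res <- normalize_age(-1, "YR"), "negative")
  expect_true(is.na(res))
  expect_true(is.na(normalize_age(NA, "YR")))
})

test_that("reporter codes classify into the published classes", {
  expect_equal(classify_reporter(c("MD", "PH", "OT", "CN", "LW")),
               c("physician", "pharmacist", "other health-professional",
                 "consumer", "consumer"))
  expect_true(is.na(classify_reporter("")))
  expect_true(is.na(classify_reporter(NA)))
  expect_warning(res <- classify_reporter("XX"), "unknown")
  expect_true(is.na(res))
})

test_that("cohort and background partition the reports; flags follow outcomes", {
  demo <- tibble::tibble(
    primaryid = as.character(1:10), caseid = as.character(1:10),
    fda_dt = "20210501", event_dt = NA_character_,
    age = c(6, 59, NA, 70, 17, 30, 40, 50, 60, 80),
    age_cod = c("DEC", "YR", NA, "YR", "YR", "YR", "YR", "YR", "YR", "YR"),
    sex = c("M", "F", "UNK", "M", "F", "M", "F", "M", "F", "M"),
    occp_cod = c("MD", "PH", "LW", NA, "CN", "MD", "MD", "OT", "PH", "MD"),
    occr_country = c("US", NA, "FR", "US", "US", "DE", "US", "US", "FR", "US"),
    reporter_country = c("US", "GB", "FR", "US", "US", "DE", "US", "US", "FR", "US"))
  drug <- tibble::tibble(
    primaryid = c("1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "1"),
    drug_seq = c(rep(1L, 10), 2L),
    role_cod = c("PS", "PS", "SS", "C", rep("PS", 6), "C"),
    drugname = c("YESCARTA", "Kymriah", "tecartus", "BREYANZI", "aspirin",
                 "ibuprofen", "metformin", "aspirin", "aspirin", "aspirin",
                 "aspirin"),
    prod_ai = NA_character_)
  reac <- tibble::tibble(
    primaryid = c("1", "1", "2", "3", "5", "6", "7", "8", "9", "10"),
    pt = c("Hypoxia", "Pyrexia", "Respiratory failure", "Nausea", "Hypoxia",
           "Pyrexia", "Nausea", "Hypoxia", "Pyrexia", "Nausea"))
  outc <- tibble::tibble(primaryid = c("1", "2", "3"),
                         outc_cod = c("DE", "HO", "OT"))

  co <- build_cohort(demo, drug, reac, outc, toy_definition())
  # report 4 carries a product only as concomitant -> excluded
  expect_setequal(co$reports$primaryid, c("1", "2", "3"))
  expect_equal(co$counters$n_background, 7L)
  expect_setequal(unique(co$background_events$primaryid),
                  c("5", "6", "7", "8", "9", "10"))
  expect_equal(co$counters$n_events + co$counters$n_background_events,
               nrow(reac))

  r <- co$reports[order(co$reports$primaryid), ]
  expect_equal(r$product, c("Axi-cel", "Tisa-cel", "Brexu-cel"))
  expect_equal(r$pae_flag, c(TRUE, TRUE, FALSE))
  expect_equal(r$death_flag, c(TRUE, FALSE, FALSE))
  expect_equal(r$serious_flag, c(TRUE, TRUE, FALSE))
  expect_equal(r$age_years, c(60, 59, NA))
  expect_true(is.na(r$sex[3]))                 # UNK folded into missing
  expect_equal(r$country, c("US", "GB", "FR")) # occr with reporter fallback
  expect_equal(r$reporter_class, c("physician", "pharmacist", "consumer"))

  # counting units: events are (report, PT) pairs, reports counted once
  expect_equal(co$counters$n_events, 4L)
  expect_equal(co$counters$n_pae_events, 2L)
  expect_equal(co$counters$n_pae_reports, 2L)
})

test_that("ambiguous product assignment keeps the report but no product", {
  demo <- tibble::tibble(primaryid = c("1", "2"), caseid = c("1", "2"),
                         fda_dt = "20220101", event_dt = NA,
                         age = NA_real_, age_cod = NA, sex = "M",
                         occp_cod = "MD", occr_country = "US",
                         reporter_country = "US")
  drug <- tibble::tibble(
    primaryid = c("1", "2"), drug_seq = 1L, role_cod = "PS",
    drugname = c("autoleucel", "brexucabtagene autoleucel"),
    prod_ai = NA_character_)
  reac <- tibble::tibble(primaryid = c("1", "2"), pt = "Hypoxia")
  co <- build_cohort(demo, drug, reac, tibble::tibble(
    primaryid = character(0), outc_cod = character(0)), toy_definition())
  r <- co$reports[order(co$reports$primaryid), ]
  expect_true(is.na(r$product[1]))
  expect_equal(r$products[[1]], c("Brexu-cel", "Cilta-cel"))
  # the longer synonym disambiguates report 2
  expect_equal(r$product[2], "Brexu-cel")
  expect_equal(co$counters$n_ambiguous_product, 1L)
})

test_that("an empty cohort is a hard error advising a dictionary check", {
  demo <- tibble::tibble(primaryid = "1", caseid = "1", fda_dt = "20220101",
                         event_dt = NA, age = NA_real_, age_cod = NA,
                         sex = "M", occp_cod = "MD", occr_country = "US",
                         reporter_country = "US")
  drug <- tibble::tibble(primaryid = "1", drug_seq = 1L, role_cod = "PS",
                         drugname = "aspirin", prod_ai = NA_character_)
  reac <- tibble::tibble(primaryid = "1", pt = "Nausea")
  expect_error(
    build_cohort(demo, drug, reac,
                 tibble::tibble(primaryid = character(0),
                                outc_cod = character(0)),
                 toy_definition()),
    "dictionary")
})

test_that("cohort membership is invariant to synonym case and surrounding text", {
  withr::local_seed(31)
  base <- c("kymriah", "KYMRIAH", "Kymriah 50mg", "  kymRIAH suspension ")
  for (name in base) {
    expect_equal(match_drug(name, definition = toy_definition()),
                 "Tisa-cel", info = name)
  }
})
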