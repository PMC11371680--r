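#' Deterministic reference fixture reproducing published marginal counts
#'
#' Builds (and optionally writes) a fully deterministic synthetic
#' FAERS-format package whose post-deduplication CAR-T cohort reproduces
#' the marginal counts reported for pulmonary adverse events after CAR-T
#' therapy in FAERS 2017Q1–2023Q3: 9,400 adverse-event records of which
#' 940 (10%) are pulmonary; per-product pulmonary case and death counts
#' (Tisa-cel 367/160, Axi-cel 406/141, Brexu-cel 82/23, Liso-cel 27/9,
#' Ide-cel 32/6, Cilta-cel 26/13); the pulmonary-column demographics
#' (538 male, 350 female, 52 missing; 602 United States reports; reporter
#' and age-stratum counts with median age 59, IQR 30–69); and per-product
#' hypoxia (344 total) and respiratory-failure (127 total) report counts.
#'
#' Every cohort report carries exactly one reaction, so record counts and
#' report counts coincide and the record totals and the per-report
#' demographic columns are reproduced simultaneously. All quantities never
#' published — the per-product split of non-pulmonary reports, the
#' background database, all dates, onset times and the resulting
#' contingency cells b, c, d — are synthetic deterministic choices:
#' statistics derived from them are properties of this fixture, not
#' published values. A small number of duplicate revisions and deleted
#' background cases are included so the deduplication stage is exercised
#' without touching the cohort marginals.
#'
#' @param dir Output directory; `NULL` keeps the package in memory.
#'
#' @return Object of class `faers_synth` (no planted multiplicative
#'   signals; `signal_truth` is empty).
#' @export
cart_reference_fixture <- function(dir = NULL) {
  prods <- c("Tisa-cel", "Axi-cel", "Brexu-cel", "Liso-cel", "Ide-cel",
             "Cilta-cel")
  pae_cases <- c(367, 406, 82, 27, 32, 26)
  pae_deaths <- c(160, 141, 23, 9, 6, 13)
  names(pae_cases) <- names(pae_deaths) <- prods

  # per-product pulmonary PT composition; hypoxia and respiratory failure
  # rows match the published per-product and total counts, the remainder
  # is a synthetic split over the other pulmonary terms
  pae_plan <- list(
    "Tisa-cel" = c("Hypoxia" = 158, "Respiratory failure" = 50,
                   "Pleural effusion" = 60, "Tachypnoea" = 40,
                   "Acute respiratory distress syndrome" = 30,
                   "Pulmonary oedema" = 29),
    "Axi-cel" = c("Hypoxia" = 143, "Respiratory failure" = 50,
                  "Tachypnoea" = 80, "Pleural effusion" = 70,
                  "Pulmonary oedema" = 63),
    "Brexu-cel" = c("Hypoxia" = 25, "Respiratory failure" = 10,
                    "Pleural effusion" = 30, "Tachypnoea" = 17),
    "Liso-cel" = c("Hypoxia" = 6, "Respiratory failure" = 5,
                   "Pleural effusion" = 16),
    "Ide-cel" = c("Hypoxia" = 12, "Respiratory failure" = 2,
                  "Tachypnoea" = 18),
    "Cilta-cel" = c("Respiratory failure" = 10, "Pleural effusion" = 16))
  stopifnot(all(vapply(prods, function(p) sum(pae_plan[[p]]), numeric(1)) ==
                  pae_cases))

  # ---- pulmonary cohort reports (940) --------------------------------
  pae_product <- rep(prods, pae_cases)
  pae_pt <- unlist(lapply(prods, function(p)
    rep(names(pae_plan[[p]]), pae_plan[[p]])), use.names = FALSE)
  pae_death <- unlist(lapply(prods, function(p)
    c(rep(TRUE, pae_deaths[[p]]), rep(FALSE, pae_cases[[p]] -
                                        pae_deaths[[p]]))))
  n_pae <- length(pae_product)

  pae_sex <- rep(c("M", "F", NA), c(538, 350, 52))
  # "Other" spread thinly over many countries so none outranks the five
  # named reporting countries
  other_codes <- c("GB", "JP", "CA", "AU", "BR", "CN", "IN", "KR", "NL",
                   "SE", "CH", "BE", "AT", "DK", "NO", "FI", "PL", "PT",
                   "IE", "GR", "CZ", "HU", "RO", "IL", "MX", "AR", "CL",
                   "CO", "ZA", "EG", "SA", "AE", "TR", "RU", "UA", "TH",
                   "SG", "MY", "NZ", "PH", "VN", "ID", "TW")
  pae_country <- rep(c("US", "FR", "ES", "DE", "IT",
                       rep(other_codes, length.out = 257)),
                     c(602, 32, 16, 26, 7, rep(1, 257)))
  pae_occp <- rep(c("MD", "PH", "OT", "CN", NA), c(391, 307, 96, 72, 74))

  # 817 non-missing ages engineered so the stratum counts are 132 / 383 /
  # 302 and the inclusive-hinge summary is median 59, IQR (30, 69)
  ages <- c(rep(c(2, 5, 8, 11, 14, 16), 22),                      # 132 < 18
            rep(c(18, 20, 22, 25, 27, 29), 12),                   # 72
            30,                                                   # lower hinge
            sort(rep(30:58, length.out = 203)),
            59,                                                   # median
            sort(rep(59:64, length.out = 106)),                   # to 515
            rep(65:68, each = 24), 69, 69,                        # upper hinge
            sort(rep(70:88, length.out = 204)))
  stopifnot(length(ages) == 817)
  pae_age <- c(sort(ages), rep(NA, 123))

  # ---- non-pulmonary cohort reports (8,460) --------------------------
  npae_counts <- 9 * pae_cases                   # synthetic per-product split
  np_product <- rep(prods, npae_counts)
  n_np <- length(np_product)
  np_pt <- rep(c("Pyrexia", "Nausea", "Fatigue", "Headache", "Diarrhoea",
                 "Cytokine release syndrome", "Hypotension", "Anaemia"),
               length.out = n_np)
  np_sex <- rep(c("F", "M", NA), c(2503, 4133, 1824))
  np_country <- rep(c("US", "FR", "ES", "DE", "IT",
                      rep(other_codes, length.out = 1915)),
                    c(5419, 359, 279, 265, 223, rep(1, 1915)))
  np_occp <- rep(c("MD", "PH", "OT", "CN", NA),
                 c(3288, 2954, 720, 893, 605))
  np_age <- rep(c(10, 42, 55, 63, 70, 78, NA),
                c(445, 1000, 1000, 895, 1200, 994, 2926))

  co_product <- c(pae_product, np_product)
  co_pt <- c(pae_pt, np_pt)
  co_death <- c(pae_death, rep(FALSE, n_np))
  co_sex <- c(pae_sex, np_sex)
  co_country <- c(pae_country, np_country)
  co_occp <- c(pae_occp, np_occp)
  co_age <- c(pae_age, np_age)
  n_co <- length(co_product)                      # 9,400

  # receipt years rising 2017..2023, striped across the cohort so every
  # stratum spans the window (7919 is coprime with 9400)
  years_sorted <- rep(2017:2023, c(200, 500, 800, 1200, 1600, 2200, 2900))
  stripe <- (seq_len(n_co) * 7919L) %% n_co + 1L
  co_year <- integer(n_co)
  co_year[stripe] <- years_sorted
  co_month <- (seq_len(n_co) %% 9L) + 1L          # Q1..Q3 only
  co_day <- (seq_len(n_co) %% 27L) + 1L
  co_fda <- as.Date(sprintf("%d-%02d-%02d", co_year, co_month, co_day))

  # onset-day pattern: 94 cycles over 940 pulmonary reports giving median
  # 2, inclusive hinges (1, 7) and 90% of onsets within 30 days
  onset_pattern <- c(1, 1, 1, 2, 2, 2, 7, 7, 25, 45)
  pae_onset <- rep(onset_pattern, length.out = n_pae)
  co_onset <- c(pae_onset, rep(NA, n_np))
  co_event <- co_fda - 7
  co_start <- co_event - ifelse(is.na(co_onset), 0, co_onset)

  co_caseid <- as.character(10000000 + seq_len(n_co))
  co_pid <- paste0(co_caseid, "9")

  demo_co <- tibble(
    primaryid = co_pid, caseid = co_caseid, fda_dt = .fmt_dt(co_fda),
    event_dt = ifelse(is.na(co_onset), NA, .fmt_dt(co_event)),
    age = co_age, age_cod = ifelse(is.na(co_age), NA, "YR"),
    sex = co_sex, occp_cod = co_occp,
    occr_country = co_country, reporter_country = co_country)
  drug_co <- tibble(
    primaryid = co_pid, drug_seq = 1L, role_cod = "PS",
    drugname = unname(.product_trade_names[co_product]),
    prod_ai = unname(.product_generic_names[co_product]))
  reac_co <- tibble(primaryid = co_pid, pt = co_pt)
  outc_co <- dplyr::bind_rows(
    tibble(primaryid = co_pid[co_death], outc_cod = "DE"),
    tibble(primaryid = co_pid[!co_death & c(rep(TRUE, n_pae),
                                            rep(FALSE, n_np))],
           outc_cod = "HO"))
  ther_co <- tibble(primaryid = co_pid[!is.na(co_onset)],
                    dsg_drug_seq = 1L,
                    start_dt = .fmt_dt(co_start[!is.na(co_onset)]),
                    end_dt = NA_character_)

  # ---- background reports (1,200; synthetic) -------------------------
  n_bg <- 1200L
  bg_caseid <- as.character(20000000 + seq_len(n_bg))
  bg_pid <- paste0(bg_caseid, "9")
  cat_pts <- synth_pt_catalogue()$pt
  bg_pt <- rep(cat_pts, length.out = n_bg)
  bg_year <- rep(2017:2023, length.out = n_bg)
  bg_fda <- as.Date(sprintf("%d-%02d-%02d", bg_year,
                            (seq_len(n_bg) %% 9L) + 1L,
                            (seq_len(n_bg) %% 27L) + 1L))
  demo_bg <- tibble(
    primaryid = bg_pid, caseid = bg_caseid, fda_dt = .fmt_dt(bg_fda),
    event_dt = NA_character_, age = rep(c(35, 55, 72, NA),
                                        length.out = n_bg),
    age_cod = rep(c("YR", "YR", "YR", NA), length.out = n_bg),
    sex = rep(c("F", "M"), length.out = n_bg),
    occp_cod = rep(c("MD", "PH", "CN"), length.out = n_bg),
    occr_country = rep(c("US", "GB", "FR"), length.out = n_bg),
    reporter_country = rep(c("US", "GB", "FR"), length.out = n_bg))
  drug_bg <- tibble(
    primaryid = bg_pid, drug_seq = 1L, role_cod = "PS",
    drugname = rep(.background_drugs, length.out = n_bg),
    prod_ai = NA_character_)
  reac_bg <- tibble(primaryid = bg_pid, pt = bg_pt)

  # duplicate revisions and deletions confined to the background
  dup_idx <- seq_len(20L)
  dup_demo <- demo_bg[dup_idx, , drop = FALSE]
  dup_demo$primaryid <- paste0(bg_caseid[dup_idx], "1")
  dup_demo$fda_dt <- .fmt_dt(pmax(bg_fda[dup_idx] - 60,
                                  as.Date("2017-01-01")))
  del_idx <- which(bg_year >= 2019)[seq_len(10L)]
  deleted <- tibble(caseid = bg_caseid[del_idx],
                    quarter = quarter_label(bg_fda[del_idx]))

  tables <- list(
    demo = dplyr::bind_rows(demo_co, demo_bg, dup_demo),
    drug = dplyr::bind_rows(drug_co, drug_bg,
                            dplyr::mutate(drug_bg[dup_idx, ],
                                          primaryid = dup_demo$primaryid)),
    reac = dplyr::bind_rows(reac_co, reac_bg,
                            dplyr::mutate(reac_bg[dup_idx, ],
                                          primaryid = dup_demo$primaryid)),
    outc = outc_co,
    ther = ther_co,
    indi = empty_faers_table("indi"))

  truth <- tibble(
    caseid = c(co_caseid, bg_caseid),
    survivor_primaryid = c(co_pid, bg_pid),
    deleted = c(co_caseid, bg_caseid) %in% deleted$caseid,
    product = c(co_product, rep(NA_character_, n_bg)),
    pts = as.list(c(co_pt, bg_pt)),
    pae = c(rep(c(TRUE, FALSE), c(n_pae, n_np)), rep(FALSE, n_bg)),
    death = c(co_death, rep(FALSE, n_bg)),
    onset_days = as.integer(c(co_onset, rep(NA, n_bg))))

  if (!is.null(dir)) write_faers_package(tables, dir, deleted)

  structure(list(
    tables = tables, deleted = deleted, truth = truth,
    signal_truth = tibble(product = character(0), pt = character(0),
                          multiplier = numeric(0)),
    config = NULL, dir = dir), class = "faers_synth")
}
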