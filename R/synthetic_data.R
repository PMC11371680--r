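#' Default event catalogue for the synthetic generator
#'
#' A small catalogue of preferred terms with SOC labels and relative
#' background reporting weights: six pulmonary terms and fourteen common
#' non-pulmonary terms. The packaged synthetic PT-to-SOC mapping covers
#' exactly these terms.
#'
#' @return Tibble with `pt`, `soc`, `weight`.
#' @export
synth_pt_catalogue <- function() {
  resp <- pae_soc()
  tibble::tribble(
    ~pt,                                   ~soc,                               ~weight,
    "Hypoxia",                             resp,                               1,
    "Respiratory failure",                 resp,                               1,
    "Tachypnoea",                          resp,                               1,
    "Pleural effusion",                    resp,                               1,
    "Pulmonary oedema",                    resp,                               1,
    "Acute respiratory distress syndrome", resp,                               1,
    "Pyrexia",                             "General disorders and administration site conditions", 1,
    "Fatigue",                             "General disorders and administration site conditions", 1,
    "Nausea",                              "Gastrointestinal disorders",       1,
    "Vomiting",                            "Gastrointestinal disorders",       1,
    "Diarrhoea",                           "Gastrointestinal disorders",       1,
    "Headache",                            "Nervous system disorders",         1,
    "Tremor",                              "Nervous system disorders",         1,
    "Confusional state",                   "Psychiatric disorders",            1,
    "Cytokine release syndrome",           "Immune system disorders",          1,
    "Hypotension",                         "Vascular disorders",               1,
    "Anaemia",                             "Blood and lymphatic system disorders", 1,
    "Neutropenia",                         "Blood and lymphatic system disorders", 1,
    "Rash",                                "Skin and subcutaneous tissue disorders", 1,
    "Oedema peripheral",                   "General disorders and administration site conditions", 1
  )
}

.product_trade_names <- c(
  "Axi-cel" = "YESCARTA", "Tisa-cel" = "KYMRIAH", "Brexu-cel" = "TECARTUS",
  "Liso-cel" = "BREYANZI", "Ide-cel" = "ABECMA", "Cilta-cel" = "CARVYKTI")
.product_generic_names <- c(
  "Axi-cel" = "axicabtagene ciloleucel", "Tisa-cel" = "tisagenlecleucel",
  "Brexu-cel" = "brexucabtagene autoleucel",
  "Liso-cel" = "lisocabtagene maraleucel",
  "Ide-cel" = "idecabtagene vicleucel",
  "Cilta-cel" = "ciltacabtagene autoleucel")
.background_drugs <- c("ASPIRIN", "METFORMIN", "IBUPROFEN", "ATORVASTATIN",
                       "OMEPRAZOLE", "LISINOPRIL", "AMOXICILLIN")

#' Configuration for the synthetic FAERS generator
#'
#' Defaults describe the study conditions the generator emulates: a CAR-T
#' cohort dominated by Axi-cel and Tisa-cel against a smaller spontaneous-
#' report background, multiplicatively planted drug–event signals,
#' FDA-style duplicate revisions and deletion lists, demographic mixes
#' approximating the observed CAR-T reporting population, a log-normal
#' onset distribution with median 2 days and roughly 90% of onsets within
#' 30 days, and receipt dates spanning 2017-01-01 to 2023-09-30.
#'
#' @param seed Mandatory integer seed.
#' @param n_background Background (non-CAR-T) report count.
#' @param product_counts Named integer vector of cohort reports per product.
#' @param signal_multipliers Tibble `product`, `pt`, `multiplier`: relative
#'   reporting-rate multipliers versus background (`> 1` plants a signal).
#' @param pt_catalogue Event catalogue, see [synth_pt_catalogue()].
#' @param events_lambda Each report carries `1 + Poisson(events_lambda)`
#'   distinct reactions.
#' @param duplicate_rate Probability in `[0, 1)` that a case carries one
#'   superseded duplicate revision.
#' @param deletion_rate Probability that an eligible case (receipt quarter
#'   2019Q1 or later) lands on its quarter's deletion list.
#' @param death_prob Named vector `c(pae = , other = )`: death-outcome
#'   probability for cohort reports with/without a pulmonary event.
#' @param onset_meanlog,onset_sdlog Log-normal onset-time parameters (days).
#' @param event_dt_missing,start_dt_missing Missingness rates of the event
#'   onset and therapy start dates.
#' @param window Character vector of two dates bounding FDA receipt dates.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_background = 5000,
                         product_counts = c("Axi-cel" = 400, "Tisa-cel" = 350,
                                            "Brexu-cel" = 80, "Liso-cel" = 30,
                                            "Ide-cel" = 30, "Cilta-cel" = 25),
                         signal_multipliers = tibble::tribble(
                           ~product,   ~pt,                   ~multiplier,
                           "Axi-cel",  "Hypoxia",             10,
                           "Axi-cel",  "Tachypnoea",          6,
                           "Tisa-cel", "Hypoxia",             10,
                           "Tisa-cel", "Respiratory failure", 4),
                         pt_catalogue = synth_pt_catalogue(),
                         events_lambda = 0.6,
                         duplicate_rate = 0.10,
                         deletion_rate = 0.02,
                         death_prob = c(pae = 0.35, other = 0.10),
                         onset_meanlog = log(2),
                         onset_sdlog = 2,
                         event_dt_missing = 0.10,
                         start_dt_missing = 0.10,
                         window = c("2017-01-01", "2023-09-30")) {
  if (missing(seed) || is.null(seed)) abort("A seed is mandatory.")
  stopifnot(n_background >= 0, all(product_counts >= 0),
            duplicate_rate >= 0, duplicate_rate < 1,
            deletion_rate >= 0, deletion_rate <= 1,
            all(death_prob >= 0 & death_prob <= 1),
            all(c("pae", "other") %in% names(death_prob)),
            event_dt_missing >= 0, event_dt_missing <= 1,
            start_dt_missing >= 0, start_dt_missing <= 1,
            events_lambda >= 0, onset_sdlog > 0)
  if (!all(signal_multipliers$pt %in% pt_catalogue$pt)) {
    abort("Every signal multiplier PT must occur in the catalogue.")
  }
  if (!all(signal_multipliers$product %in% names(product_counts))) {
    abort("Every signal multiplier product must have a report count.")
  }
  structure(list(
    seed = as.integer(seed), n_background = as.integer(n_background),
    product_counts = product_counts, signal_multipliers = signal_multipliers,
    pt_catalogue = pt_catalogue, events_lambda = events_lambda,
    duplicate_rate = duplicate_rate, deletion_rate = deletion_rate,
    death_prob = death_prob, onset_meanlog = onset_meanlog,
    onset_sdlog = onset_sdlog, event_dt_missing = event_dt_missing,
    start_dt_missing = start_dt_missing,
    window = as.Date(window)), class = "synth_config")
}

.fmt_dt <- function(date) format(date, "%Y%m%d")

#' Generate a seeded synthetic FAERS-format package with ground truth
#'
#' Draws a spontaneous-report database under the configured conditions and
#' (optionally) writes it to disk as FAERS quarterly ASCII packages —
#' "$"-delimited DEMO/DRUG/REAC/OUTC/THER/INDI tables split by receipt
#' quarter, with deletion lists from 2019Q1 on. Duplicate revisions share a
#' CASEID with a distinct, lower PRIMARYID and an earlier-or-equal receipt
#' date, so the intended survivor always wins under the FDA rule; deleted
#' cases are listed in their own receipt quarter. Runs with the same
#' configuration are byte-identical.
#'
#' @param config A [synth_config()].
#' @param dir Output directory; `NULL` keeps the package in memory only.
#'
#' @return Object of class `faers_synth`: list with `tables` (the six
#'   tibbles, including duplicate revisions), `deleted` (tibble `caseid`,
#'   `quarter`), `truth` (per-case ground truth: survivor primaryid,
#'   deletion flag, product, reaction list, pulmonary/death indicators,
#'   onset days) and `signal_truth` (the planted `(product, pt)` pairs),
#'   plus `dir` when written.
#' @export
generate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    n_bg <- config$n_background
    products <- rep(names(config$product_counts), config$product_counts)
    n_co <- length(products)
    n <- n_bg + n_co
    if (n == 0L) abort("Configuration generates no reports.")
    product <- c(rep(NA_character_, n_bg), products)
    is_cohort <- !is.na(product)

    caseid <- as.character(90000000 + seq_len(n))
    primaryid <- paste0(caseid, "9")

    # demographics approximating the observed reporting population
    sex <- sample(c("F", "M", NA), n, TRUE, prob = c(0.31, 0.50, 0.19))
    age <- round(pmin(pmax(stats::rnorm(n, 58, 20), 0.5), 95), 1)
    age[stats::runif(n) < 0.15] <- NA
    age_cod <- ifelse(is.na(age), NA, "YR")
    country <- sample(c("US", "FR", "ES", "DE", "IT", "GB", "JP", "CA"), n,
                      TRUE, prob = c(0.64, 0.04, 0.03, 0.03, 0.02, 0.09,
                                     0.08, 0.07))
    occp <- sample(c("MD", "PH", "OT", "CN", NA), n, TRUE,
                   prob = c(0.39, 0.34, 0.09, 0.11, 0.07))

    window_days <- as.integer(config$window[2] - config$window[1])
    fda_date <- config$window[1] +
      sample.int(window_days + 1L, n, TRUE) - 1L

    # reactions: weighted sampling without replacement per report, cohort
    # weights multiplied by the planted (product, pt) multipliers
    cat <- config$pt_catalogue
    # per-product weight vectors with the planted multipliers applied
    weights <- list(.background = cat$weight)
    for (p in names(config$product_counts)) {
      w <- cat$weight
      sm <- config$signal_multipliers[config$signal_multipliers$product == p, ]
      w[match(sm$pt, cat$pt)] <- w[match(sm$pt, cat$pt)] * sm$multiplier
      weights[[p]] <- w
    }
    n_pt <- pmin(1L + stats::rpois(n, config$events_lambda), nrow(cat))
    wkey <- ifelse(is_cohort, product, ".background")
    pts <- vector("list", n)
    for (i in seq_len(n)) {
      pts[[i]] <- sample(cat$pt, n_pt[i], prob = weights[[wkey[i]]])
    }
    pae_soc_norm <- norm_text(pae_soc())
    soc_of <- stats::setNames(cat$soc, cat$pt)
    is_pae <- vapply(pts, function(p)
      any(norm_text(soc_of[p]) == pae_soc_norm), logical(1))

    # outcomes
    death <- stats::runif(n) <
      ifelse(is_cohort & is_pae, config$death_prob[["pae"]],
             config$death_prob[["other"]])
    hosp <- !death & stats::runif(n) < 0.3

    # onset and dates (cohort only)
    onset <- ifelse(is_cohort,
                    round(stats::rlnorm(n, config$onset_meanlog,
                                        config$onset_sdlog)), NA)
    event_date <- fda_date - sample.int(30L, n, TRUE)
    start_date <- event_date - ifelse(is.na(onset), 0, onset)
    event_miss <- stats::runif(n) < config$event_dt_missing
    start_miss <- stats::runif(n) < config$start_dt_missing

    demo <- tibble(
      primaryid = primaryid, caseid = caseid,
      fda_dt = .fmt_dt(fda_date),
      event_dt = ifelse(is_cohort & !event_miss, .fmt_dt(event_date), NA),
      age = age, age_cod = age_cod, sex = sex, occp_cod = occp,
      occr_country = country, reporter_country = country)

    co_idx <- which(is_cohort)
    bg_idx <- which(!is_cohort)
    bg_second <- bg_idx[sample(c(TRUE, FALSE), length(bg_idx), TRUE)]
    drug_rows <- dplyr::bind_rows(
      tibble(primaryid = primaryid[co_idx], drug_seq = 1L, role_cod = "PS",
             drugname = unname(.product_trade_names[product[co_idx]]),
             prod_ai = unname(.product_generic_names[product[co_idx]])),
      tibble(primaryid = primaryid[bg_idx], drug_seq = 1L, role_cod = "PS",
             drugname = sample(.background_drugs, length(bg_idx), TRUE),
             prod_ai = NA_character_),
      tibble(primaryid = primaryid[bg_second], drug_seq = 2L,
             role_cod = "C",
             drugname = sample(.background_drugs, length(bg_second), TRUE),
             prod_ai = NA_character_))

    reac <- tibble(primaryid = rep(primaryid, lengths(pts)),
                   pt = unlist(pts))
    outc <- dplyr::bind_rows(
      tibble(primaryid = primaryid[death], outc_cod = "DE"),
      tibble(primaryid = primaryid[hosp], outc_cod = "HO"))
    ther <- tibble(
      primaryid = primaryid[is_cohort & !start_miss],
      dsg_drug_seq = 1L,
      start_dt = .fmt_dt(start_date[is_cohort & !start_miss]),
      end_dt = NA_character_)
    indi <- empty_faers_table("indi")

    # duplicate revisions: lower primaryid, earlier-or-equal receipt date
    dup_sel <- which(stats::runif(n) < config$duplicate_rate)
    if (length(dup_sel) > 0L) {
      tie <- stats::runif(length(dup_sel)) < 0.3
      dup_fda <- fda_date[dup_sel] - sample.int(120L, length(dup_sel), TRUE)
      dup_fda[tie] <- fda_date[dup_sel][tie]
      dup_fda <- pmax(dup_fda, config$window[1])
      dup_pid <- paste0(caseid[dup_sel],
                        sample(1:8, length(dup_sel), TRUE))
      dup_demo <- demo[dup_sel, , drop = FALSE]
      dup_demo$primaryid <- dup_pid
      dup_demo$fda_dt <- .fmt_dt(dup_fda)
      demo <- dplyr::bind_rows(demo, dup_demo)
      clone <- function(df) {
        idx <- match(df$primaryid, primaryid[dup_sel])
        cl <- df[!is.na(idx), , drop = FALSE]
        cl$primaryid <- dup_pid[idx[!is.na(idx)]]
        dplyr::bind_rows(df, cl)
      }
      drug_rows <- clone(drug_rows); reac <- clone(reac)
      outc <- clone(outc); ther <- clone(ther)
    }

    # deletion lists exist only from 2019Q1 on
    qlab <- quarter_label(fda_date)
    eligible_del <- which(quarter_key(qlab) >= 20191L)
    del_sel <- eligible_del[stats::runif(length(eligible_del)) <
                              config$deletion_rate]
    deleted <- tibble(caseid = caseid[del_sel], quarter = qlab[del_sel])

    truth <- tibble(
      caseid = caseid, survivor_primaryid = primaryid,
      deleted = caseid %in% deleted$caseid,
      product = product, pts = pts, pae = is_pae, death = death,
      onset_days = as.integer(onset))

    tables <- list(demo = demo, drug = drug_rows, reac = reac, outc = outc,
                   ther = ther, indi = indi)
    if (!is.null(dir)) write_faers_package(tables, dir, deleted)

    structure(list(
      tables = tables, deleted = deleted, truth = truth,
      signal_truth = config$signal_multipliers[
        config$signal_multipliers$multiplier > 1, , drop = FALSE],
      config = config, dir = dir), class = "faers_synth")
  })
}

#' @export
print.faers_synth <- function(x, ...) {
  cat(sprintf(paste0("<faers_synth> %d reports (%d revisions), %d deleted ",
                     "cases, %d planted signal pairs%s\n"),
              nrow(x$truth), nrow(x$tables$demo) - nrow(x$truth),
              nrow(x$deleted), nrow(x$signal_truth),
              if (is.null(x$dir)) "" else paste0("; written to ", x$dir)))
  invisible(x)
}
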