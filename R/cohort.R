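#' Build the CAR-T cohort and the background event table
#'
#' Screens deduplicated reports for CAR-T products among suspect drugs
#' (`role_cod` in `role_codes`), assigns each cohort report to a product,
#' labels every reaction with its SOC and flags pulmonary events, death and
#' serious outcomes, and normalises demographics. Reports without a product
#' match form the background; their (report, PT) pairs are kept for
#' contingency building, so cohort and background partition the
#' deduplicated database.
#'
#' Product assignment prefers, within each matched drug string, the longest
#' matching synonym; when that still names several products (the ambiguous
#' "autoleucel" alone) the report stays in the cohort but carries no product
#' (`product = NA`) and is excluded from per-product stratification, with a
#' counter.
#'
#' @param demo,drug,reac,outc Deduplicated FAERS tibbles (see
#'   [filter_to_retained()]).
#' @param definition A [cohort_definition()].
#' @param role_codes Drug role codes that qualify a report for the cohort;
#'   default suspect drugs (`PS`, `SS`).
#'
#' @return An object of class `cart_cohort`: list with
#'   \describe{
#'     \item{reports}{one row per cohort report: identifiers, matched
#'       `products` (list-column), assigned `product`, `pae_flag`,
#'       `death_flag`, `serious_flag`, `age_years`, `sex`, `country`,
#'       `reporter_class`, FDA and event dates.}
#'     \item{events}{cohort (report, PT) pairs with `soc` and `is_pae`.}
#'     \item{background_events}{(report, PT) pairs of all other reports.}
#'     \item{matched_drugs}{cohort drug rows that matched, for therapy
#'       linkage.}
#'     \item{counters}{named counts used in the run manifest.}
#'   }
#' @export
build_cohort <- function(demo, drug, reac, outc, definition,
                         role_codes = c("PS", "SS")) {
  stopifnot(inherits(definition, "cohort_definition"))

  eligible <- drug[!is.na(drug$role_cod) & drug$role_cod %in% role_codes, ,
                   drop = FALSE]
  eligible$dn_norm <- norm_text(eligible$drugname)
  eligible$ai_norm <- norm_text(eligible$prod_ai)

  hits <- syn_matches(c(eligible$dn_norm, eligible$ai_norm), definition)

  # per drug row: products of all matched synonyms, and of the longest one
  row_hits <- dplyr::bind_rows(
    dplyr::mutate(hits[hits$string %in% eligible$dn_norm, ], field = "dn"),
    dplyr::mutate(hits[hits$string %in% eligible$ai_norm, ], field = "ai")
  )
  drug_matches <- dplyr::bind_rows(
    dplyr::inner_join(
      dplyr::select(eligible, "primaryid", "drug_seq", string = "dn_norm"),
      row_hits[row_hits$field == "dn", ], by = "string",
      relationship = "many-to-many"),
    dplyr::inner_join(
      dplyr::select(eligible, "primaryid", "drug_seq", string = "ai_norm"),
      row_hits[row_hits$field == "ai", ], by = "string",
      relationship = "many-to-many")
  )

  if (nrow(drug_matches) == 0L) {
    abort(paste("No report matched the product dictionary;",
                "check the synonym dictionary and drug name fields."))
  }

  # longest-synonym products per (report, drug row, field-string)
  assigned_by_row <- drug_matches |>
    dplyr::group_by(.data$primaryid, .data$drug_seq, .data$field) |>
    dplyr::filter(.data$syn_nchar == max(.data$syn_nchar)) |>
    dplyr::ungroup()

  per_report <- drug_matches |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(products = list(sort(unique(.data$product))),
                     .groups = "drop")
  assignment <- assigned_by_row |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(.assigned = list(sort(unique(.data$product))),
                     .groups = "drop") |>
    dplyr::mutate(product = purrr::map_chr(
      .data$.assigned,
      function(p) if (length(p) == 1L) p else NA_character_)) |>
    dplyr::select("primaryid", "product")
  n_ambiguous <- sum(is.na(assignment$product))

  cohort_ids <- per_report$primaryid
  in_cohort <- demo$primaryid %in% cohort_ids

  # reactions with SOC labels
  soc <- assign_soc(reac$pt, definition)
  n_unmapped <- attr(soc, "n_unmapped")
  reac2 <- reac |>
    dplyr::mutate(soc = as.character(soc),
                  is_pae = !is.na(soc) &
                    norm_text(soc) == norm_text(definition$pae_soc_label)) |>
    dplyr::filter(!is.na(.data$pt) & nzchar(.data$pt))
  events <- reac2[reac2$primaryid %in% cohort_ids, , drop = FALSE]
  background_events <- reac2[!reac2$primaryid %in% cohort_ids,
                             c("primaryid", "pt"), drop = FALSE]

  # report-level flags
  pae_ids <- unique(events$primaryid[events$is_pae])
  death_ids <- unique(outc$primaryid[!is.na(outc$outc_cod) &
                                       outc$outc_cod == "DE"])
  serious_ids <- unique(outc$primaryid[!is.na(outc$outc_cod) &
                                         outc$outc_cod %in%
                                         c("DE", "LT", "HO", "DS")])

  dm <- demo[in_cohort, , drop = FALSE]
  fda <- parse_faers_date(dm$fda_dt)
  country <- dplyr::coalesce(dm$occr_country,
                             dm$reporter_country %||%
                               rep(NA_character_, nrow(dm)))
  reports <- tibble(
    primaryid = dm$primaryid,
    caseid = dm$caseid,
    sex = ifelse(!is.na(dm$sex) & dm$sex %in% c("F", "M"), dm$sex,
                 NA_character_),
    age_years = normalize_age(dm$age, dm$age_cod),
    country = country,
    reporter_class = classify_reporter(dm$occp_cod),
    fda_dt = dm$fda_dt,
    fda_date = fda$date,
    fda_year = fda$year,
    event_dt = dm$event_dt
  ) |>
    dplyr::left_join(per_report, by = "primaryid") |>
    dplyr::left_join(assignment, by = "primaryid") |>
    dplyr::mutate(
      pae_flag = .data$primaryid %in% pae_ids,
      death_flag = .data$primaryid %in% death_ids,
      serious_flag = .data$primaryid %in% serious_ids
    )

  matched_drugs <- assigned_by_row |>
    dplyr::distinct(.data$primaryid, .data$drug_seq, .data$product)

  structure(
    list(reports = reports,
         events = as_tibble(events),
         background_events = as_tibble(background_events),
         matched_drugs = matched_drugs,
         counters = list(
           n_cohort = nrow(reports),
           n_background = sum(!in_cohort),
           n_events = nrow(events),
           n_pae_events = sum(events$is_pae),
           n_pae_reports = length(pae_ids),
           n_background_events = nrow(background_events),
           n_unmapped_pts = n_unmapped,
           n_ambiguous_product = n_ambiguous
         )),
    class = "cart_cohort"
  )
}

#' @export
print.cart_cohort <- function(x, ...) {
  ct <- x$counters
  cat(sprintf(paste0("<cart_cohort> %d reports (%d with pulmonary events); ",
                     "%d cohort events (%d pulmonary); background %d reports",
                     " / %d events\n"),
              ct$n_cohort, ct$n_pae_reports, ct$n_events, ct$n_pae_events,
              ct$n_background, ct$n_background_events))
  invisible(x)
}

#' @method tidy cart_cohort
#' @export
tidy.cart_cohort <- function(x, ...) x$reports

#' @method glance cart_cohort
#' @export
glance.cart_cohort <- function(x, ...) as_tibble(x$counters)
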