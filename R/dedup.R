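#' Apply the FDA case-level deduplication and deletion rules
#'
#' Spontaneous reports are revised over time, so one case (CASEID) appears
#' as several reports (PRIMARYIDs) across quarterly packages. Per the FDA
#' rule, the report with the most recent FDA receipt date (`fda_dt`) is
#' retained for each case; when receipt dates tie, the higher PRIMARYID
#' wins. Afterwards, any case whose identifier appears on a deletion list
#' is removed entirely.
#'
#' Records whose `fda_dt` does not parse to a full calendar date are
#' excluded and counted (`dropped_undated`): the retention rule is
#' undefined without a date. PRIMARYIDs are compared numerically when every
#' id in the input is all-digits, lexicographically otherwise.
#'
#' @param demo A DEMO tibble pooled across quarters (needs `primaryid`,
#'   `caseid`, `fda_dt`).
#' @param deleted_caseids Character vector of case identifiers from the
#'   union of deletion lists.
#'
#' @return An object of class `dedup_result`: list with `retained` (the
#'   surviving DEMO rows, one per case), `retained_primaryids`, and counts
#'   `dropped_duplicates`, `dropped_deleted`, `dropped_undated`.
#'
#' @examples
#' demo <- tibble::tibble(
#'   primaryid = c("1000", "1001", "2000"),
#'   caseid    = c("100",  "100",  "200"),
#'   fda_dt    = c("20200301", "20200101", "20200401"))
#' deduplicate(demo)$retained_primaryids
#' @export
deduplicate <- function(demo, deleted_caseids = character(0)) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  pd <- parse_faers_date(demo$fda_dt)
  usable <- pd$precision == "day"
  dropped_undated <- sum(!usable)
  if (dropped_undated > 0L) {
    warn(sprintf("%d record(s) without a parseable FDA_DT excluded from deduplication.",
                 dropped_undated))
  }
  d <- demo[usable, , drop = FALSE]
  d$.fda <- pd$date[usable]
  if (all(stringr::str_detect(d$primaryid, "^[0-9]+$"))) {
    d$.pid <- as.numeric(d$primaryid)
  } else {
    d$.pid <- d$primaryid
  }

  winners <- d |>
    dplyr::arrange(.data$caseid, dplyr::desc(.data$.fda),
                   dplyr::desc(.data$.pid)) |>
    dplyr::distinct(.data$caseid, .keep_all = TRUE)
  dropped_duplicates <- nrow(d) - nrow(winners)

  kept <- winners[!winners$caseid %in% deleted_caseids, , drop = FALSE]
  dropped_deleted <- nrow(winners) - nrow(kept)
  kept$.fda <- NULL
  kept$.pid <- NULL

  structure(
    list(retained = as_tibble(kept),
         retained_primaryids = kept$primaryid,
         dropped_duplicates = dropped_duplicates,
         dropped_deleted = dropped_deleted,
         dropped_undated = dropped_undated),
    class = "dedup_result"
  )
}

#' @export
print.dedup_result <- function(x, ...) {
  cat(sprintf(paste0("<dedup_result> %d cases retained ",
                     "(%d duplicates, %d deleted, %d undated dropped)\n"),
              nrow(x$retained), x$dropped_duplicates, x$dropped_deleted,
              x$dropped_undated))
  invisible(x)
}

# Restrict the satellite tables of a pooled record set to the retained
# reports after deduplication.
filter_to_retained <- function(pooled, retained_primaryids) {
  out <- pooled
  for (tbl in c("demo", "drug", "reac", "outc", "ther", "indi")) {
    if (!is.null(out[[tbl]])) {
      out[[tbl]] <- out[[tbl]][out[[tbl]]$primaryid %in% retained_primaryids, ,
                               drop = FALSE]
    }
  }
  out
}
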