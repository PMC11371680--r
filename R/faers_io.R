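#' @name faers_io
#' @title FAERS quarterly ASCII ingestion
#'
#' @description
#' FAERS quarterly data packages are distributed as "$"-delimited ASCII
#' tables (DEMO, DRUG, REAC, OUTC, THER, INDI) with a single header line,
#' plus — from 2019Q1 onwards — plain-text lists of deleted case
#' identifiers. Columns are resolved from the header, not by position, so
#' both legacy and current field sets parse; files are decoded as Latin-1
#' (FAERS files contain non-UTF-8 bytes). Ragged lines are tolerated:
#' missing trailing fields are right-padded with `NA`, surplus fields
#' dropped, and every such line is counted as malformed.
NULL

# typed columns guaranteed per table (lower-case); extras are kept untouched
.faers_schema <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "occr_country", "reporter_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

.faers_int_cols <- c("drug_seq", "dsg_drug_seq", "indi_drug_seq")
.faers_dbl_cols <- c("age")

empty_faers_table <- function(table) {
  cols <- .faers_schema[[table]]
  out <- as_tibble(stats::setNames(
    lapply(cols, function(x) character(0)), cols))
  for (col in intersect(cols, .faers_int_cols)) out[[col]] <- integer(0)
  for (col in intersect(cols, .faers_dbl_cols)) out[[col]] <- double(0)
  out
}

read_faers_table <- function(path, table) {
  df <- suppressWarnings(readr::read_delim(
    path,
    delim = "$", quote = "",
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = "latin1"),
    na = character(), progress = FALSE, show_col_types = FALSE
  ))
  if (ncol(df) == 0L) {
    abort(sprintf("Unreadable header in FAERS table file '%s'.", path))
  }
  n_malformed <- length(unique(readr::problems(df)$row))
  names(df) <- tolower(names(df))
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::everything(), ~ dplyr::na_if(stringr::str_trim(.x), "")))
  for (col in setdiff(.faers_schema[[table]], names(df))) {
    df[[col]] <- NA_character_
  }
  for (col in intersect(names(df), .faers_int_cols)) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  for (col in intersect(names(df), .faers_dbl_cols)) {
    df[[col]] <- suppressWarnings(as.double(df[[col]]))
  }
  attr(df, "n_malformed") <- n_malformed
  df
}

.find_table_file <- function(files, table) {
  hit <- files[grepl(sprintf("^%s.*\\.txt$", table), tolower(basename(files)))]
  if (length(hit) > 1L) hit <- sort(hit)[1L]
  hit
}

#' Parse one FAERS-format quarterly package
#'
#' Reads every recognised table in a quarter directory. DEMO, DRUG and REAC
#' are mandatory; OUTC, THER and INDI default to empty tables when absent.
#' Any file whose name contains "delet" is read as a deletion list (one
#' case identifier per line, no header).
#'
#' @param path Directory holding the "$"-delimited `.txt` files of one
#'   quarter.
#' @param quarter Optional quarter label such as `"2019Q1"`; when `NULL`
#'   the label is taken from the directory name if it matches the pattern.
#'
#' @return An object of class `faers_quarter`: a list with tibbles `demo`,
#'   `drug`, `reac`, `outc`, `ther`, `indi`, a character vector
#'   `deleted_caseids`, the `quarter` label (or `NA`), and `n_malformed`,
#'   a named count of ragged lines per table.
#'
#' @seealso [generate_faers()] to produce packages in this format.
#' @export
parse_quarter <- function(path, quarter = NULL) {
  if (!dir.exists(path)) {
    abort(sprintf("Quarter directory '%s' does not exist.", path))
  }
  files <- list.files(path, full.names = TRUE)

  tables <- list()
  n_malformed <- integer(0)
  for (tbl in names(.faers_schema)) {
    f <- .find_table_file(files, tbl)
    if (length(f) == 0L) {
      if (tbl %in% c("demo", "drug", "reac")) {
        abort(sprintf("Missing mandatory FAERS table '%s' in '%s'.",
                      toupper(tbl), path))
      }
      tables[[tbl]] <- empty_faers_table(tbl)
      n_malformed[[tbl]] <- 0L
    } else {
      parsed <- read_faers_table(f, tbl)
      n_malformed[[tbl]] <- attr(parsed, "n_malformed")
      attr(parsed, "n_malformed") <- NULL
      tables[[tbl]] <- parsed
    }
  }

  del_files <- files[grepl("delet", tolower(basename(files)))]
  deleted <- character(0)
  for (f in del_files) {
    lines <- stringr::str_trim(readLines(f, encoding = "latin1", warn = FALSE))
    deleted <- c(deleted, lines[nzchar(lines)])
  }

  if (is.null(quarter)) {
    base <- basename(normalizePath(path, mustWork = FALSE))
    quarter <- if (grepl("^[0-9]{4}[Qq][1-4]$", base)) toupper(base)
               else NA_character_
  }

  structure(
    c(tables, list(deleted_caseids = unique(deleted), quarter = quarter,
                   n_malformed = n_malformed)),
    class = "faers_quarter"
  )
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat(sprintf("<faers_quarter %s>\n",
              ifelse(is.na(x$quarter), "(unlabelled)", x$quarter)))
  for (tbl in names(.faers_schema)) {
    cat(sprintf("  %s: %d records\n", toupper(tbl), nrow(x[[tbl]])))
  }
  cat(sprintf("  deleted caseids: %d; malformed lines: %d\n",
              length(x$deleted_caseids), sum(x$n_malformed)))
  invisible(x)
}

#' Pool parsed quarters into one multi-quarter record set
#'
#' Row-binds each table across quarters and unions the deletion lists.
#' Duplicate PRIMARYIDs across quarters (report revisions) are retained and
#' resolved later by [deduplicate()].
#'
#' @param quarters A list of `faers_quarter` objects from [parse_quarter()].
#'
#' @return A list with the six pooled tibbles, `deleted_caseids`, the
#'   vector of `quarter` labels, and total `n_malformed`.
#' @export
pool_quarters <- function(quarters) {
  stopifnot(length(quarters) > 0L)
  pooled <- lapply(names(.faers_schema), function(tbl) {
    dplyr::bind_rows(lapply(quarters, `[[`, tbl))
  })
  names(pooled) <- names(.faers_schema)
  c(pooled, list(
    deleted_caseids = unique(unlist(lapply(quarters, `[[`, "deleted_caseids"))),
    quarter = vapply(quarters, `[[`, character(1), "quarter"),
    n_malformed = sum(vapply(quarters, function(q) sum(q$n_malformed),
                             numeric(1)))
  ))
}

# Write one quarter's tables in FAERS ASCII format. `tables` is a named list
# of tibbles (demo/drug/...); deletion list written only when non-empty.
write_quarter <- function(tables, dir, quarter, deleted_caseids = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yq <- sub("^[0-9]{2}", "", quarter)  # "2019Q1" -> "19Q1"
  for (tbl in names(.faers_schema)) {
    df <- tables[[tbl]] %||% empty_faers_table(tbl)
    readr::write_delim(df, file.path(dir, sprintf("%s%s.txt", toupper(tbl), yq)),
                       delim = "$", na = "")
  }
  if (length(deleted_caseids) > 0L) {
    writeLines(deleted_caseids,
               file.path(dir, sprintf("DELETED_CASES_%s.txt", yq)))
  }
  invisible(dir)
}

# Split in-memory tables into quarter directories keyed by each report's
# FDA receipt date. `deleted` is a tibble (caseid, quarter).
write_faers_package <- function(tables, dir, deleted = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fda <- parse_faers_date(tables$demo$fda_dt)
  qlab <- quarter_label(fda$date)
  if (anyNA(qlab)) {
    abort("Every DEMO record needs a full FDA receipt date to be written.")
  }
  pid_quarter <- stats::setNames(qlab, tables$demo$primaryid)
  for (q in sort(unique(qlab))) {
    qt <- list()
    for (tbl in names(.faers_schema)) {
      df <- tables[[tbl]] %||% empty_faers_table(tbl)
      qt[[tbl]] <- df[!is.na(pid_quarter[df$primaryid]) &
                        pid_quarter[df$primaryid] == q, , drop = FALSE]
    }
    del <- character(0)
    if (!is.null(deleted) && nrow(deleted) > 0L) {
      del <- deleted$caseid[deleted$quarter == q]
    }
    write_quarter(qt, file.path(dir, q), q, del)
  }
  invisible(dir)
}
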