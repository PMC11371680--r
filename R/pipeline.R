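#' Assemble a validated pipeline run configuration
#'
#' @param input_dir Directory containing quarter subdirectories (or itself
#'   a single quarter directory of FAERS ASCII files).
#' @param window Character vector `c(start, end)` of quarter labels
#'   bounding the study window, inclusive.
#' @param synonyms,pt_soc,pae_soc_label Passed to [cohort_definition()].
#' @param thresholds A [signal_thresholds()] list.
#' @param ic_method IC interval model, `"credibility"` or `"delta"`.
#' @param zero_correction Haldane 0.5 correction flag.
#' @param role_codes Drug roles qualifying a report for the cohort.
#' @param min_cases Minimum cell count in the per-product IC025 matrix.
#' @param output_dir Directory for report tables; `NULL` skips writing.
#' @param seed Integer seed recorded in the manifest (the analysis itself
#'   is deterministic).
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir, window = c("2017Q1", "2023Q3"),
                       synonyms = NULL, pt_soc = NULL,
                       pae_soc_label = pae_soc(),
                       thresholds = signal_thresholds(),
                       ic_method = "credibility",
                       zero_correction = FALSE,
                       role_codes = c("PS", "SS"),
                       min_cases = 3,
                       output_dir = NULL, seed = 1L) {
  if (!dir.exists(input_dir)) {
    abort(sprintf("Input directory '%s' does not exist.", input_dir))
  }
  wk <- quarter_key(window)
  if (anyNA(wk) || wk[1] > wk[2]) {
    abort("The study window must be two quarter labels with start <= end.")
  }
  structure(list(input_dir = input_dir, window = toupper(window),
                 synonyms = synonyms, pt_soc = pt_soc,
                 pae_soc_label = pae_soc_label, thresholds = thresholds,
                 ic_method = ic_method, zero_correction = zero_correction,
                 role_codes = role_codes, min_cases = min_cases,
                 output_dir = output_dir, seed = as.integer(seed)),
        class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the [run_config()] fields by name; omitted fields keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown configuration field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (!is.null(vals$thresholds)) {
    vals$thresholds <- do.call(signal_thresholds, vals$thresholds)
  }
  do.call(run_config, vals)
}

.discover_quarters <- function(input_dir) {
  has_demo <- function(d) length(.find_table_file(
    list.files(d, full.names = TRUE), "demo")) > 0L
  subdirs <- list.dirs(input_dir, recursive = FALSE)
  subdirs <- subdirs[vapply(subdirs, has_demo, logical(1))]
  if (length(subdirs) == 0L && has_demo(input_dir)) subdirs <- input_dir
  subdirs
}

#' Run the full analysis pipeline
#'
#' Orchestrates parse, deduplication, cohort extraction, signal screening,
#' per-product IC025 stratification, time-to-onset, demographics, annual
#' counts and fatality summaries, and (when an output directory is
#' configured) writes the report tables and a machine-readable manifest.
#' Re-running with an identical configuration and inputs reproduces
#' byte-identical outputs.
#'
#' @param config A [run_config()] list, or the path of a YAML file for
#'   [read_run_config()].
#'
#' @return An object of class `cartpv_run` holding the cohort, all result
#'   tables and the manifest. `tidy()` returns the signal table,
#'   `glance()` the manifest counts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  dirs <- .discover_quarters(config$input_dir)
  if (length(dirs) == 0L) {
    abort(sprintf("No FAERS quarter directories found under '%s'.",
                  config$input_dir))
  }
  quarters <- lapply(dirs, parse_quarter)
  keys <- quarter_key(vapply(quarters, `[[`, character(1), "quarter"))
  wk <- quarter_key(config$window)
  in_window <- is.na(keys) | (keys >= wk[1] & keys <= wk[2])
  quarters <- quarters[in_window]
  if (length(quarters) == 0L) abort("No quarters selected by the study window.")

  pooled <- pool_quarters(quarters)
  n_parsed <- nrow(pooled$demo)

  dedup <- deduplicate(pooled$demo, pooled$deleted_caseids)
  records <- filter_to_retained(pooled, dedup$retained_primaryids)
  records$demo <- dedup$retained

  definition <- cohort_definition(config$synonyms, config$pt_soc,
                                  config$pae_soc_label)
  cohort <- build_cohort(records$demo, records$drug, records$reac,
                         records$outc, definition,
                         role_codes = config$role_codes)

  signals <- signal_screen(cohort, ic_method = config$ic_method,
                           zero_correction = config$zero_correction,
                           thresholds = config$thresholds)
  ic_matrix <- per_drug_ic_matrix(cohort, min_cases = config$min_cases,
                                  ic_method = config$ic_method,
                                  zero_correction = config$zero_correction)
  tto <- time_to_onset(cohort, records$ther)
  tto_summary <- summarize_tto(tto)
  fatality <- fatality_by_drug(cohort)
  demographics <- demographics_table(cohort)
  annual <- counts_by_year(cohort)

  ct <- cohort$counters
  manifest <- list(
    package = "cartpv",
    version = as.character(utils::packageVersion("cartpv")),
    seed = config$seed,
    # hash over the analysis-relevant settings only, so identical analyses
    # of the same data hash alike regardless of filesystem locations
    config_hash = rlang::hash(
      unclass(config)[setdiff(names(unclass(config)),
                              c("input_dir", "output_dir"))]),
    window = config$window,
    quarters = sort(vapply(quarters, `[[`, character(1), "quarter")),
    ic_method = config$ic_method,
    zero_correction = config$zero_correction,
    role_codes = config$role_codes,
    quartile_convention = "tukey_inclusive_hinges",
    meddra_version = definition$meddra_version,
    counts = list(
      parsed_reports = n_parsed,
      malformed_lines = pooled$n_malformed,
      dropped_duplicates = dedup$dropped_duplicates,
      dropped_deleted = dedup$dropped_deleted,
      dropped_undated = dedup$dropped_undated,
      deduplicated_reports = nrow(dedup$retained),
      cohort_reports = ct$n_cohort,
      background_reports = ct$n_background,
      cohort_events = ct$n_events,
      cohort_pae_events = ct$n_pae_events,
      cohort_pae_reports = ct$n_pae_reports,
      unmapped_pts = ct$n_unmapped_pts,
      ambiguous_product = ct$n_ambiguous_product))
  stopifnot(manifest$counts$parsed_reports >=
              manifest$counts$deduplicated_reports,
            manifest$counts$deduplicated_reports >=
              manifest$counts$cohort_reports)

  run <- structure(
    list(cohort = cohort, signals = signals, ic_matrix = ic_matrix,
         tto = tto, tto_summary = tto_summary, fatality = fatality,
         demographics = demographics, annual = annual,
         manifest = manifest, config = config),
    class = "cartpv_run")

  if (!is.null(config$output_dir)) {
    write_report_tables(run, config$output_dir)
  }
  run
}

#' Write all report tables and the run manifest
#'
#' Emits CSV tables — the signal table, the wide per-product IC025 matrix,
#' demographics, time-to-onset summaries, per-product fatality (with the
#' display convention of one-decimal percentages; full precision stays in
#' the returned objects) and annual counts — plus `manifest.json` with the
#' configuration hash, seed and per-stage record counts.
#'
#' @param run A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report_tables <- function(run, outdir) {
  stopifnot(inherits(run, "cartpv_run"))
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    abort(sprintf("Cannot create output directory '%s'.", outdir))
  }
  w <- function(df, name) readr::write_csv(df, file.path(outdir, name),
                                           na = "")
  sig <- as_tibble(run$signals)
  sig$drug_set <- "all CAR-T"
  w(sig[, c("drug_set", setdiff(names(sig), "drug_set"))],
    "signal_table.csv")
  w(ic_matrix_wide(run$ic_matrix), "ic025_matrix.csv")
  w(run$demographics, "demographics.csv")
  tto <- dplyr::mutate(run$tto_summary,
                       pct_within_30d = 100 * .data$prop_within_30d)
  w(tto[, c("product", "n_usable", "n_excluded", "median_days", "q1", "q3",
            "pct_within_30d")], "time_to_onset.csv")
  fat <- dplyr::mutate(run$fatality,
                       fatality_pct = round(.data$fatality_pct, 1))
  w(fat, "fatality.csv")
  w(run$annual, "annual_counts.csv")
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.cartpv_run <- function(x, ...) {
  ct <- x$manifest$counts
  cat("<cartpv_run>\n")
  cat(sprintf("  parsed %d reports -> %d after deduplication -> cohort %d (background %d)\n",
              ct$parsed_reports, ct$deduplicated_reports, ct$cohort_reports,
              ct$background_reports))
  cat(sprintf("  cohort events %d of which pulmonary %d (%.1f%%)\n",
              ct$cohort_events, ct$cohort_pae_events,
              100 * ct$cohort_pae_events / max(ct$cohort_events, 1)))
  cat(sprintf("  joint signals: %d of %d screened terms\n",
              sum(x$signals$joint_signal), nrow(x$signals)))
  invisible(x)
}

#' @method tidy cartpv_run
#' @export
tidy.cartpv_run <- function(x, ...) as_tibble(x$signals)

#' @method glance cartpv_run
#' @export
glance.cartpv_run <- function(x, ...) as_tibble(x$manifest$counts)
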