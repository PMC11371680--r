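`%||%` <- function(x, y) if (is.null(x)) y else x

# shared in-code fixtures: a toy PT-to-SOC mapping, a toy cohort
# definition, and a hand-rolled two-report quarter on disk

toy_pt_soc <- function() {
  tibble::tibble(
    pt = c("Hypoxia", "Respiratory failure", "Pyrexia", "Nausea"),
    soc = c(pae_soc(), pae_soc(), "General disorders", "GI disorders"),
    meddra_version = "toy")
}

toy_definition <- function() {
  cohort_definition(pt_soc = toy_pt_soc())
}

# write a minimal quarter directory from raw "$" lines per table
write_raw_quarter <- function(dir, demo_lines, drug_lines = NULL,
                              reac_lines = NULL, deleted = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$occr_country",
               demo_lines), file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drug_seq$role_cod$drugname$prod_ai",
               drug_lines %||% character(0)), file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", reac_lines %||% character(0)),
             file.path(dir, "REAC.txt"))
  if (!is.null(deleted)) {
    writeLines(deleted, file.path(dir, "DELETED_CASES.txt"))
  }
  dir
}

# small generator configuration with one planted pair; fast enough to run
# in replicate loops
small_synth_config <- function(seed, multiplier = 10) {
  synth_config(
    seed = seed, n_background = 800,
    product_counts = c("Axi-cel" = 120),
    signal_multipliers = tibble::tibble(
      product = "Axi-cel", pt = "Hypoxia", multiplier = multiplier),
    duplicate_rate = 0.1, deletion_rate = 0.02)
}

# run dedup + cohort on an in-memory synthetic package
cohort_from_synth <- function(g, definition = cohort_definition()) {
  dd <- deduplicate(g$tables$demo, g$deleted$caseid)
  rec <- filter_to_retained(g$tables, dd$retained_primaryids)
  build_cohort(dd$retained, rec$drug, rec$reac, rec$outc, definition)
}

filter_to_retained <- cartpv:::filter_to_retained
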