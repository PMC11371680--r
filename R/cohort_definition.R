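#' Built-in CAR-T product synonym dictionary
#'
#' Trade names, generic names and development codes of the six approved
#' CAR-T cell products, used to screen FAERS drug name fields. The synonym
#' "autoleucel" is genuinely ambiguous (it occurs in both brexucabtagene
#' autoleucel and ciltacabtagene autoleucel); ambiguity is resolved at
#' assignment time by preferring the longest matching synonym per drug
#' string.
#'
#' @return A tibble with columns `product` and `synonym`.
#' @export
cart_synonyms <- function() {
  tibble::tribble(
    ~product,     ~synonym,
    "Axi-cel",    "axicabtagene",
    "Axi-cel",    "ciloleucel",
    "Axi-cel",    "yescarta",
    "Axi-cel",    "axi-cel",
    "Axi-cel",    "kte-c19",
    "Tisa-cel",   "tisagenlecleucel",
    "Tisa-cel",   "kymriah",
    "Tisa-cel",   "tisa-cel",
    "Tisa-cel",   "ctl019",
    "Brexu-cel",  "brexucabtagene",
    "Brexu-cel",  "autoleucel",
    "Brexu-cel",  "tecartus",
    "Brexu-cel",  "kte-x19",
    "Liso-cel",   "lisocabtagene maraleucel",
    "Liso-cel",   "breyanzi",
    "Liso-cel",   "jcar017",
    "Ide-cel",    "idecabtagene",
    "Ide-cel",    "vicleucel",
    "Ide-cel",    "abecma",
    "Ide-cel",    "bb2121",
    "Cilta-cel",  "ciltacabtagene",
    "Cilta-cel",  "autoleucel",
    "Cilta-cel",  "carvykti",
    "Cilta-cel",  "jcarh125"
  )
}

#' Default pulmonary SOC label
#'
#' The MedDRA system organ class designated as pulmonary adverse events.
#' Compared case-insensitively after whitespace normalisation.
#' @export
pae_soc <- function() "Respiratory, thoracic and mediastinal disorders"

#' Assemble a cohort definition
#'
#' Bundles the drug synonym dictionary, the MedDRA PT-to-SOC mapping and
#' the pulmonary SOC label. MedDRA content is licensed and not shipped: the
#' mapping is user-supplied as a TSV with columns `pt`, `soc` and
#' optionally `meddra_version`. The package ships a small synthetic
#' example mapping (see `system.file("extdata", "pt_soc_map_synthetic.tsv",
#' package = "cartpv")`) covering the terms used by the synthetic
#' generator; it is a demonstration stand-in, not MedDRA.
#'
#' @param synonyms `NULL` for the built-in [cart_synonyms()], a TSV path
#'   (columns `product`, `synonym`), or a tibble in the same shape.
#' @param pt_soc `NULL` for the packaged synthetic example mapping, a TSV
#'   path (columns `pt`, `soc`, optional `meddra_version`), or a tibble.
#' @param pae_soc_label SOC string defining pulmonary adverse events.
#'
#' @return An object of class `cohort_definition`.
#' @export
cohort_definition <- function(synonyms = NULL, pt_soc = NULL,
                              pae_soc_label = pae_soc()) {
  if (is.null(synonyms)) {
    synonyms <- cart_synonyms()
  } else if (is.character(synonyms)) {
    synonyms <- readr::read_tsv(synonyms, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
  }
  synonyms <- as_tibble(synonyms)
  stopifnot(all(c("product", "synonym") %in% names(synonyms)))
  if (any(!nzchar(synonyms$synonym) | is.na(synonyms$synonym))) {
    abort("Every synonym must be a non-empty string.")
  }
  synonyms$syn_norm <- norm_text(synonyms$synonym)

  if (is.null(pt_soc)) {
    pt_soc <- system.file("extdata", "pt_soc_map_synthetic.tsv",
                          package = "cartpv")
  }
  if (is.character(pt_soc)) {
    pt_soc <- readr::read_tsv(pt_soc, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
  }
  pt_soc <- as_tibble(pt_soc)
  stopifnot(all(c("pt", "soc") %in% names(pt_soc)))
  pt_soc$pt_norm <- norm_text(pt_soc$pt)
  pt_soc <- dplyr::distinct(pt_soc, .data$pt_norm, .keep_all = TRUE)
  meddra_version <- if ("meddra_version" %in% names(pt_soc)) {
    unique(stats::na.omit(pt_soc$meddra_version))[1] %||% NA_character_
  } else NA_character_

  if (nrow(pt_soc) > 0L &&
      !norm_text(pae_soc_label) %in% norm_text(pt_soc$soc)) {
    warn("The pulmonary SOC label does not occur in the PT-to-SOC mapping; no reaction can be flagged as a pulmonary event.")
  }

  structure(
    list(synonyms = synonyms, pt_soc = pt_soc,
         pae_soc_label = pae_soc_label, meddra_version = meddra_version),
    class = "cohort_definition"
  )
}

#' @export
print.cohort_definition <- function(x, ...) {
  cat(sprintf(paste0("<cohort_definition> %d products / %d synonyms; ",
                     "%d PT-to-SOC entries (MedDRA %s); pulmonary SOC: %s\n"),
              dplyr::n_distinct(x$synonyms$product), nrow(x$synonyms),
              nrow(x$pt_soc),
              ifelse(is.na(x$meddra_version), "version unstated",
                     x$meddra_version),
              x$pae_soc_label))
  invisible(x)
}

# All (string, synonym, product) matches of the dictionary against a
# character vector, on normalised text, substring containment.
syn_matches <- function(strings, definition) {
  proto <- tibble(string = character(0), synonym = character(0),
                  product = character(0), syn_nchar = integer(0))
  u <- unique(strings[!is.na(strings) & nzchar(strings)])
  if (length(u) == 0L) return(proto)
  syn <- definition$synonyms
  found <- purrr::map(seq_len(nrow(syn)), function(i) {
    hit <- u[stringr::str_detect(u, stringr::fixed(syn$syn_norm[i]))]
    if (length(hit) == 0L) return(NULL)
    tibble(string = hit, synonym = syn$synonym[i], product = syn$product[i],
           syn_nchar = nchar(syn$syn_norm[i]))
  })
  dplyr::bind_rows(proto, found)
}

#' Match one drug name against the product dictionary
#'
#' Case-insensitive substring matching of every synonym against the
#' whitespace-normalised `drugname` and active-ingredient text; returns
#' the union of matched products.
#'
#' @param drugname Verbatim drug name text.
#' @param prod_ai Active ingredient text (optional).
#' @param definition A [cohort_definition()].
#'
#' @return Character vector of matched product names (possibly empty;
#'   several when a synonym is ambiguous).
#'
#' @examples
#' match_drug("YESCARTA", definition = cohort_definition(pt_soc = tibble::tibble(
#'   pt = character(0), soc = character(0))))
#' @export
match_drug <- function(drugname, prod_ai = "", definition) {
  strings <- norm_text(c(drugname, prod_ai))
  sort(unique(syn_matches(strings, definition)$product))
}

#' Map a preferred term to its system organ class
#'
#' Exact match after case-folding and whitespace normalisation against the
#' definition's PT-to-SOC table; unmapped terms yield `NA`.
#'
#' @param pt Character vector of MedDRA preferred terms.
#' @param definition A [cohort_definition()].
#'
#' @return Character vector of SOC labels (`NA` where unmapped), with
#'   attribute `n_unmapped`.
#' @export
assign_soc <- function(pt, definition) {
  lut <- stats::setNames(definition$pt_soc$soc, definition$pt_soc$pt_norm)
  out <- unname(lut[norm_text(pt)])
  attr(out, "n_unmapped") <- sum(is.na(out) & !is.na(pt))
  out
}

#' Normalise reported age to years
#'
#' FAERS ages carry a unit code: `DY` days, `WK` weeks, `MON` months, `YR`
#' years, `DEC` decades, `HR` hours. A missing code with a non-missing age
#' is taken as years. Negative ages become missing with a warning.
#'
#' @param age Numeric vector of reported ages.
#' @param age_cod Character vector of unit codes.
#'
#' @return Numeric vector of ages in years (`NA` where missing/invalid).
#'
#' @examples
#' normalize_age(c(6, 6, 59), c("MON", "DEC", "YR"))
#' @export
normalize_age <- function(age, age_cod) {
  age <- suppressWarnings(as.double(age))
  divisor <- c(DY = 365.25, WK = 52.18, MON = 12, YR = 1, HR = 8766)
  code <- toupper(trimws(ifelse(is.na(age_cod), "YR", age_cod)))
  code[!nzchar(code)] <- "YR"
  years <- rep(NA_real_, length(age))
  known <- code %in% c(names(divisor), "DEC")
  years[known & code != "DEC"] <-
    age[known & code != "DEC"] / divisor[code[known & code != "DEC"]]
  years[code == "DEC"] <- age[code == "DEC"] * 10
  years[!known & !is.na(age)] <- age[!known & !is.na(age)]  # unknown unit: years
  neg <- !is.na(years) & years < 0
  if (any(neg)) {
    warn(sprintf("%d negative age(s) set to missing.", sum(neg)))
    years[neg] <- NA_real_
  }
  years
}

#' Classify the reporter occupation code
#'
#' `MD` physician, `PH` pharmacist, `OT` other health-professional, `CN`
#' consumer, `LW` (lawyer) folded into consumer; the healthcare-professional
#' superclass is physician + pharmacist + other health-professional.
#' Unknown non-missing codes yield `NA` with a warning.
#'
#' @param occp_cod Character vector of FAERS occupation codes.
#'
#' @return Character vector in `{"physician", "pharmacist",
#'   "other health-professional", "consumer", NA}`.
#' @export
classify_reporter <- function(occp_cod) {
  lut <- c(MD = "physician", PH = "pharmacist",
           OT = "other health-professional", CN = "consumer",
           LW = "consumer")
  code <- toupper(trimws(occp_cod))
  out <- unname(lut[code])
  unknown <- !is.na(code) & nzchar(code) & !code %in% names(lut)
  if (any(unknown)) {
    warn(sprintf("%d unknown reporter code(s) set to missing.", sum(unknown)))
  }
  out
}
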