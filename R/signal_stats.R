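#' Signal-detection thresholds
#'
#' The flagging criteria of the four disproportionality algorithms. A
#' drug–event pair is a joint signal only when all four flags hold and the
#' pair has at least `min_n` reports.
#'
#' @param ror_lower Lower 95% CI bound of the ROR must exceed this (1).
#' @param prr PRR point estimate threshold (2).
#' @param chi2 Chi-squared threshold paired with the PRR (4).
#' @param ic025 Lower IC bound must exceed this (0).
#' @param ebgm05 Lower EBGM bound must exceed this (2; stricter than some
#'   practice, kept as printed and configurable).
#' @param min_n Minimum number of target reports (3).
#' @export
signal_thresholds <- function(ror_lower = 1, prr = 2, chi2 = 4,
                              ic025 = 0, ebgm05 = 2, min_n = 3) {
  list(ror_lower = ror_lower, prr = prr, chi2 = chi2,
       ic025 = ic025, ebgm05 = ebgm05, min_n = min_n)
}

#' Count 2x2 contingency cells per preferred term
#'
#' For each event term, `a` counts target (report, PT) pairs with that
#' term, `b` the target pairs with other terms, `c`/`d` the same split in
#' the comparator. The counting unit is the (report, PT) pair throughout.
#'
#' @param target_events Tibble of target (report, PT) pairs (`primaryid`,
#'   `pt`).
#' @param comparator_events Tibble of comparator (report, PT) pairs.
#' @param pts Terms to tabulate; default every distinct target term.
#'
#' @return Tibble with columns `pt`, `a`, `b`, `c`, `d`.
#' @export
contingency_counts <- function(target_events, comparator_events, pts = NULL) {
  n_t <- nrow(target_events)
  n_c <- nrow(comparator_events)
  if (n_t + n_c == 0L) abort("Empty contingency background (N = 0).")
  pts <- pts %||% sort(unique(target_events$pt))
  a_tab <- dplyr::count(target_events, .data$pt, name = "a")
  c_tab <- dplyr::count(comparator_events, .data$pt, name = "c")
  tibble(pt = pts) |>
    dplyr::left_join(a_tab, by = "pt") |>
    dplyr::left_join(c_tab, by = "pt") |>
    dplyr::mutate(a = dplyr::coalesce(.data$a, 0L),
                  c = dplyr::coalesce(.data$c, 0L),
                  b = n_t - .data$a, d = n_c - .data$c) |>
    dplyr::select("pt", "a", "b", "c", "d")
}

#' Compute the four disproportionality algorithms on 2x2 tables
#'
#' Adds to each row of a table of counts `a, b, c, d` the reporting odds
#' ratio (ROR) with Wald 95% CI, the proportional reporting ratio (PRR)
#' with its chi-squared statistic (no continuity correction), the
#' information component `IC = log2(a N / ((a+b)(a+c)))` with a 95%
#' interval from the chosen variance model, and the empirical Bayes
#' geometric mean closed form `EBGM = a N / ((a+b)(a+c))` (algebraically
#' `2^IC`) with a log-normal Wald CI — together with per-algorithm flags
#' and the joint signal rule (all four flags and `a >= min_n`).
#'
#' Two IC interval models are built in. `"credibility"` (default) is the
#' closed-form credibility approximation for the shrunk observed-to-
#' expected ratio: with `E = (a+b)(a+c)/N`,
#' `IC_shrunk = log2((a+0.5)/(E+0.5))`,
#' `IC025 = IC_shrunk - 3.3 (a+0.5)^-1/2 - 2 (a+0.5)^-3/2` and
#' `IC975 = IC_shrunk + 2.4 (a+0.5)^-1/2 + 0.5 (a+0.5)^-3/2`; the interval
#' brackets the shrunk estimate (returned as `ic_shrunk`), while `ic`
#' is always the unshrunk point. `"delta"` is a delta-method interval
#' around the unshrunk point with `sd(IC) = 1/(a^0.5 ln 2)`.
#'
#' Undefined metrics (zero cells in a denominator or the CI radical) are
#' marked `NA` and force their flag — and the joint signal — false. No
#' Haldane 0.5 continuity correction is applied unless
#' `zero_correction = TRUE`, in which case 0.5 is added to every cell for
#' estimation (never for `n`).
#'
#' @param x Tibble with integer columns `a`, `b`, `c`, `d` (id columns are
#'   carried through).
#' @param ic_method `"credibility"` or `"delta"`.
#' @param zero_correction Add 0.5 to all cells for estimation.
#' @param thresholds A [signal_thresholds()] list.
#'
#' @return `x` plus columns `n`, `ror`, `ror_lo95`, `ror_hi95`, `prr`,
#'   `chi2`, `ic`, `ic_shrunk`, `ic025`, `ic975`, `ebgm`, `ebgm05`,
#'   `ebgm95`, `ror_flag`, `prr_flag`, `ic_flag`, `ebgm_flag`,
#'   `joint_signal`.
#'
#' @examples
#' disproportionality(tibble::tibble(a = 20, b = 80, c = 100, d = 9800))
#' @export
disproportionality <- function(x, ic_method = c("credibility", "delta"),
                               zero_correction = FALSE,
                               thresholds = signal_thresholds()) {
  ic_method <- match.arg(ic_method)
  stopifnot(all(c("a", "b", "c", "d") %in% names(x)))
  n <- as.double(x$a)
  a <- as.double(x$a); b <- as.double(x$b)
  cc <- as.double(x$c); d <- as.double(x$d)
  if (any(c(a, b, cc, d) < 0)) abort("Contingency cells must be >= 0.")
  if (zero_correction) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  N <- a + b + cc + d
  if (any(N == 0)) abort("Contingency table with N = 0.")

  na_ify <- function(v, bad) { v[bad] <- NA_real_; v }

  ror <- na_ify(a * d / (b * cc), a == 0 | b == 0 | cc == 0 | d == 0)
  se_log <- na_ify(sqrt(1 / a + 1 / b + 1 / cc + 1 / d),
                   a == 0 | b == 0 | cc == 0 | d == 0)
  ror_lo95 <- exp(log(ror) - 1.96 * se_log)
  ror_hi95 <- exp(log(ror) + 1.96 * se_log)

  prr <- na_ify((a / (a + b)) / (cc / (cc + d)),
                a + b == 0 | cc == 0)
  chi2 <- na_ify((a * d - b * cc)^2 * N /
                   ((a + b) * (a + cc) * (cc + d) * (b + d)),
                 (a + b) * (a + cc) * (cc + d) * (b + d) == 0)

  ic <- na_ify(log2(a * N / ((a + b) * (a + cc))), a == 0)
  E <- (a + b) * (a + cc) / N
  ic_shrunk <- log2((a + 0.5) / (E + 0.5))
  if (ic_method == "credibility") {
    ic025 <- ic_shrunk - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
    ic975 <- ic_shrunk + 2.4 * (a + 0.5)^(-0.5) + 0.5 * (a + 0.5)^(-1.5)
  } else {
    sd_ic <- na_ify(1 / (sqrt(a) * log(2)), a == 0)
    ic025 <- ic - 1.96 * sd_ic
    ic975 <- ic + 1.96 * sd_ic
  }

  ebgm <- na_ify(a * N / ((a + cc) * (a + b)), a == 0)
  ebgm05 <- exp(log(ebgm) - 1.96 * se_log)
  ebgm95 <- exp(log(ebgm) + 1.96 * se_log)

  th <- thresholds
  flag <- function(v) !is.na(v) & v
  ror_flag <- flag(ror_lo95 > th$ror_lower) & n >= th$min_n
  prr_flag <- flag(prr >= th$prr) & flag(chi2 >= th$chi2) & n >= th$min_n
  ic_flag <- flag(ic025 > th$ic025) & !is.na(ic) & n >= th$min_n
  ebgm_flag <- flag(ebgm05 > th$ebgm05) & n >= th$min_n
  joint <- ror_flag & prr_flag & ic_flag & ebgm_flag & n >= th$min_n

  out <- dplyr::mutate(
    x, n = as.integer(n),
    ror = ror, ror_lo95 = ror_lo95, ror_hi95 = ror_hi95,
    prr = prr, chi2 = chi2,
    ic = ic, ic_shrunk = ic_shrunk, ic025 = ic025, ic975 = ic975,
    ebgm = ebgm, ebgm05 = ebgm05, ebgm95 = ebgm95,
    ror_flag = ror_flag, prr_flag = prr_flag, ic_flag = ic_flag,
    ebgm_flag = ebgm_flag, joint_signal = joint)
  class(out) <- c("cartpv_signals", class(out))
  out
}

#' Evaluate a single 2x2 table
#'
#' Scalar convenience wrapper around [disproportionality()].
#'
#' @param a,b,c,d Cell counts: `a` target drug and target event, `b`
#'   target drug other events, `c` other drugs target event, `d` the rest.
#' @inheritParams disproportionality
#' @return One-row tibble of metrics and flags.
#' @export
signal_metrics <- function(a, b, c, d, ic_method = c("credibility", "delta"),
                           zero_correction = FALSE,
                           thresholds = signal_thresholds()) {
  disproportionality(tibble(a = a, b = b, c = c, d = d),
                     ic_method = match.arg(ic_method),
                     zero_correction = zero_correction,
                     thresholds = thresholds)
}

#' Screen the cohort for disproportionality signals
#'
#' Builds, for each pulmonary preferred term reported in the cohort (or
#' all terms with `pae_only = FALSE`), the 2x2 table of (report, PT) pairs
#' against the background and evaluates the four algorithms and the joint
#' signal rule.
#'
#' @param cohort A [build_cohort()] result.
#' @inheritParams disproportionality
#' @param pae_only Restrict to pulmonary terms (default).
#'
#' @return A `cartpv_signals` tibble sorted by descending `n`.
#' @export
signal_screen <- function(cohort, ic_method = c("credibility", "delta"),
                          zero_correction = FALSE,
                          thresholds = signal_thresholds(),
                          pae_only = TRUE) {
  stopifnot(inherits(cohort, "cart_cohort"))
  ev <- cohort$events
  pts <- if (pae_only) sort(unique(ev$pt[ev$is_pae])) else NULL
  contingency_counts(ev[, c("primaryid", "pt")], cohort$background_events,
                     pts = pts) |>
    disproportionality(ic_method = match.arg(ic_method),
                       zero_correction = zero_correction,
                       thresholds = thresholds) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Per-product IC025 stratification
#'
#' For every product-by-term pair with at least `min_cases` target pairs,
#' the lower 95% IC bound, with the comparator being all reports not
#' containing that product (the full-database background plus the other
#' cohort reports). Pairs below `min_cases` are absent, not zero. Reports
#' whose product assignment is ambiguous contribute to comparators only.
#'
#' @param cohort A [build_cohort()] result.
#' @param min_cases Minimum `a` for a cell to be reported (3).
#' @inheritParams disproportionality
#' @param pae_only Restrict to pulmonary terms (default).
#'
#' @return A tibble of class `cartpv_ic_matrix` with columns `product`,
#'   `pt`, `n`, `ic`, `ic025`, `signal` (`ic025 > 0`).
#' @export
per_drug_ic_matrix <- function(cohort, min_cases = 3,
                               ic_method = c("credibility", "delta"),
                               zero_correction = FALSE, pae_only = TRUE) {
  stopifnot(inherits(cohort, "cart_cohort"))
  ic_method <- match.arg(ic_method)
  ev <- cohort$events
  all_events <- dplyr::bind_rows(ev[, c("primaryid", "pt")],
                                 cohort$background_events)
  pts <- if (pae_only) sort(unique(ev$pt[ev$is_pae])) else
    sort(unique(ev$pt))
  products <- sort(unique(stats::na.omit(cohort$reports$product)))

  out <- purrr::map_dfr(products, function(p) {
    target_ids <- cohort$reports$primaryid[
      !is.na(cohort$reports$product) & cohort$reports$product == p]
    containing_ids <- cohort$reports$primaryid[
      purrr::map_lgl(cohort$reports$products, ~ p %in% .x)]
    tgt <- all_events[all_events$primaryid %in% target_ids, , drop = FALSE]
    cmp <- all_events[!all_events$primaryid %in% containing_ids, ,
                      drop = FALSE]
    if (nrow(tgt) == 0L) return(NULL)
    contingency_counts(tgt, cmp, pts = pts) |>
      dplyr::filter(.data$a >= min_cases) |>
      disproportionality(ic_method = ic_method,
                         zero_correction = zero_correction) |>
      dplyr::transmute(product = p, pt = .data$pt, n = .data$n,
                       ic = .data$ic, ic025 = .data$ic025,
                       signal = !is.na(.data$ic025) & .data$ic025 > 0)
  })
  class(out) <- c("cartpv_ic_matrix", class(out))
  out
}

#' Widen a per-product IC025 table into a product-by-term matrix
#'
#' @param x A [per_drug_ic_matrix()] result.
#' @return Tibble with one row per product, one column per term; absent
#'   cells (fewer than the minimum cases) are `NA`.
#' @export
ic_matrix_wide <- function(x) {
  tidyr::pivot_wider(as_tibble(x)[, c("product", "pt", "ic025")],
                     names_from = "pt", values_from = "ic025")
}
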