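# independent arithmetic oracle: each quantity computed directly from its
# closed form, separately from the vectorised implementation
oracle_metrics <- function(a, b, c, d) {
  a <- as.double(a); b <- as.double(b)
  c <- as.double(c); d <- as.double(d)
  N <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a / c) / (b / d)
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- (a * d - b * c)^2 * N / ((a + b) * (a + c) * (c + d) * (b + d))
  ic <- log((a * N) / ((a + b) * (a + c)), base = 2)
  E <- (a + b) * (a + c) / N
  ebgm <- (a / E)
  list(ror = ror, ror_lo95 = exp(log(ror) - 1.96 * se),
       ror_hi95 = exp(log(ror) + 1.96 * se),
       prr = prr, chi2 = chi2, ic = ic,
       ic025_cred = log2((a + 0.5) / (E + 0.5)) -
         3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5),
       ic975_cred = log2((a + 0.5) / (E + 0.5)) +
         2.4 * (a + 0.5)^(-0.5) + 0.5 * (a + 0.5)^(-1.5),
       ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.96 * se),
       ebgm95 = exp(log(ebgm) + 1.96 * se))
}

test_that("the worked 2x2 example reproduces every algorithm's arithmetic", {
  m <- signal_metrics(20, 80, 100, 9800)
  expect_equal(m$ror, 24.5)
  expect_equal(m$ror_lo95, exp(log(24.5) - 1.96 * sqrt(0.0726021)),
               tolerance = 1e-6)
  expect_equal(m$prr, 19.8)
  expect_equal(m$chi2, 188000^2 * 10000 / (100 * 120 * 9900 * 9880))
  expect_equal(m$ic, log2(20 * 10000 / (100 * 120)))
  expect_equal(m$ebgm, 20 * 10000 / (120 * 100))
  expect_true(all(m$ror_flag, m$prr_flag, m$ic_flag, m$ebgm_flag,
                  m$joint_signal))
})

test_that("all metrics match the arithmetic oracle on 1000 random tables", {
  withr::local_seed(515)
  a <- sample(1:500, 1000, TRUE)
  b <- sample(1:2000, 1000, TRUE)
  cc <- sample(1:5000, 1000, TRUE)
  d <- sample(1:100000, 1000, TRUE)
  got <- disproportionality(tibble::tibble(a = a, b = b, c = cc, d = d))
  want <- oracle_metrics(a, b, cc, d)
  rel <- function(x, y) max(abs(x - y) / pmax(abs(y), 1e-300))
  expect_lt(rel(got$ror, want$ror), 1e-12)
  expect_lt(rel(got$ror_lo95, want$ror_lo95), 1e-12)
  expect_lt(rel(got$ror_hi95, want$ror_hi95), 1e-12)
  expect_lt(rel(got$prr, want$prr), 1e-12)
  expect_lt(rel(got$chi2, want$chi2), 1e-12)
  expect_lt(max(abs(got$ic - want$ic)), 1e-12)
  expect_lt(max(abs(got$ic025 - want$ic025_cred)), 1e-12)
  expect_lt(max(abs(got$ic975 - want$ic975_cred)), 1e-12)
  expect_lt(rel(got$ebgm, want$ebgm), 1e-12)
  expect_lt(rel(got$ebgm05, want$ebgm05), 1e-12)
  expect_lt(rel(got$ebgm95, want$ebgm95), 1e-12)
  # ROR >= PRR whenever ROR >= 1, and interval ordering holds
  up <- got$ror >= 1
  expect_true(all(got$ror[up] >= got$prr[up]))
  expect_true(all(got$ror_lo95 <= got$ror & got$ror <= got$ror_hi95))
  expect_true(all(got$ebgm05 <= got$ebgm & got$ebgm <= got$ebgm95))
  # the credibility interval brackets the shrunk estimate
  expect_true(all(got$ic025 <= got$ic_shrunk & got$ic_shrunk <= got$ic975))
})

test_that("algebraic identities hold: EBGM = 2^IC, independence gives nulls", {
  withr::local_seed(99)
  tb <- tibble::tibble(a = sample(1:50, 200, TRUE),
                       b = sample(1:500, 200, TRUE),
                       c = sample(1:500, 200, TRUE),
                       d = sample(1:5000, 200, TRUE))
  got <- disproportionality(tb)
  expect_equal(got$ebgm, 2^got$ic, tolerance = 1e-12)

  u <- signal_metrics(10, 10, 10, 10)
  expect_equal(u$ror, 1)
  expect_equal(u$prr, 1)
  expect_equal(u$ebgm, 1)
  expect_equal(u$ic, 0)
  expect_equal(u$chi2, 0)
  expect_false(u$joint_signal)

  # proportional margins (independence), not just uniform
  ind <- signal_metrics(30, 70, 300, 700)
  expect_equal(ind$prr, 1)
  expect_equal(ind$ic, 0)
  expect_equal(ind$ebgm, 1)
  expect_equal(ind$ror, 1)
})

test_that("increasing a with other cells fixed strictly increases all estimates", {
  av <- 5:40
  got <- disproportionality(tibble::tibble(a = av, b = 100, c = 50,
                                           d = 5000))
  expect_true(all(diff(got$ror) > 0))
  expect_true(all(diff(got$prr) > 0))
  expect_true(all(diff(got$ic) > 0))
  expect_true(all(diff(got$ebgm) > 0))
})

test_that("no table with fewer than 3 cases is ever a joint signal", {
  for (a in 0:2) {
    m <- signal_metrics(a, 1, 1, 100000)  # huge disproportion
    expect_false(m$joint_signal, info = paste("a =", a))
  }
  # and undefined metrics (zero cells) force joint_signal false
  z <- signal_metrics(10, 0, 5, 1000)
  expect_true(is.na(z$ror))
  expect_false(z$joint_signal)
})

test_that("the IC variance model changes the interval, never the point", {
  cred <- signal_metrics(20, 80, 100, 9800, ic_method = "credibility")
  delt <- signal_metrics(20, 80, 100, 9800, ic_method = "delta")
  expect_equal(cred$ic, delt$ic)
  expect_false(isTRUE(all.equal(cred$ic025, delt$ic025)))
  expect_equal(delt$ic025, delt$ic - 1.96 / (sqrt(20) * log(2)))
  expect_true(delt$ic025 <= delt$ic & delt$ic <= delt$ic975)
})

test_that("the Haldane correction is off by default and applies on request", {
  plain <- signal_metrics(10, 0, 5, 1000)
  expect_true(is.na(plain$ror))
  corrected <- signal_metrics(10, 0, 5, 1000, zero_correction = TRUE)
  expect_equal(corrected$ror,
               (10.5 * 1000.5) / (0.5 * 5.5), tolerance = 1e-12)
  expect_equal(corrected$n, 10L)  # n stays the raw count
})

test_that("contingency building equals a brute-force double loop", {
  withr::local_seed(404)
  tgt <- tibble::tibble(
    primaryid = as.character(sample(100, 300, TRUE)),
    pt = sample(LETTERS[1:8], 300, TRUE))
  cmp <- tibble::tibble(
    primaryid = as.character(sample(1000:2000, 900, TRUE)),
    pt = sample(LETTERS[1:8], 900, TRUE))
  got <- contingency_counts(tgt, cmp)
  for (p in got$pt) {
    a <- sum(tgt$pt == p); cc <- sum(cmp$pt == p)
    row <- got[got$pt == p, ]
    expect_equal(row$a, a)
    expect_equal(row$b, nrow(tgt) - a)
    expect_equal(row$c, cc)
    expect_equal(row$d, nrow(cmp) - cc)
  }
  expect_error(contingency_counts(tgt[0, ], cmp[0, ]), "N = 0")
})

test_that("per-product IC025 cells match single-pair evaluation and drop a < 3", {
  g <- generate_faers(small_synth_config(seed = 23))
  co <- cohort_from_synth(g)
  mat <- per_drug_ic_matrix(co, min_cases = 3)
  expect_true(all(mat$n >= 3))
  # consistency: recompute one cell by hand
  row <- mat[which.max(mat$n), ]
  ids <- co$reports$primaryid[!is.na(co$reports$product) &
                                co$reports$product == row$product]
  containing <- co$reports$primaryid[
    purrr::map_lgl(co$reports$products, ~ row$product %in% .x)]
  all_ev <- dplyr::bind_rows(co$events[, c("primaryid", "pt")],
                             co$background_events)
  tab <- contingency_counts(all_ev[all_ev$primaryid %in% ids, ],
                            all_ev[!all_ev$primaryid %in% containing, ],
                            pts = row$pt)
  single <- disproportionality(tab)
  expect_equal(row$ic025, single$ic025)
  expect_equal(row$n, single$n)
  # the planted product-specific signal is present and positive
  expect_true(mat$ic025[mat$product == "Axi-cel" & mat$pt == "Hypoxia"] > 0)
})
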