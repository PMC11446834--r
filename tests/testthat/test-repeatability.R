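test_that("Cohen's kappa matches hand arithmetic on 2x2 tables", {
  # 32 participants, 9 positive on visit 1, 7 on visit 2, 4 on both
  k <- cohens_kappa(agreement_table(4, 5, 3, 20))
  expect_equal(k$po, 24 / 32)
  expect_equal(k$pe, (9 * 7 + 23 * 25) / 32^2)
  expect_equal(k$kappa, (0.75 - 638 / 1024) / (1 - 638 / 1024),
               tolerance = 1e-12)
  expect_equal(round(k$kappa, 3), 0.337)

  expect_equal(cohens_kappa(agreement_table(10, 0, 0, 10))$kappa, 1)
  # independence by construction: po = pe = 0.5
  expect_equal(cohens_kappa(agreement_table(10, 10, 10, 10))$kappa, 0)

  # a constant rater leaves kappa undefined, flagged not thrown
  und <- cohens_kappa(agreement_table(12, 0, 0, 0))
  expect_true(und$undefined)
  expect_true(is.na(und$kappa))
})

test_that("kappa is symmetric in visits and invariant to table scaling", {
  set.seed(5)
  for (i in 1:20) {
    cells <- as.integer(rmultinom(1, 40, runif(4, 0.05, 1)))
    k1 <- cohens_kappa(agreement_table(cells[1], cells[2], cells[3],
                                       cells[4]))$kappa
    kswap <- cohens_kappa(agreement_table(cells[1], cells[3], cells[2],
                                          cells[4]))$kappa
    kx3 <- cohens_kappa(agreement_table(3 * cells[1], 3 * cells[2],
                                        3 * cells[3], 3 * cells[4]))$kappa
    if (is.na(k1)) next
    expect_equal(k1, kswap, tolerance = 1e-12)
    expect_equal(k1, kx3, tolerance = 1e-12)
  }
})

test_that("kappa and ICC classification bands match the printed intervals", {
  expect_equal(kappa_class(c(0.10, 0.337, 0.474, 0.65, 0.85, 0.95)),
               c("none", "minimal", "weak", "moderate", "strong",
                 "almost perfect"))
  expect_equal(kappa_class(-0.2), "none")
  expect_equal(kappa_class(0.90), "strong")  # shared endpoint, lower band

  expect_equal(icc_class(c(0.34, 0.60, 0.80, 0.99)),
               c("poor", "moderate", "good", "excellent"))
  expect_equal(icc_class(c(0.50, 0.75, 0.90)),
               c("moderate", "moderate", "good"))
})

test_that("ICC recovers known variance components and matches an aov oracle", {
  # identical pairs with between-subject spread: perfect agreement
  x <- c(1, 2, 3, 4, 5, 9)
  expect_equal(icc(x, x, "ICC2_1")$icc, 1, tolerance = 1e-12)
  expect_equal(icc(x, x, "ICC3_1")$icc, 1, tolerance = 1e-12)

  # subject variance 3, visit noise variance 1: ICC(2,1) ~ 0.75
  set.seed(99)
  n <- 500
  subj <- rnorm(n, 10, sqrt(3))
  r <- icc(subj + rnorm(n), subj + rnorm(n), "ICC2_1")
  expect_equal(r$icc, 0.75, tolerance = 0.04)
  expect_lt(r$p, 1e-10)
  expect_lt(r$ci_lo, r$icc); expect_gt(r$ci_hi, r$icc)

  # 6-pair worked table equals the explicit mean-squares oracle
  x1 <- c(9.1, 10.4, 12.2, 8.0, 11.5, 10.0)
  x2 <- c(9.6, 10.0, 12.9, 8.3, 10.9, 10.7)
  for (form in c("ICC2_1", "ICC3_1")) {
    expect_equal(icc(x1, x2, form)$icc, icc_aov_oracle(x1, x2, form),
                 tolerance = 1e-10, label = form)
  }

  # symmetric in visit relabeling
  expect_equal(icc(x1, x2, "ICC2_1")$icc, icc(x2, x1, "ICC2_1")$icc,
               tolerance = 1e-12)

  # ICC rises to 1 as the visit noise shrinks
  set.seed(123)
  base <- rnorm(80, 0, sqrt(3))
  iccs <- vapply(c(2, 1, 0.5, 0.2, 0.05, 0.001), function(s) {
    icc(base + rnorm(80, 0, s), base + rnorm(80, 0, s), "ICC2_1")$icc
  }, numeric(1))
  expect_true(all(diff(iccs) > 0))
  expect_gt(iccs[length(iccs)], 0.999)

  expect_true(icc(c(1, 1, 1), c(1, 1, 1))$undefined)
  expect_error(icc(1:2, 1:2), ">= 3")
})

test_that("between-day CV matches its closed form and recovers itself", {
  expect_equal(between_day_cv(c(3, 4, 5), c(3, 4, 5)), 0)
  # single pair (90, 110): s = 20/sqrt(2), mean 100
  expect_equal(between_day_cv(90, 110), 100 * (20 / sqrt(2)) / 100,
               tolerance = 1e-9)
  expect_equal(between_day_cv(90, 110), 14.14, tolerance = 1e-2)

  # simulated 5% within-subject CV at n = 500
  set.seed(42)
  mu <- runif(500, 80, 120)
  x1 <- mu * (1 + 0.05 * rnorm(500))
  x2 <- mu * (1 + 0.05 * rnorm(500))
  expect_equal(between_day_cv(x1, x2), 5, tolerance = 0.5)

  expect_error(between_day_cv(c(-2, 0), c(1, 1)), "positive")
})

test_that("paired t and Fisher's exact behave as their references", {
  pt <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pt$t, 0); expect_equal(pt$p, 1)

  set.seed(8)
  a <- rnorm(15); b <- a + rnorm(15, 0.4)
  ref <- t.test(a, b, paired = TRUE)
  got <- paired_t(a, b)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)

  # visit-wise EFL frequencies: 9/23 vs 7/25 (n = 32 each)
  p <- fisher_exact(9, 23, 7, 25)
  expect_equal(p, fisher_oracle(9, 23, 7, 25), tolerance = 1e-9)
  expect_equal(round(p, 2), 0.77)

  # symmetry of extreme tables
  expect_equal(fisher_exact(10, 0, 0, 10), fisher_exact(0, 10, 10, 0))

  # enumeration oracle across random tables with n <= 40
  set.seed(14)
  for (i in 1:30) {
    cells <- as.integer(rmultinom(1, sample(8:40, 1), runif(4, 0.1, 1)))
    expect_equal(fisher_exact(cells[1], cells[2], cells[3], cells[4]),
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("repeatability reports assemble, tidy and serialize", {
  set.seed(21)
  n <- 12
  base_vt <- rnorm(n, 2.4, 0.4)
  base_ic <- rnorm(n, 3.1, 0.5)
  pairs <- tibble::tibble(
    VT_1 = base_vt * (1 + 0.03 * rnorm(n)),
    VT_2 = base_vt * (1 + 0.03 * rnorm(n)),
    IC_1 = base_ic * (1 + 0.03 * rnorm(n)),
    IC_2 = base_ic * (1 + 0.03 * rnorm(n)),
    EFL_1 = c(rep(TRUE, 4), rep(FALSE, 8)),
    EFL_2 = c(rep(TRUE, 3), FALSE, FALSE, TRUE, rep(FALSE, 6)))
  rep_ <- repeatability_report(pairs)
  expect_s3_class(rep_, "repeat_report")
  expect_setequal(rep_$continuous$parameter, c("VT", "IC"))
  expect_true(all(rep_$continuous$icc <= 1))
  expect_false(is.null(rep_$binary))
  expect_equal(rep_$binary$kappa,
               cohens_kappa(agreement_from_pairs(pairs$EFL_1,
                                                 pairs$EFL_2))$kappa)

  td <- tidy(rep_)
  expect_equal(nrow(td), 3)  # VT, IC, EFL
  expect_true("kappa" %in% td$statistic_type)
  gl <- glance(rep_)
  expect_equal(gl$n_pairs, n)

  path <- withr::local_tempfile(fileext = ".json")
  write_repeat_report(rep_, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_pairs, n)
  expect_equal(back$binary$kappa, rep_$binary$kappa, tolerance = 1e-9)
})
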