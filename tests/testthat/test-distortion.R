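# Exact binomial machinery and the class-level distortion scan.

test_that("expected frequencies follow the cross design", {
  expect_equal(as.numeric(expected_frequency("backcross", "FUSION_SWE")),
               0.75)
  expect_equal(as.numeric(expected_frequency("intercross", "HOMOLOGOUS")),
               0.5)
  z <- expected_frequency("backcross", "SEX_Z")
  expect_equal(as.numeric(z), 1.0)
  expect_false(attr(z, "testable"))
  expect_error(expected_frequency("backcross", "EXCLUDED_COMPLEX"),
               "EXCLUDED_COMPLEX")
})

test_that("counts are rounded per unit and pairs are the trials", {
  expect_equal(counts_from_af(0.75, 4)[c("k", "n")], list(k = 3L, n = 4L))
  expect_equal(counts_from_af(0.5, 3)$k, 2L)  # half-up tie rule
  expect_equal(counts_from_af(0.5, 5)$k, 3L)
  expect_equal(counts_from_af(0.5, 5, rounding = "half_even")$k, 2L)
  cls <- counts_from_af(rep(0.701, 6), 67)
  expect_equal(cls$k, 282L)
  expect_equal(cls$n, 402L)
  expect_error(counts_from_af(1.2, 10), "outside")
})

test_that("exact binomial test matches enumeration anchors", {
  flat <- exact_binomial_test(2, 4, 0.5)
  expect_equal(flat$p_value, 1.0) # every outcome is <= P(2) = 6/16
  tail0 <- exact_binomial_test(0, 10, 0.5)
  expect_equal(tail0$p_value, 2 / 1024)
  expect_equal(tail0$ci_low, 0)
  t1 <- exact_binomial_test(282, 402, 0.75)
  expect_equal(round(t1$p_value, 3), 0.028)
  expect_equal(round(t1$ci_low, 3), 0.654)
  expect_equal(round(t1$ci_high, 3), 0.746)
})

test_that("exact test and interval agree with the reference implementation", {
  for (n in c(1, 2, 5, 11, 17, 25)) {
    for (p0 in c(0.1, 0.5, 0.75)) {
      for (k in 0:n) {
        mine <- exact_binomial_test(k, n, p0)
        ref <- stats::binom.test(k, n, p0)
        expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
        expect_equal(c(mine$ci_low, mine$ci_high),
                     as.numeric(ref$conf.int), tolerance = 1e-12)
      }
    }
  }
})

test_that("the null-consistent count maximizes the p-value", {
  for (n in c(20, 67, 150)) {
    for (p0 in c(0.5, 0.75)) {
      p <- vapply(0:n, function(k) exact_binomial_test(k, n, p0)$p_value,
                  numeric(1))
      expect_lte(abs((which.max(p) - 1L) - round(n * p0)), 1)
    }
  }
})

test_that("count recovery finds the pairs behind printed summaries", {
  cand <- recover_counts_from_summary(0.701, 0.654, 0.746, n_max = 1000)
  expect_true(any(cand$k == 282 & cand$n == 402))
  expect_true(all(diff(cand$n) >= 0))

  # interval of (2, 4) computed with the Clopper-Pearson oracle
  cand2 <- recover_counts_from_summary(0.5, 0.068, 0.932, n_max = 100,
                                       n_min = 2L)
  expect_true(any(cand2$k == 2 & cand2$n == 4))

  cand3 <- recover_counts_from_summary(0.531, 0.511, 0.551, n_max = 5000)
  expect_true(2396 %in% cand3$n) # 4 units x 599 individuals
  expect_equal(nrow(recover_counts_from_summary(0.5, 0.49, 0.51,
                                                n_max = 20)), 0L)
})

test_that("the distortion scan reports classes, units and trends", {
  sim <- study_sim(markers_per_chromosome = 10)
  pools <- backcross_pools()
  co <- simulate_backcross(67, drive_params(FUSION_SWE = 0.9),
                           sim$karyotype, seed = 31)
  cts <- simulate_pool_reads(co, sim$markers, pools, seed = 32)
  maf <- marker_af_table(cts, pools)
  uaf <- suppressWarnings(aggregate_unit_af(maf, sim$markers,
                                            sim$karyotype))
  scan <- run_distortion_scan(uaf, "backcross", 67)
  expect_setequal(scan$classes$chromosome_type,
                  c("Fission CAT", "Fusion SWE", "Homologous",
                    "Unknown polarization"))
  expect_true(all(scan$classes$expected_frequency == 0.75))
  expect_true(all(scan$classes$lower_95_CI <=
                    scan$classes$observed_frequency &
                  scan$classes$observed_frequency <=
                    scan$classes$upper_95_CI))
  expect_true(all(scan$classes$k <= scan$classes$n))
  fus <- scan$classes[scan$classes$chromosome_type == "Fusion SWE", ]
  expect_lt(fus$observed_frequency, 0.65) # strong drive against fusion
  expect_lt(fus$p_value, 0.001)
  expect_true(is.data.frame(scan$units))
  expect_true("opposite_to_class_trend" %in% names(scan$units))

  empty <- run_distortion_scan(uaf[0, ], "backcross", 67)
  expect_equal(nrow(empty$classes), 0L)

  expect_warning(run_distortion_scan(uaf[uaf$class == "HOMOLOGOUS", ],
                                     "backcross", 67),
                 "FUSION_SWE")
})

test_that("drive at the study's magnitude is detectable with fair power", {
  sim <- study_sim(markers_per_chromosome = 10)
  pools <- backcross_pools()
  hits <- 0L
  n_rep <- 25L
  obs <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    co <- simulate_backcross(67, drive_params(FUSION_SWE = 0.6),
                             sim$karyotype, seed = 100 + r)
    cts <- simulate_pool_reads(co, sim$markers, pools, seed = 200 + r)
    maf <- marker_af_table(cts, pools)
    uaf <- suppressWarnings(aggregate_unit_af(maf, sim$markers,
                                              sim$karyotype))
    scan <- run_distortion_scan(uaf, "backcross", 67)
    fus <- scan$classes[scan$classes$chromosome_type == "Fusion SWE", ]
    obs[r] <- fus$observed_frequency
    hits <- hits + (fus$p_value < 0.05)
  }
  expect_equal(mean(obs), 0.70, tolerance = 0.02) # 1 - d/2 at d = 0.6
  expect_gte(hits / n_rep, 0.6)
})
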