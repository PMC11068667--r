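# Allele frequency estimation, pooling, orientation averaging, filtering.

test_that("marker AF and the polymorphism filter behave at the anchors", {
  bal <- estimate_marker_af(30, 30)
  expect_equal(bal$af, 0.5)
  expect_true(bal$retained) # p far below 1e-6

  mono <- estimate_marker_af(60, 0)
  expect_equal(mono$af, 1.0)
  expect_false(mono$retained) # consistent with a monomorphic site

  thin <- estimate_marker_af(5, 1)
  expect_equal(thin$af, 5 / 6, tolerance = 1e-12)
  expect_gt(thin$p_lr, 1e-6)
  expect_false(thin$retained)

  none <- estimate_marker_af(0, 0, other = 7)
  expect_true(is.na(none$af))
  expect_false(none$retained)
})

test_that("retention is monotonic in depth at fixed true frequency", {
  depths <- c(10, 30, 100, 300, 1000)
  p <- vapply(depths, function(d) {
    estimate_marker_af(round(0.7 * d), d - round(0.7 * d))$p_lr
  }, numeric(1))
  expect_true(all(diff(p) < 0))
  retained <- estimate_marker_af(round(0.7 * depths),
                                 depths - round(0.7 * depths))$retained
  expect_true(all(diff(as.integer(retained)) >= 0))
})

test_that("pool combination weights by individuals", {
  expect_equal(combine_pools(c(0.7, 0.8), c(100, 300)), 0.775)
  expect_equal(combine_pools(0.63, 50), 0.63)
  sizes <- c(298, 73, 72, 76, 80) # the study's intercross pools
  expect_equal(combine_pools(rep(0.4812, 5), sizes), 0.4812)
  expect_equal(combine_pools(c(0.7, 0.8), c(100, 300), "equal"), 0.75)
  expect_equal(combine_pools(c(NA, 0.8), c(100, 300)), 0.8)
})

test_that("orientation averaging is the arithmetic mean with fallback", {
  avg <- average_orientations(c(0.4, 0.526, 0.75, NA),
                              c(0.6, 0.474, 0.75, 0.9))
  expect_equal(avg$af_mean, c(0.5, 0.5, 0.75, 0.9))
  expect_equal(avg$single_orientation, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(average_orientations(NA_real_, NA_real_), "orientation")
})

test_that("unit aggregation averages chromosome means, not markers", {
  kar <- karyotype(data.frame(
    unit_id = c("u1", "h1"), swe_chrom = c("s1", "s2"),
    cat_chroms = c("c1;c2", "c3"),
    state_swe = "FUSED", state_cat = c("UNFUSED", "FUSED"),
    state_reali = c("UNFUSED", "FUSED"),
    state_juvernica = c("UNFUSED", "FUSED"),
    is_sex = FALSE, stringsAsFactors = FALSE))
  markers <- data.frame(
    chrom = c("c1", "c1", "c2", "c3", "c3", "c3"),
    pos = c(1, 2, 1, 1, 2, 3),
    swe_allele = "A", cat_allele = "T",
    unit_id = c("u1", "u1", "u1", "h1", "h1", "h1"),
    stringsAsFactors = FALSE)
  marker_af <- data.frame(
    chrom = markers$chrom, pos = markers$pos,
    af_mean = c(0.68, 0.72, 0.72, 0.5, 0.5, 0.5),
    retained = TRUE, stringsAsFactors = FALSE)
  uaf <- aggregate_unit_af(marker_af, markers, kar)
  # c1 mean 0.70, c2 mean 0.72 -> unit mean 0.71 despite unequal markers
  expect_equal(uaf$mean_af[uaf$unit_id == "u1"], 0.71)
  expect_equal(uaf$af_cat_1[uaf$unit_id == "u1"], 0.70)
  expect_equal(uaf$af_cat_2[uaf$unit_id == "u1"], 0.72)
  expect_equal(uaf$mean_af[uaf$unit_id == "h1"], 0.5)
  expect_true(all(uaf$mean_af >= min(marker_af$af_mean) &
                    uaf$mean_af <= max(marker_af$af_mean)))

  marker_af$retained[4:6] <- FALSE
  expect_warning(aggregate_unit_af(marker_af, markers, kar), "h1")
})

test_that("dual-orientation averaging cancels symmetric reference bias", {
  sim <- small_sim(markers_per_chromosome = 25)
  co <- simulate_backcross(400, drive_params(), sim$karyotype, seed = 21)
  pools <- data.frame(pool_spec("p", 400, mean_depth = 120,
                                error_rate = 0, ref_bias = 0.3))
  cts <- simulate_pool_reads(co, sim$markers, pools, seed = 22)
  maf <- marker_af_table(cts, pools)
  truth <- true_unit_af(co)
  names(truth) <- co$units$unit_id
  m <- merge(maf, sim$markers[, c("chrom", "pos", "unit_id")],
             by = c("chrom", "pos"))
  m <- m[m$unit_id %in% co$units$unit_id[!co$units$is_sex], ]
  err_mean <- abs(mean(m$af_mean - truth[m$unit_id]))
  err_single <- abs(mean(m$af_swe_orientation - truth[m$unit_id]))
  expect_lt(err_mean, err_single) # averaging beats one orientation
  expect_lt(err_mean, 0.01)
  expect_gt(err_single, 0.02) # bias 0.3 visibly distorts one mapping
  expect_true(all(maf$af_mean >= 0 & maf$af_mean <= 1))
})

test_that("relabeling the reference orientations leaves af_mean invariant", {
  sim <- small_sim(markers_per_chromosome = 5)
  co <- simulate_backcross(30, drive_params(), sim$karyotype, seed = 23)
  pools <- data.frame(pool_spec("p", 30, mean_depth = 60, ref_bias = 0.1))
  cts <- simulate_pool_reads(co, sim$markers, pools, seed = 24)
  swapped <- cts
  swapped$orientation <- ifelse(cts$orientation == "SWE_ref",
                                "CAT_ref", "SWE_ref")
  a <- marker_af_table(cts, pools)
  b <- marker_af_table(swapped, pools)
  expect_equal(a$af_mean, b$af_mean)
  expect_equal(a$af_swe_orientation, b$af_cat_orientation)
})
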