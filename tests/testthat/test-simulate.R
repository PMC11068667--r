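# Forward simulator: meiosis, crosses, pooling, reads.

test_that("make_karyotype_and_markers builds the requested structure", {
  sim <- study_sim(markers_per_chromosome = 5)
  expect_equal(nrow(sim$karyotype), 23L) # 6 + 5 + 4 + 5 + 3 Z
  expect_equal(n_z_units(sim$karyotype), 3L)
  # every 1:2 unit has markers on both CAT chromosomes
  two_cat <- sim$karyotype[sim$karyotype$n_cat == 2L, ]
  for (i in seq_len(nrow(two_cat))) {
    chroms <- strsplit(two_cat$cat_chroms[i], ";")[[1]]
    mk <- sim$markers[sim$markers$unit_id == two_cat$unit_id[i], ]
    expect_setequal(unique(mk$chrom), chroms)
  }
  expect_true(all(sim$markers$swe_allele != sim$markers$cat_allele))
  expect_false(any(duplicated(sim$markers[, c("chrom", "pos")])))

  expect_identical(study_sim(markers_per_chromosome = 5),
                   study_sim(markers_per_chromosome = 5))
  empty <- make_karyotype_and_markers(
    n_per_class = c(FUSION_SWE = 0L), n_z = 0L)
  expect_equal(nrow(empty$karyotype), 0L)
  expect_equal(nrow(empty$markers), 0L)
  expect_error(make_karyotype_and_markers(markers_per_chromosome = 0),
               "markers_per_chromosome")
})

test_that("female gametes follow the drive probabilities", {
  sim <- small_sim()
  full <- simulate_female_gametes(
    200, drive_params(FISSION_CAT = 1, FUSION_SWE = 1,
                      UNKNOWN_POLARIZATION = 1, HOMOLOGOUS = 1),
    sim$karyotype, seed = 1)
  expect_true(all(full == 1L)) # d = 1: every gamete carries the CAT state

  n <- 1e5
  g <- simulate_female_gametes(n, drive_params(FUSION_SWE = 0.6),
                               sim$karyotype, seed = 2)
  frac <- mean(g[, grepl("FUSION_SWE", colnames(g))])
  se <- sqrt(0.6 * 0.4 / (2 * n))
  expect_lt(abs(frac - 0.6), 3 * se)
  frac05 <- mean(g[, grepl("HOMOLOGOUS", colnames(g))])
  expect_lt(abs(frac05 - 0.5), 3 * sqrt(0.25 / (2 * n)))
})

test_that("backcross allele frequencies follow 1 - d/2", {
  sim <- small_sim()
  # d = 1 is deterministic: every maternal copy is CAT, af exactly 0.5
  co1 <- simulate_backcross(50, drive_params(1, 1, 1, 1), sim$karyotype,
                            seed = 3)
  af1 <- true_unit_af(co1)
  auto <- !co1$units$is_sex
  expect_equal(unname(af1[auto]), rep(0.5, sum(auto)))
  # Z units are monomorphic SWE in the backcross
  expect_equal(unname(af1[!auto]), rep(1.0, sum(!auto)))

  n <- 20000
  co <- simulate_backcross(n, drive_params(FUSION_SWE = 0.6),
                           sim$karyotype, seed = 4)
  af <- true_unit_af(co)
  se <- sqrt(0.6 * 0.4 / n) / 2
  fus <- grepl("FUSION_SWE", co$units$unit_id)
  expect_lt(max(abs(af[fus] - 0.7)), 3.5 * se) # 1 - 0.6/2
  hom <- co$units$class == "HOMOLOGOUS"
  expect_lt(max(abs(af[hom] - 0.75)), 3.5 * sqrt(0.25 / n) / 2)
})

test_that("intercross expectation is ((1-d_f) + (1-d_m))/2", {
  sim <- small_sim()
  n <- 20000
  co <- simulate_intercross(n, drive_params(FUSION_SWE = 0.6),
                            drive_params(), sim$karyotype, recomb = FALSE,
                            seed = 5)
  af <- true_unit_af(co)
  fus <- grepl("FUSION_SWE", co$units$unit_id)
  se <- sqrt((0.6 * 0.4 + 0.25) / (4 * n))
  expect_lt(max(abs(af[fus] - 0.45)), 3.5 * se)
  hom <- co$units$class == "HOMOLOGOUS"
  expect_lt(max(abs(af[hom] - 0.5)), 3.5 * sqrt(0.5 / (4 * n)))
})

test_that("male recombination leaves Mendelian marker expectations intact", {
  sim <- small_sim(markers_per_chromosome = 20)
  pools <- data.frame(pool_spec("all", 4000, mean_depth = 30,
                                error_rate = 0, ref_bias = 0))
  af_by_recomb <- vapply(c(FALSE, TRUE), function(rc) {
    co <- simulate_intercross(4000, drive_params(), drive_params(),
                              sim$karyotype, recomb = rc, seed = 6)
    cts <- simulate_pool_reads(co, sim$markers, pools, seed = 7)
    maf <- marker_af_table(cts, pools)
    uaf <- suppressWarnings(aggregate_unit_af(maf, sim$markers,
                                              sim$karyotype))
    mean(uaf$mean_af[uaf$class != "SEX_Z"])
  }, numeric(1))
  se <- sqrt(0.5 / (4 * 4000 * 8)) # 8 autosomal units
  expect_lt(abs(af_by_recomb[1] - 0.5), 4 * se + 0.005)
  expect_lt(abs(diff(af_by_recomb)), 0.01)
})

test_that("pool reads honour boundary and thinning algebra", {
  sim <- small_sim(markers_per_chromosome = 5)
  # d = 0: all maternal copies SWE -> q = 1 everywhere in a backcross
  co <- simulate_backcross(40, drive_params(0, 0, 0, 0), sim$karyotype,
                           seed = 8)
  pools <- data.frame(pool_spec("p", 40, mean_depth = 100,
                                error_rate = 0, ref_bias = 0))
  cts <- simulate_pool_reads(co, sim$markers, pools, seed = 9)
  expect_true(all(cts$cat_reads == 0))
  expect_true(all(cts$other_reads == 0))
  expect_gt(sum(cts$swe_reads), 0)

  # d_HOMOLOGOUS = 1 makes homologous units exactly q = 0.5; symmetric
  # ref bias then gives af ~ 0.5/(0.5 + 0.45) in the SWE orientation
  co2 <- simulate_backcross(40, drive_params(HOMOLOGOUS = 1),
                            sim$karyotype, seed = 10)
  pools2 <- data.frame(pool_spec("p", 40, mean_depth = 2e5,
                                 depth_model = "fixed", error_rate = 0,
                                 ref_bias = 0.1))
  hom_mk <- sim$markers[grepl("HOMOLOGOUS", sim$markers$unit_id), ][1:3, ]
  cts2 <- simulate_pool_reads(co2, hom_mk, pools2, seed = 11)
  af <- with(cts2, swe_reads / (swe_reads + cat_reads))
  swe_ref <- cts2$orientation == "SWE_ref"
  expect_equal(mean(af[swe_ref]), 0.5 / 0.95, tolerance = 0.01)
  expect_equal(mean(af[!swe_ref]), 0.45 / 0.95, tolerance = 0.01)
  expect_equal(mean(c(af[swe_ref], af[!swe_ref])), 0.5, tolerance = 0.005)
})

test_that("identical seeds give identical simulated read counts", {
  sim <- small_sim(markers_per_chromosome = 5)
  co <- simulate_backcross(20, drive_params(), sim$karyotype, seed = 12)
  pools <- backcross_pools()
  pools$n_individuals <- c(10L, 10L)
  a <- simulate_pool_reads(co, sim$markers, pools, seed = 13)
  b <- simulate_pool_reads(co, sim$markers, pools, seed = 13)
  expect_identical(a, b)
  d <- simulate_pool_reads(co, sim$markers, pools, seed = 14)
  expect_false(identical(a, d))
})

test_that("aneuploidy injection scales coverage and shifts dosage", {
  sim <- small_sim(markers_per_chromosome = 5)
  co <- simulate_backcross(50, drive_params(), sim$karyotype, seed = 15)
  expect_identical(inject_aneuploidy(co, "FUSION_SWE_1", 0), co)
  expect_error(inject_aneuploidy(co, "nope", 0.5), "unknown unit_id")

  tri <- inject_aneuploidy(co, "FUSION_SWE_1", 1, extra_origin = "S",
                           seed = 16)
  pools <- data.frame(pool_spec("p", 50, mean_depth = 400,
                                depth_model = "fixed", error_rate = 0,
                                ref_bias = 0))
  cts_n <- simulate_pool_reads(co, sim$markers, pools, seed = 17)
  cts_t <- simulate_pool_reads(tri, sim$markers, pools, seed = 17)
  depth_of <- function(cts, unit) {
    mk <- sim$markers[sim$markers$unit_id == unit, c("chrom", "pos")]
    sub <- merge(cts, mk, by = c("chrom", "pos"))
    mean(sub$swe_reads + sub$cat_reads + sub$other_reads)
  }
  expect_equal(depth_of(cts_t, "FUSION_SWE_1") /
                 depth_of(cts_n, "FUSION_SWE_1"), 1.5, tolerance = 0.02)
  expect_equal(depth_of(cts_t, "HOMOLOGOUS_1"),
               depth_of(cts_n, "HOMOLOGOUS_1"), tolerance = 0.02)
  af_of <- function(cts, unit) {
    mk <- sim$markers[sim$markers$unit_id == unit, c("chrom", "pos")]
    sub <- merge(cts, mk, by = c("chrom", "pos"))
    sum(sub$swe_reads) / sum(sub$swe_reads + sub$cat_reads)
  }
  expect_gt(af_of(cts_t, "FUSION_SWE_1"), af_of(cts_n, "FUSION_SWE_1"))
})

test_that("viability selection shifts survivor pools but not egg pools", {
  sim <- small_sim()
  co <- simulate_intercross(4000, drive_params(), drive_params(),
                            sim$karyotype, recomb = FALSE, seed = 18)
  expect_true(all(viability_filter(co)$stage == "survivor"))

  loss <- data.frame(unit_id = "FUSION_SWE_1", genotype = "CC",
                     loss_prob = 0.8, stringsAsFactors = FALSE)
  filt <- viability_filter(co, loss, seed = 19)
  expect_setequal(unique(filt$stage), c("survivor", "dead_embryo"))
  adults <- subset_cohort(filt, filt$stage == "survivor")
  af_all <- true_unit_af(co)
  af_adults <- true_unit_af(adults)
  j <- match("FUSION_SWE_1", co$units$unit_id)
  expect_gt(af_adults[j], af_all[j] + 0.03) # CC losses enrich SWE
  j2 <- match("HOMOLOGOUS_1", co$units$unit_id)
  expect_lt(abs(af_adults[j2] - af_all[j2]), 0.03)
})
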