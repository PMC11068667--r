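# Shared fixtures, built in code.

# compact karyotype for unit tests: 2 units per autosomal class + 1 Z
small_sim <- function(markers_per_chromosome = 10, n_z = 1L, seed = 42L,
                      n_per_class = c(FUSION_SWE = 2L, FISSION_CAT = 2L,
                                      UNKNOWN_POLARIZATION = 2L,
                                      HOMOLOGOUS = 2L)) {
  make_karyotype_and_markers(n_per_class = n_per_class,
                             markers_per_chromosome = markers_per_chromosome,
                             n_z = n_z, seed = seed)
}

# study-scale karyotype (6/5/4/5 autosomal units, 3 Z), reduced marker count
study_sim <- function(markers_per_chromosome = 40, seed = 42L) {
  make_karyotype_and_markers(markers_per_chromosome = markers_per_chromosome,
                             seed = seed)
}

backcross_pools <- function(mean_depth = 50, error_rate = 0.002,
                            ref_bias = 0.02, depth_model = "poisson") {
  rbind(pool_spec("fam1", 32, mean_depth, depth_model, error_rate, ref_bias),
        pool_spec("fam2", 35, mean_depth, depth_model, error_rate, ref_bias))
}

# true pool SWE frequency per unit straight from the cohort matrices
# (independent of the read simulator)
true_unit_af <- function(cohort) {
  vapply(seq_len(nrow(cohort$units)), function(j) {
    mat <- cohort$maternal[, j]
    pat <- cohort$paternal[, j]
    swe <- ifelse(is.na(mat), 0L, 1L - mat) +
      ifelse(is.na(pat), 0L, 1L - pat)
    copies <- as.integer(!is.na(mat)) + as.integer(!is.na(pat))
    sum(swe) / sum(copies)
  }, numeric(1))
}
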