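# Forward simulator of heterokaryotypic meiosis and pooled sequencing.
#
# The model follows the biology of Leptidea sinapis hybrids: F1 females are
# heterokaryotypic for every rearranged unit (one fused SWE chromosome
# pairing with two unfused CAT homologs in a trivalent). Female meiosis is
# achiasmatic, so each unit transmits intact; a single drive parameter per
# rearrangement class gives the probability that the unfused (CAT) side of
# the trivalent segregates to the egg pole. Male meiosis is chiasmatic and
# can carry one obligate crossover per unit. Offspring are pooled and
# sequenced; reads are simulated per marker with Poisson (or fixed) depth,
# a symmetric sequencing error, and orientation-specific reference bias for
# the two modified reference genomes (all fixed differences set to the SWE
# or the CAT allele).

#' Drive parameters per rearrangement class
#'
#' For rearranged units, the value is the probability that the unfused
#' (CAT-state) chromosome pair of the trivalent segregates to the egg pole
#' during F1 female meiosis: 0.5 is Mendelian, values above 0.5 favour the
#' unfused/CAT state. For `HOMOLOGOUS` units it is the probability that the
#' CAT-origin homolog goes to the egg.
#'
#' @param FISSION_CAT,FUSION_SWE,UNKNOWN_POLARIZATION,HOMOLOGOUS
#'   Probabilities in \[0, 1\].
#' @return Named numeric vector keyed by rearrangement class.
#' @export
drive_params <- function(FISSION_CAT = 0.5, FUSION_SWE = 0.5,
                         UNKNOWN_POLARIZATION = 0.5, HOMOLOGOUS = 0.5) {
  d <- c(FISSION_CAT = FISSION_CAT, FUSION_SWE = FUSION_SWE,
         UNKNOWN_POLARIZATION = UNKNOWN_POLARIZATION,
         HOMOLOGOUS = HOMOLOGOUS)
  for (nm in names(d)) stopifnot_scalar_prob(d[[nm]], nm)
  d
}

#' Sequencing pool specification
#'
#' @param pool_id Pool label.
#' @param n_individuals Number of F2 individuals in the pool.
#' @param mean_depth Expected read depth per marker for a pool of diploid
#'   individuals (scaled by relative copy number, e.g. 0.75 for Z markers
#'   in a mixed-sex pool).
#' @param depth_model `"poisson"` (default) or `"fixed"`.
#' @param error_rate Probability that a read reports a wrong base; wrong
#'   bases are uniform over the three alternatives, so a third of errors
#'   convert one marker allele into the other and two thirds produce
#'   `other` reads.
#' @param ref_bias Probability in \[0, 0.5) that a read carrying the
#'   non-reference allele of a mapping orientation is lost in that
#'   orientation.
#' @return A one-row data.frame; combine pools with `rbind()`.
#' @export
pool_spec <- function(pool_id, n_individuals, mean_depth = 50,
                      depth_model = c("poisson", "fixed"),
                      error_rate = 0.002, ref_bias = 0.02) {
  depth_model <- match.arg(depth_model)
  stopifnot(n_individuals >= 1, mean_depth > 0)
  stopifnot_scalar_prob(error_rate, "error_rate")
  if (ref_bias < 0 || ref_bias >= 0.5) {
    stop("`ref_bias` must be in [0, 0.5)", call. = FALSE)
  }
  data.frame(pool_id = as.character(pool_id),
             n_individuals = as.integer(n_individuals),
             mean_depth = mean_depth, depth_model = depth_model,
             error_rate = error_rate, ref_bias = ref_bias,
             stringsAsFactors = FALSE)
}

#' Intercross pool sizes of the original study design
#'
#' Five life-stage pools of F2 intercross offspring: dead embryos (298),
#' eggs (73), dead larvae plus dead pupae (72), adult males (76) and adult
#' females (80); 599 individuals in total.
#'
#' @return Named integer vector of pool sizes.
#' @export
default_intercross_pool_sizes <- function() {
  c(dead_embryos = 298L, eggs = 73L, dead_larvae_pupae = 72L,
    adult_males = 76L, adult_females = 80L)
}

#' Generate a karyotype and fixed-difference marker set
#'
#' Builds a synthetic hybrid karyotype with the requested number of units
#' per rearrangement class plus `n_z` Z chromosome units, and places
#' `markers_per_chromosome` fixed differences on every CAT chromosome.
#' Rearranged units carry two CAT chromosomes (markers on both); homologous
#' and Z units carry one. Defaults mirror the study scale: class sizes
#' 6/5/4/5, three Z units, and enough markers per chromosome to reach
#' roughly 27,700 fixed differences genome-wide.
#'
#' @param n_per_class Named vector of unit counts for `FUSION_SWE`,
#'   `FISSION_CAT`, `UNKNOWN_POLARIZATION`, `HOMOLOGOUS`.
#' @param markers_per_chromosome Markers per CAT chromosome (>= 1).
#' @param n_z Number of Z units.
#' @param chrom_length Chromosome length within which marker positions are
#'   drawn.
#' @param seed Optional integer seed; identical seeds give identical
#'   output.
#' @return A list with elements `karyotype` and `markers` (data.frame with
#'   columns `chrom`, `pos`, `swe_allele`, `cat_allele`, `unit_id`).
#' @export
make_karyotype_and_markers <- function(
    n_per_class = c(FUSION_SWE = 6L, FISSION_CAT = 5L,
                    UNKNOWN_POLARIZATION = 4L, HOMOLOGOUS = 5L),
    markers_per_chromosome = 730L, n_z = 3L, chrom_length = 5e6,
    seed = NULL) {
  stopifnot(all(n_per_class >= 0), n_z >= 0)
  if (markers_per_chromosome < 1L) {
    stop("`markers_per_chromosome` must be >= 1", call. = FALSE)
  }
  defaults <- c(FUSION_SWE = 0L, FISSION_CAT = 0L,
                UNKNOWN_POLARIZATION = 0L, HOMOLOGOUS = 0L)
  bad <- setdiff(names(n_per_class), names(defaults))
  if (length(bad)) stop("unknown class in n_per_class: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  defaults[names(n_per_class)] <- as.integer(n_per_class)
  n_per_class <- defaults

  states <- list(
    FUSION_SWE = c("FUSED", "UNFUSED", "UNFUSED", "UNFUSED"),
    FISSION_CAT = c("FUSED", "UNFUSED", "FUSED", "FUSED"),
    UNKNOWN_POLARIZATION = c("FUSED", "UNFUSED", "POLYMORPHIC",
                             "POLYMORPHIC"),
    HOMOLOGOUS = c("FUSED", "FUSED", "FUSED", "FUSED")
  )
  rows <- list()
  cat_counter <- 0L
  swe_counter <- 0L
  new_cat <- function(k) {
    ids <- sprintf("C%02d", cat_counter + seq_len(k))
    cat_counter <<- cat_counter + k
    ids
  }
  for (klass in names(states)) {
    k_units <- n_per_class[[klass]]
    n_cat <- if (klass == "HOMOLOGOUS") 1L else 2L
    for (i in seq_len(k_units)) {
      swe_counter <- swe_counter + 1L
      st <- states[[klass]]
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = sprintf("%s_%d", klass, i),
        swe_chrom = sprintf("S%02d", swe_counter),
        cat_chroms = paste(new_cat(n_cat), collapse = ";"),
        state_swe = st[1], state_cat = st[2], state_reali = st[3],
        state_juvernica = st[4], is_sex = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_z)) {
    swe_counter <- swe_counter + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = sprintf("Z_%d", i), swe_chrom = sprintf("S%02d", swe_counter),
      cat_chroms = new_cat(1L), state_swe = "FUSED", state_cat = "FUSED",
      state_reali = "FUSED", state_juvernica = "FUSED", is_sex = TRUE,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    kar <- karyotype(data.frame(
      unit_id = character(), swe_chrom = character(),
      cat_chroms = character(), state_swe = character(),
      state_cat = character(), state_reali = character(),
      state_juvernica = character(), is_sex = logical(),
      stringsAsFactors = FALSE))
    markers <- data.frame(chrom = character(), pos = integer(),
                          swe_allele = character(), cat_allele = character(),
                          unit_id = character(), stringsAsFactors = FALSE)
    return(list(karyotype = kar, markers = markers))
  }
  kar <- karyotype(do.call(rbind, rows))

  markers <- with_seed(seed, {
    per_chrom <- lapply(seq_len(nrow(kar)), function(i) {
      chroms <- strsplit(kar$cat_chroms[i], ";", fixed = TRUE)[[1L]]
      do.call(rbind, lapply(chroms, function(ch) {
        pos <- sort(sample.int(chrom_length, markers_per_chromosome))
        swe <- sample(c("A", "C", "G", "T"), markers_per_chromosome,
                      replace = TRUE)
        shift <- sample.int(3L, markers_per_chromosome, replace = TRUE)
        bases <- c("A", "C", "G", "T")
        cat_al <- bases[(match(swe, bases) - 1L + shift) %% 4L + 1L]
        data.frame(chrom = ch, pos = pos, swe_allele = swe,
                   cat_allele = cat_al, unit_id = kar$unit_id[i],
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, per_chrom)
  })
  rownames(markers) <- NULL
  list(karyotype = kar, markers = markers)
}

# Units carried by an F2 cohort: scan-eligible autosomal units plus Z units.
cohort_units <- function(kar) {
  rbind(eligible_units(kar), kar[kar$is_sex, , drop = FALSE])
}

#' Simulate achiasmatic female gametes with drive
#'
#' Draws the maternal origin of every non-sex cohort unit for `n` gametes.
#' Because female meiosis is achiasmatic, each unit segregates intact; the
#' gamete carries the CAT side with probability `drive[class]`,
#' independently across units and gametes.
#'
#' @param n Number of gametes.
#' @param drive [drive_params()] vector.
#' @param kar A `karyotype`; the F1 mother is heterokaryotypic at all
#'   eligible units.
#' @param seed Optional seed.
#' @return Integer matrix `n x units` (columns named by unit) with 1 where
#'   the gamete carries the CAT state and 0 for the SWE state.
#' @export
simulate_female_gametes <- function(n, drive = drive_params(), kar,
                                    seed = NULL) {
  units <- eligible_units(kar)
  with_seed(seed, {
    m <- matrix(0L, n, nrow(units),
                dimnames = list(NULL, units$unit_id))
    for (j in seq_len(nrow(units))) {
      m[, j] <- stats::rbinom(n, 1L, drive[[units$class[j]]])
    }
    m
  })
}

# male F1 gametes: same per-unit Bernoulli draw (drive_male), plus optional
# one obligate crossover per unit expressed as a (recombinant, breakpoint)
# pair applied to the per-marker origin vector downstream.
simulate_male_gametes <- function(n, drive, kar, recomb) {
  units <- eligible_units(kar)
  pat <- matrix(0L, n, nrow(units), dimnames = list(NULL, units$unit_id))
  for (j in seq_len(nrow(units))) {
    pat[, j] <- stats::rbinom(n, 1L, drive[[units$class[j]]])
  }
  rec <- NULL
  if (recomb && nrow(units)) {
    recombinant <- matrix(stats::rbinom(n * nrow(units), 1L, 0.5) == 1L,
                          n, nrow(units), dimnames = dimnames(pat))
    breakpoint <- matrix(stats::runif(n * nrow(units)), n, nrow(units),
                         dimnames = dimnames(pat))
    rec <- list(recombinant = recombinant, breakpoint = breakpoint)
  }
  list(origin = pat, recomb = rec)
}

new_f2_cohort <- function(cross, n, sex, units, maternal, paternal,
                          recomb = NULL) {
  structure(list(cross = cross, n = n, sex = sex, units = units,
                 maternal = maternal, paternal = paternal, recomb = recomb,
                 aneuploid = data.frame(individual = integer(),
                                        unit_id = character(),
                                        extra_origin = character(),
                                        stringsAsFactors = FALSE),
                 stage = rep("sampled", n)),
            class = "f2_cohort")
}

# Z-unit transmission shared by both cross designs. The F1 mother carries a
# single SWE-origin Z per unit (her father was SWE); sons receive it,
# daughters receive only the paternal Z (the W is invisible to markers).
z_origins <- function(n, sex, z_units, paternal_z_cat_prob) {
  k <- nrow(z_units)
  mat <- matrix(NA_integer_, n, k, dimnames = list(NULL, z_units$unit_id))
  pat <- matrix(0L, n, k, dimnames = list(NULL, z_units$unit_id))
  if (k == 0L) return(list(maternal = mat, paternal = pat))
  males <- sex == "male"
  mat[males, ] <- 0L
  if (paternal_z_cat_prob > 0) {
    pat[] <- stats::rbinom(n * k, 1L, paternal_z_cat_prob)
  }
  list(maternal = mat, paternal = pat)
}

#' Simulate a backcross F2 cohort (F1 female x SWE male)
#'
#' Maternal unit origins come from drive-biased achiasmatic female meiosis;
#' the SWE father is homozygous, so every paternal copy is SWE. The
#' expected SWE allele frequency at a rearranged unit is `1 - d/2` for
#' drive `d` (0.75 under Mendelian segregation).
#'
#' @inheritParams simulate_female_gametes
#' @param n_offspring Number of F2 offspring.
#' @param recomb Ignored for the backcross (female meiosis is achiasmatic
#'   and the father is homokaryotypic); kept for interface symmetry.
#' @return An `f2_cohort` object.
#' @export
simulate_backcross <- function(n_offspring, drive = drive_params(), kar,
                               recomb = FALSE, seed = NULL) {
  stopifnot(n_offspring >= 1)
  with_seed(seed, {
    units <- cohort_units(kar)
    auto <- !units$is_sex
    sex <- ifelse(stats::rbinom(n_offspring, 1L, 0.5) == 1L,
                  "female", "male")
    maternal <- matrix(NA_integer_, n_offspring, nrow(units),
                       dimnames = list(NULL, units$unit_id))
    paternal <- matrix(0L, n_offspring, nrow(units),
                       dimnames = list(NULL, units$unit_id))
    if (any(auto)) {
      maternal[, auto] <- simulate_female_gametes(
        n_offspring, drive, kar, seed = NULL)
    }
    if (any(!auto)) {
      z <- z_origins(n_offspring, sex, units[!auto, , drop = FALSE], 0)
      maternal[, !auto] <- z$maternal
      paternal[, !auto] <- z$paternal
    }
    new_f2_cohort("backcross", n_offspring, sex, units, maternal, paternal)
  })
}

#' Simulate an intercross F2 cohort (F1 x F1)
#'
#' Maternal origins are drawn with `drive_female` (achiasmatic, no
#' recombination); paternal origins with `drive_male`, optionally with one
#' obligate crossover per unit at a uniform breakpoint (male meiosis is
#' chiasmatic). The expected SWE allele frequency at a unit is
#' `((1 - d_f) + (1 - d_m)) / 2` without recombination; a crossover mixes
#' the two paternal haplotypes along the unit, pulling per-marker paternal
#' expectations towards 0.5 when `d_m != 0.5` (with the Mendelian default
#' `d_m = 0.5` expectations are unchanged).
#'
#' @inheritParams simulate_backcross
#' @param drive_female,drive_male [drive_params()] for the two meioses.
#' @param recomb Logical; apply one obligate crossover per unit in the
#'   male.
#' @return An `f2_cohort` object.
#' @export
simulate_intercross <- function(n_offspring, drive_female = drive_params(),
                                drive_male = drive_params(), kar,
                                recomb = TRUE, seed = NULL) {
  stopifnot(n_offspring >= 1)
  with_seed(seed, {
    units <- cohort_units(kar)
    auto <- !units$is_sex
    sex <- ifelse(stats::rbinom(n_offspring, 1L, 0.5) == 1L,
                  "female", "male")
    maternal <- matrix(NA_integer_, n_offspring, nrow(units),
                       dimnames = list(NULL, units$unit_id))
    paternal <- matrix(0L, n_offspring, nrow(units),
                       dimnames = list(NULL, units$unit_id))
    rec <- NULL
    if (any(auto)) {
      maternal[, auto] <- simulate_female_gametes(
        n_offspring, drive_female, kar, seed = NULL)
      male <- simulate_male_gametes(n_offspring, drive_male, kar, recomb)
      paternal[, auto] <- male$origin
      rec <- male$recomb
    }
    if (any(!auto)) {
      z <- z_origins(n_offspring, sex, units[!auto, , drop = FALSE], 0.5)
      maternal[, !auto] <- z$maternal
      paternal[, !auto] <- z$paternal
    }
    new_f2_cohort("intercross", n_offspring, sex, units, maternal, paternal,
                  recomb = rec)
  })
}

#' Make a fraction of individuals trisomic for one unit
#'
#' Adds an extra copy of one haplotype (SWE or CAT origin) of `unit_id` to
#' a random subset of `round(fraction * n)` individuals. Read simulation
#' then weights allele dosage by copy number (trisomic individuals
#' contribute each allele at dosage/3 and 1.5x depth), so the expected
#' per-marker depth of the unit scales by `1 + fraction/2`.
#'
#' @param cohort An `f2_cohort`.
#' @param unit_id Unit to make trisomic.
#' @param fraction Fraction of individuals affected, in \[0, 1\].
#' @param extra_origin `"S"` or `"C"`: origin of the extra copy.
#' @param seed Optional seed.
#' @return The modified cohort.
#' @export
inject_aneuploidy <- function(cohort, unit_id, fraction,
                              extra_origin = c("S", "C"), seed = NULL) {
  extra_origin <- match.arg(extra_origin)
  stopifnot_scalar_prob(fraction, "fraction")
  if (!unit_id %in% cohort$units$unit_id) {
    stop("unknown unit_id: ", unit_id, call. = FALSE)
  }
  k <- as.integer(round_half_up(fraction * cohort$n))
  if (k == 0L) return(cohort)
  idx <- with_seed(seed, sample.int(cohort$n, k))
  cohort$aneuploid <- rbind(
    cohort$aneuploid,
    data.frame(individual = idx, unit_id = unit_id,
               extra_origin = extra_origin, stringsAsFactors = FALSE))
  cohort
}

#' Apply genotype-dependent viability selection
#'
#' Off by default (`loss = NULL`, everybody survives). Used for
#' sensitivity experiments separating meiotic drive (acts before
#' fertilization, visible in egg pools) from early viability selection
#' (shifts frequencies only among survivors).
#'
#' @param cohort An `f2_cohort`.
#' @param loss `NULL`, or a data.frame with columns `unit_id`, `genotype`
#'   (`"SS"`, `"SC"`, `"CC"`; `"S"`/`"C"` for hemizygous Z) and
#'   `loss_prob`. Per-individual survival is the product over matching
#'   rows of `1 - loss_prob`.
#' @param seed Optional seed.
#' @return The cohort with `$stage` set to `"dead_embryo"` or
#'   `"survivor"`; combine with [subset_cohort()] to build stage pools.
#' @export
viability_filter <- function(cohort, loss = NULL, seed = NULL) {
  if (is.null(loss) || !nrow(loss)) {
    cohort$stage <- rep("survivor", cohort$n)
    return(cohort)
  }
  stopifnot(all(c("unit_id", "genotype", "loss_prob") %in% names(loss)))
  stopifnot(all(loss$loss_prob >= 0 & loss$loss_prob <= 1))
  surv_p <- rep(1, cohort$n)
  for (r in seq_len(nrow(loss))) {
    j <- match(loss$unit_id[r], cohort$units$unit_id)
    if (is.na(j)) stop("unknown unit_id in loss table: ", loss$unit_id[r],
                       call. = FALSE)
    s_copies <- (1L - cohort$maternal[, j]) + (1L - cohort$paternal[, j])
    copies <- (!is.na(cohort$maternal[, j])) + (!is.na(cohort$paternal[, j]))
    s_copies <- ifelse(is.na(cohort$maternal[, j]),
                       1L - cohort$paternal[, j], s_copies)
    geno <- ifelse(copies == 2L,
                   c("CC", "SC", "SS")[s_copies + 1L],
                   c("C", "S")[s_copies + 1L])
    hit <- geno == loss$genotype[r]
    surv_p[hit] <- surv_p[hit] * (1 - loss$loss_prob[r])
  }
  survived <- with_seed(seed, stats::rbinom(cohort$n, 1L, surv_p) == 1L)
  cohort$stage <- ifelse(survived, "survivor", "dead_embryo")
  cohort
}

#' Subset an F2 cohort by individual index
#'
#' @param cohort An `f2_cohort`.
#' @param idx Integer or logical index of individuals to keep.
#' @return The subsetted cohort, with aneuploidy records re-indexed.
#' @export
subset_cohort <- function(cohort, idx) {
  idx <- seq_len(cohort$n)[idx]
  cohort$sex <- cohort$sex[idx]
  cohort$stage <- cohort$stage[idx]
  cohort$maternal <- cohort$maternal[idx, , drop = FALSE]
  cohort$paternal <- cohort$paternal[idx, , drop = FALSE]
  if (!is.null(cohort$recomb)) {
    cohort$recomb$recombinant <- cohort$recomb$recombinant[idx, ,
                                                           drop = FALSE]
    cohort$recomb$breakpoint <- cohort$recomb$breakpoint[idx, ,
                                                         drop = FALSE]
  }
  keep <- cohort$aneuploid$individual %in% idx
  an <- cohort$aneuploid[keep, , drop = FALSE]
  an$individual <- match(an$individual, idx)
  cohort$aneuploid <- an
  cohort$n <- length(idx)
  cohort
}

# per-individual copy number and SWE copy count for one unit column j,
# before any per-marker recombination adjustment
unit_dosage <- function(cohort, j) {
  mat <- cohort$maternal[, j]
  pat <- cohort$paternal[, j]
  copies <- as.integer(!is.na(mat)) + as.integer(!is.na(pat))
  swe <- ifelse(is.na(mat), 0L, 1L - mat) + ifelse(is.na(pat), 0L, 1L - pat)
  an <- cohort$aneuploid[cohort$aneuploid$unit_id ==
                           cohort$units$unit_id[j], , drop = FALSE]
  if (nrow(an)) {
    copies[an$individual] <- copies[an$individual] + 1L
    extra_s <- an$individual[an$extra_origin == "S"]
    swe[extra_s] <- swe[extra_s] + 1L
  }
  list(copies = copies, swe = swe)
}

#' Simulate pooled sequencing read counts at marker loci
#'
#' For each marker and pool the true pool SWE frequency is the copy-number
#' weighted mean SWE dosage across the pool's individuals. Read depth is
#' drawn per marker (Poisson or fixed) scaled by the pool's mean relative
#' copy number at the unit; each read reports the true allele subject to
#' sequencing error, and the same reads are then "mapped" in the two
#' reference orientations, where non-reference reads are lost with
#' probability `ref_bias` (binomial thinning).
#'
#' Pools partition the cohort by index ranges in the order given, so pool
#' sizes must sum to the cohort size.
#'
#' @param cohort An `f2_cohort`.
#' @param markers Marker table from [make_karyotype_and_markers()].
#' @param pools Data.frame of [pool_spec()] rows.
#' @param seed Optional seed; identical `(cohort, markers, pools, seed)`
#'   give identical counts.
#' @return Data.frame with columns `chrom`, `pos`, `orientation`
#'   (`"SWE_ref"`/`"CAT_ref"`), `pool_id`, `swe_reads`, `cat_reads`,
#'   `other_reads`.
#' @export
simulate_pool_reads <- function(cohort, markers, pools, seed = NULL) {
  stopifnot(inherits(cohort, "f2_cohort"), is.data.frame(pools))
  if (any(pools$n_individuals < 1L)) stop("empty pool", call. = FALSE)
  if (sum(pools$n_individuals) != cohort$n) {
    stop("pool sizes must partition the cohort (sum to ", cohort$n, ")",
         call. = FALSE)
  }
  mk <- markers[markers$unit_id %in% cohort$units$unit_id, , drop = FALSE]
  mk <- mk[order(match(mk$unit_id, cohort$units$unit_id), mk$chrom, mk$pos), ,
           drop = FALSE]
  # relative position of each marker along its unit, for male crossovers
  relpos <- stats::ave(seq_len(nrow(mk)), mk$unit_id,
                       FUN = function(ix) (seq_along(ix) - 0.5) /
                         length(ix))
  unit_j <- match(mk$unit_id, cohort$units$unit_id)
  ends <- cumsum(pools$n_individuals)
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  with_seed(seed, {
    out <- vector("list", nrow(pools))
    for (p in seq_len(nrow(pools))) {
      idx <- starts[p]:ends[p]
      q <- numeric(nrow(mk))
      depth_scale <- numeric(nrow(mk))
      for (j in unique(unit_j)) {
        rows <- which(unit_j == j)
        dos <- unit_dosage(cohort, j)
        w_sum <- sum(dos$copies[idx]) / 2
        depth_scale[rows] <- mean(dos$copies[idx]) / 2
        rec <- cohort$recomb
        if (!is.null(rec) &&
            cohort$units$unit_id[j] %in% colnames(rec$recombinant)) {
          # a marker past a crossover breakpoint sees the other paternal
          # haplotype; accumulate the flips with a prefix sum over sorted
          # breakpoints instead of looping individuals per marker
          cn <- cohort$units$unit_id[j]
          pat <- cohort$paternal[idx, j]
          s_base <- sum(dos$swe[idx])
          rec_i <- which(rec$recombinant[idx, cn])
          bps <- rec$breakpoint[idx, cn][rec_i]
          flip <- 2L * pat[rec_i] - 1L # S copy change when haplotype flips
          ord <- order(bps)
          csum <- c(0L, cumsum(flip[ord]))
          delta <- csum[findInterval(relpos[rows], bps[ord]) + 1L]
          q[rows] <- ((s_base + delta) / 2) / w_sum
        } else {
          q[rows] <- sum(dos$swe[idx] / 2) / w_sum
        }
      }
      mu <- pools$mean_depth[p] * depth_scale
      depth <- if (pools$depth_model[p] == "fixed") {
        as.integer(round_half_up(mu))
      } else {
        stats::rpois(length(mu), mu)
      }
      e <- pools$error_rate[p]
      b <- pools$ref_bias[p]
      n_s <- stats::rbinom(length(depth), depth, q)
      n_c <- depth - n_s
      err_s <- stats::rbinom(length(n_s), n_s, e)
      err_c <- stats::rbinom(length(n_c), n_c, e)
      s_to_c <- stats::rbinom(length(err_s), err_s, 1 / 3)
      c_to_s <- stats::rbinom(length(err_c), err_c, 1 / 3)
      s_reads <- n_s - err_s + c_to_s
      c_reads <- n_c - err_c + s_to_c
      o_reads <- (err_s - s_to_c) + (err_c - c_to_s)
      swe_ref <- data.frame(
        chrom = mk$chrom, pos = mk$pos, orientation = "SWE_ref",
        pool_id = pools$pool_id[p],
        swe_reads = s_reads,
        cat_reads = stats::rbinom(length(c_reads), c_reads, 1 - b),
        other_reads = stats::rbinom(length(o_reads), o_reads, 1 - b),
        stringsAsFactors = FALSE)
      cat_ref <- data.frame(
        chrom = mk$chrom, pos = mk$pos, orientation = "CAT_ref",
        pool_id = pools$pool_id[p],
        swe_reads = stats::rbinom(length(s_reads), s_reads, 1 - b),
        cat_reads = c_reads,
        other_reads = stats::rbinom(length(o_reads), o_reads, 1 - b),
        stringsAsFactors = FALSE)
      out[[p]] <- rbind(swe_ref, cat_ref)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Read or write a sync-style read count table
#'
#' Tab-separated, one row per marker x orientation x pool:
#' `chrom`, `pos`, `orientation`, `pool_id`, `swe_reads`, `cat_reads`,
#' `other_reads`. Lines starting with `#` are treated as comments.
#'
#' @param path File path.
#' @return `read_pool_counts()` returns the data.frame;
#'   `write_pool_counts()` returns `path` invisibly.
#' @export
read_pool_counts <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_pool_counts
#' @param counts Read count data.frame.
#' @export
write_pool_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a marker table
#'
#' Tab-separated marker table: `chrom`, `pos`, `swe_allele`, `cat_allele`,
#' `unit_id`.
#'
#' @param path File path.
#' @return `read_marker_table()` returns the data.frame.
#' @export
read_marker_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_marker_table
#' @param markers Marker data.frame.
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
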