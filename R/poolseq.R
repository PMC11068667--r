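# Allele frequency estimation from per-orientation pooled read counts.
#
# Reads are mapped to two modified references (all fixed differences set to
# the SWE or the CAT allele); averaging the allele frequency of both
# mappings cancels symmetric, orientation-specific reference bias. Markers
# must pass a likelihood-ratio polymorphism filter before entering unit
# averages.

#' Per-marker allele frequency and polymorphism filter
#'
#' Computes the SWE allele frequency `swe / (swe + cat)` (reads carrying
#' neither marker allele are excluded: fixed-difference markers are
#' biallelic by construction), and a likelihood-ratio test of polymorphism.
#' The LR statistic is `2 * (l(q_hat) - l(q0))` for a binomial likelihood
#' of SWE reads, where `q0` is the nearer monomorphic null. A strictly
#' monomorphic null has zero likelihood as soon as one minor read appears,
#' so the null allows a sequencing-error floor: `q0` is `error_floor` or
#' `1 - error_floor`. The p-value is the chi-square(1) upper tail halved
#' (the null lies on the boundary of the parameter space); a marker is
#' retained when `p < threshold`.
#'
#' @param swe,cat,other Read counts (vectorized).
#' @param threshold Retention threshold on the p-value (default `1e-6`).
#' @param error_floor Sequencing-error rate allowed under the monomorphic
#'   null.
#' @return Data.frame with columns `af`, `p_lr`, `retained`,
#'   `depth_informative`. Zero informative reads give `af = NA` and
#'   `retained = FALSE`.
#' @examples
#' estimate_marker_af(30, 30)  # af 0.5, retained
#' estimate_marker_af(60, 0)   # af 1, monomorphic, not retained
#' @export
estimate_marker_af <- function(swe, cat, other = 0, threshold = 1e-6,
                               error_floor = 0.01) {
  stopifnot(all(swe >= 0), all(cat >= 0))
  n <- swe + cat
  af <- ifelse(n > 0, swe / n, NA_real_)
  xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)
  l1 <- xlogy(swe, pmax(af, .Machine$double.eps)) +
    xlogy(cat, pmax(1 - af, .Machine$double.eps))
  q0 <- ifelse(af >= 0.5, 1 - error_floor, error_floor)
  l0 <- xlogy(swe, q0) + xlogy(cat, 1 - q0)
  lr <- pmax(2 * (l1 - l0), 0)
  p <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  p[is.na(af)] <- NA_real_
  data.frame(af = af, p_lr = p,
             retained = !is.na(p) & p < threshold,
             depth_informative = n)
}

#' Combine per-pool allele frequencies
#'
#' Weighted mean across pools, weighting each pool by the number of
#' individuals it contains (default) or equally.
#'
#' @param af Numeric vector of per-pool allele frequencies (`NA` allowed).
#' @param n_individuals Pool sizes aligned with `af`.
#' @param weighting `"individuals"` or `"equal"`.
#' @return Single combined frequency (`NA` if no pool has data).
#' @export
combine_pools <- function(af, n_individuals,
                          weighting = c("individuals", "equal")) {
  weighting <- match.arg(weighting)
  if (!length(af)) stop("no pools", call. = FALSE)
  w <- if (weighting == "individuals") n_individuals else rep(1, length(af))
  ok <- !is.na(af)
  if (!any(ok)) return(NA_real_)
  sum(af[ok] * w[ok]) / sum(w[ok])
}

#' Average allele frequencies across the two mapping orientations
#'
#' @param af_swe_ref,af_cat_ref Allele frequencies from the SWE-reference
#'   and CAT-reference mappings (`NA` when an orientation is missing).
#' @return Data.frame with `af_mean` (arithmetic mean, or the single
#'   available orientation) and `single_orientation` flag. Errors if both
#'   are missing for some marker.
#' @export
average_orientations <- function(af_swe_ref, af_cat_ref) {
  both_na <- is.na(af_swe_ref) & is.na(af_cat_ref)
  if (any(both_na)) {
    stop("marker with no allele frequency in either orientation",
         call. = FALSE)
  }
  af_mean <- rowMeans(cbind(af_swe_ref, af_cat_ref), na.rm = TRUE)
  data.frame(af_mean = af_mean,
             single_orientation = is.na(af_swe_ref) | is.na(af_cat_ref))
}

#' Marker-level allele frequency table from pooled read counts
#'
#' Runs the full marker pipeline: per (marker, pool, orientation) allele
#' frequencies, individual-count weighted combination across pools,
#' polymorphism filtering on counts summed over pools within each
#' orientation, and averaging over the two mapping orientations. A marker
#' is retained when every orientation with data passes the filter.
#'
#' @param counts Read count data.frame (see [simulate_pool_reads()]).
#' @param pools [pool_spec()] data.frame; `n_individuals` provides the
#'   combination weights.
#' @param threshold,error_floor Passed to [estimate_marker_af()].
#' @param weighting Passed to [combine_pools()].
#' @return Data.frame with columns `chrom`, `pos`, `af_swe_orientation`,
#'   `af_cat_orientation`, `af_mean`, `depth_total`, `retained`,
#'   `single_orientation`.
#' @export
marker_af_table <- function(counts, pools, threshold = 1e-6,
                            error_floor = 0.01,
                            weighting = c("individuals", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("chrom", "pos", "orientation", "pool_id", "swe_reads",
                  "cat_reads", "other_reads") %in% names(counts)))
  counts$n_ind <- pools$n_individuals[match(counts$pool_id, pools$pool_id)]
  if (anyNA(counts$n_ind)) stop("read counts reference unknown pool_id",
                                call. = FALSE)
  key <- interaction(counts$chrom, counts$pos, counts$orientation,
                     drop = TRUE)
  per <- estimate_marker_af(counts$swe_reads, counts$cat_reads,
                            counts$other_reads, threshold, error_floor)
  w <- if (weighting == "individuals") counts$n_ind else rep(1, nrow(counts))
  w <- ifelse(is.na(per$af), 0, w)
  af_comb <- as.numeric(tapply(per$af * w, key, sum, na.rm = TRUE)) /
    as.numeric(tapply(w, key, sum))
  swe_sum <- as.numeric(tapply(counts$swe_reads, key, sum))
  cat_sum <- as.numeric(tapply(counts$cat_reads, key, sum))
  other_sum <- as.numeric(tapply(counts$other_reads, key, sum))
  lev <- levels(key)
  first <- match(lev, key)
  ori <- data.frame(chrom = counts$chrom[first], pos = counts$pos[first],
                    orientation = counts$orientation[first],
                    af = af_comb,
                    retained = estimate_marker_af(swe_sum, cat_sum,
                                                  other_sum, threshold,
                                                  error_floor)$retained,
                    depth = swe_sum + cat_sum + other_sum,
                    stringsAsFactors = FALSE)
  wide_af <- function(o) {
    sub <- ori[ori$orientation == o, c("chrom", "pos", "af", "retained",
                                       "depth")]
    names(sub)[3:5] <- paste0(c("af_", "retained_", "depth_"), o)
    sub
  }
  m <- merge(wide_af("SWE_ref"), wide_af("CAT_ref"),
             by = c("chrom", "pos"), all = TRUE)
  avg <- average_orientations(m$af_SWE_ref, m$af_CAT_ref)
  ret_swe <- ifelse(is.na(m$retained_SWE_ref), TRUE, m$retained_SWE_ref)
  ret_cat <- ifelse(is.na(m$retained_CAT_ref), TRUE, m$retained_CAT_ref)
  out <- data.frame(
    chrom = m$chrom, pos = m$pos,
    af_swe_orientation = m$af_SWE_ref,
    af_cat_orientation = m$af_CAT_ref,
    af_mean = avg$af_mean,
    depth_total = rowSums(cbind(m$depth_SWE_ref, m$depth_CAT_ref),
                          na.rm = TRUE),
    retained = ret_swe & ret_cat,
    single_orientation = avg$single_orientation,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate marker allele frequencies to chromosome units
#'
#' Per CAT chromosome, the unweighted mean of the retained markers'
#' orientation-averaged frequencies; per unit, the mean of its chromosome
#' means (one value for 1:1 units, the mean of the two CAT chromosome
#' means for 1:2 units, treating the pair as a single segregating entity).
#'
#' @param marker_af Output of [marker_af_table()].
#' @param markers Marker table mapping `(chrom, pos)` to units.
#' @param kar A `karyotype`.
#' @return Data.frame with one row per unit: `unit_id`, `class`,
#'   `mean_af`, `n_markers` (retained), `af_cat_1`, `af_cat_2` (`NA` for
#'   1:1 units). Units with zero retained markers are dropped with a
#'   warning.
#' @export
aggregate_unit_af <- function(marker_af, markers, kar) {
  df <- merge(marker_af[marker_af$retained, , drop = FALSE],
              markers[, c("chrom", "pos", "unit_id")],
              by = c("chrom", "pos"))
  if (nrow(df) && any(!df$unit_id %in% kar$unit_id)) {
    stop("retained marker maps to a unit absent from the karyotype",
         call. = FALSE)
  }
  chrom_means <- if (nrow(df)) {
    agg <- stats::aggregate(df$af_mean,
                            by = list(unit_id = df$unit_id,
                                      chrom = df$chrom),
                            FUN = mean)
    names(agg)[3] <- "af"
    cnt <- stats::aggregate(df$af_mean,
                            by = list(unit_id = df$unit_id,
                                      chrom = df$chrom),
                            FUN = length)
    agg$n <- cnt$x
    agg
  } else {
    data.frame(unit_id = character(), chrom = character(), af = numeric(),
               n = integer(), stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(kar)), function(i) {
    cm <- chrom_means[chrom_means$unit_id == kar$unit_id[i], , drop = FALSE]
    if (!nrow(cm)) return(NULL)
    cm <- cm[order(cm$chrom), , drop = FALSE]
    data.frame(unit_id = kar$unit_id[i], class = kar$class[i],
               mean_af = mean(cm$af), n_markers = sum(cm$n),
               af_cat_1 = cm$af[1],
               af_cat_2 = if (nrow(cm) > 1L) cm$af[2] else NA_real_,
               stringsAsFactors = FALSE)
  })
  dropped <- kar$unit_id[vapply(rows, is.null, TRUE)]
  if (length(dropped)) {
    warning("units dropped (no retained markers): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(unit_id = character(), class = character(),
                      mean_af = numeric(), n_markers = integer(),
                      af_cat_1 = numeric(), af_cat_2 = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
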