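# Coverage-based aneuploidy scan.
#
# Systematic aneuploidy of a chromosome category inflates its sequencing
# depth at marker loci relative to other categories; a one-way ANOVA over
# per-chromosome mean depths with Tukey HSD post-hoc contrasts tests for
# such differentials. Per-chromosome (not per-marker) records are the unit
# of replication, to avoid pseudo-replication of correlated markers.

#' Mean marker coverage per chromosome
#'
#' Per marker, depth is summed over pools and averaged over the two
#' mapping orientations; per chromosome, the mean over its markers (a
#' mean, not a sum, so the record is invariant to marker count).
#'
#' @param counts Read count data.frame (see [simulate_pool_reads()]).
#' @param markers Marker table mapping `(chrom, pos)` to units.
#' @param kar A `karyotype`.
#' @param retained Optional logical-bearing data.frame from
#'   [marker_af_table()]; when given, only retained markers contribute.
#' @return Data.frame with `chrom`, `unit_id`, `class`, `mean_depth`,
#'   `n_markers`. Chromosomes with no (retained) markers are omitted.
#' @export
coverage_by_chromosome <- function(counts, markers, kar, retained = NULL) {
  counts$depth <- counts$swe_reads + counts$cat_reads + counts$other_reads
  # sum over pools within orientation, then average the two orientations
  per_ori <- stats::aggregate(
    counts$depth,
    by = list(chrom = counts$chrom, pos = counts$pos,
              orientation = counts$orientation),
    FUN = sum)
  per_marker <- stats::aggregate(
    per_ori$x, by = list(chrom = per_ori$chrom, pos = per_ori$pos),
    FUN = mean)
  names(per_marker)[3] <- "depth"
  if (!is.null(retained)) {
    keep <- retained[retained$retained, c("chrom", "pos")]
    per_marker <- merge(per_marker, keep, by = c("chrom", "pos"))
  }
  per_marker <- merge(per_marker, markers[, c("chrom", "pos", "unit_id")],
                      by = c("chrom", "pos"))
  if (!nrow(per_marker)) {
    return(data.frame(chrom = character(), unit_id = character(),
                      class = character(), mean_depth = numeric(),
                      n_markers = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(per_marker$depth,
                          by = list(chrom = per_marker$chrom,
                                    unit_id = per_marker$unit_id),
                          FUN = mean)
  names(agg)[3] <- "mean_depth"
  cnt <- stats::aggregate(per_marker$depth,
                          by = list(chrom = per_marker$chrom,
                                    unit_id = per_marker$unit_id),
                          FUN = length)
  agg$n_markers <- cnt$x
  agg$class <- kar$class[match(agg$unit_id, kar$unit_id)]
  out <- agg[order(agg$chrom), c("chrom", "unit_id", "class", "mean_depth",
                                 "n_markers")]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of coverage across chromosome classes
#'
#' Fixed-effects ANOVA of per-chromosome mean depth grouped by
#' rearrangement class (the four autosomal classes plus Z), with Tukey
#' honest-significant-difference post-hoc contrasts.
#'
#' @param records Output of [coverage_by_chromosome()].
#' @return List with `anova` (data.frame: `df_between`, `df_within`,
#'   `F`, `p_value`; `F` is `NA` with a `diagnostic` when within-group
#'   variance is zero), `posthoc` (Tukey contrasts: `contrast`, `diff`,
#'   `lwr`, `upr`, `p_adj`) and `groups` (per-class `n`, `mean`, `sd`).
#' @export
coverage_anova <- function(records) {
  records <- records[!is.na(records$class), , drop = FALSE]
  grp <- factor(records$class)
  if (nlevels(grp) < 2L) stop("need at least 2 chromosome classes",
                              call. = FALSE)
  sizes <- table(grp)
  if (any(sizes < 2L)) {
    stop("each class needs at least 2 chromosomes: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  groups <- data.frame(
    class = levels(grp),
    n = as.integer(sizes),
    mean = as.numeric(tapply(records$mean_depth, grp, mean)),
    sd = as.numeric(tapply(records$mean_depth, grp, stats::sd)),
    stringsAsFactors = FALSE)
  ss_within <- sum((records$mean_depth -
                      stats::ave(records$mean_depth, grp))^2)
  if (ss_within < .Machine$double.eps * sum(records$mean_depth^2)) {
    return(list(
      anova = data.frame(df_between = nlevels(grp) - 1L,
                         df_within = nrow(records) - nlevels(grp),
                         F = NA_real_, p_value = NA_real_,
                         diagnostic = "zero within-class variance"),
      posthoc = NULL, groups = groups))
  }
  fit <- stats::aov(mean_depth ~ class,
                    data = data.frame(mean_depth = records$mean_depth,
                                      class = grp))
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$class
  posthoc <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(posthoc) <- NULL
  list(
    anova = data.frame(df_between = tab$Df[1], df_within = tab$Df[2],
                       F = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
                       diagnostic = NA_character_),
    posthoc = posthoc, groups = groups)
}
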